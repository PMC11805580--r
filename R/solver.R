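# Implicit coupled solver for the axisymmetric tumor-cord equations.
#
# The three tissue fields (extracellular C1, free intracellular C2, bound
# intracellular C3) are advanced with backward Euler; within each step the
# fields and the vessel concentration are swept Gauss-Seidel style
# (C1 -> C2 -> C3 -> Cv) with under-relaxation until the maximum relative
# change falls below the configured tolerance.  C1 is discretized with a
# conservative finite-volume scheme in cylindrical (r, z) coordinates: with
# a sealed wall the interior fluxes telescope exactly, so total mass is
# conserved to solver tolerance.  C2 and C3 have no spatial operator and
# reduce to pointwise implicit updates that are linear once the partner
# field is frozen.

grid_weights <- function(x) {
  n <- length(x)
  faces <- c(x[1], (x[-n] + x[-1]) / 2, x[n])
  list(faces = faces, w = diff(faces))
}

cyl_weights <- function(r) {
  n <- length(r)
  faces <- c(r[1], (r[-n] + r[-1]) / 2, r[n])
  list(faces = faces, w = (faces[-1]^2 - faces[-(n + 1)]^2) / 2)
}

#' Create a fresh cord state
#'
#' Builds the (r, z) grid spanning the annular cord, zero concentration
#' fields, and the geometry-dependent properties for the given normalized
#' vessel radius.
#'
#' @param p A `cord_params` object.
#' @param rhat Normalized vessel radius (default 1: uncompressed).
#' @param t Initial time, s.
#' @return An object of class `cord_state`.
#' @export
new_cord_state <- function(p, rhat = 1, t = 0) {
  g <- p$geometry
  n <- p$numerics
  r_v <- rhat * g$rv0
  r <- seq(r_v, g$R_cord, length.out = n$n_r)
  z <- seq(0, g$L_cord, length.out = n$n_z)
  props <- update_geometry_props(rhat, g, p$transport$D0)
  zero <- matrix(0, n$n_r, n$n_z)
  structure(list(
    r = r, z = z,
    C1 = zero, C2 = zero, C3 = zero,
    r_v = r_v, rhat = rhat,
    delta1 = props$delta1, delta2 = props$delta2,
    alpha = props$alpha, D = props$D,
    t = t,
    cache = new.env(parent = emptyenv())
  ), class = "cord_state")
}

#' @export
print.cord_state <- function(x, ...) {
  cat(sprintf("<cord_state t = %.1f s, %d x %d grid, r_v = %.2f um>\n",
              x$t, length(x$r), length(x$z), x$r_v * 1e6))
  cat(sprintf("  max C1 = %.4g, C2 = %.4g, C3 = %.4g uM\n",
              max(x$C1), max(x$C2), max(x$C3)))
  invisible(x)
}

# Assemble the backward-Euler finite-volume system for C1.
# Returns the sparse matrix A such that A c1_new = rhs_base + coupling terms;
# diagonal includes time, reaction-coupling and Robin-boundary parts.
build_c1_matrix <- function(state, p, dt, k1, kv, u_r) {
  nr <- length(state$r); nz <- length(state$z)
  rw <- cyl_weights(state$r)
  zw <- grid_weights(state$z)
  dr <- state$r[2] - state$r[1]
  dz <- if (nz > 1) state$z[2] - state$z[1] else 1
  D <- state$D
  idx <- function(i, j) i + (j - 1L) * nr
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) {
    ii[[length(ii) + 1L]] <<- a; jj[[length(jj) + 1L]] <<- b
    xx[[length(xx) + 1L]] <<- v
  }
  # time + membrane-exchange diagonal
  Vw <- outer(rw$w, zw$w)
  diag_base <- as.vector((state$delta1 / dt + state$alpha * k1) * Vw)
  # Robin faces at the vessel wall (i = 1)
  robin <- kv * state$r[1] * zw$w
  for (j in seq_len(nz)) {
    a <- idx(1L, j)
    diag_base[a] <- diag_base[a] + robin[j]
  }
  # radial diffusive faces
  rfm <- rw$faces[2:nr]                      # interior faces
  for (j in seq_len(nz)) {
    coefs <- D * rfm / dr * zw$w[j]
    for (i in seq_len(nr - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j); cf <- coefs[i]
      add(a, a, cf); add(a, b, -cf); add(b, b, cf); add(b, a, -cf)
    }
  }
  # axial diffusive faces
  if (nz > 1) {
    for (j in seq_len(nz - 1L)) {
      coefs <- D * rw$w / dz
      for (i in seq_len(nr)) {
        a <- idx(i, j); b <- idx(i, j + 1L); cf <- coefs[i]
        add(a, a, cf); add(a, b, -cf); add(b, b, cf); add(b, a, -cf)
      }
    }
  }
  # radial advection (upwind on the sign of u_r), non-conservative form
  if (any(u_r != 0)) {
    for (j in seq_len(nz)) {
      for (i in seq_len(nr)) {
        u <- u_r[i]
        if (u == 0) next
        V <- rw$w[i] * zw$w[j]
        a <- idx(i, j)
        if (u < 0 && i < nr) {          # inflow from larger r
          add(a, idx(i + 1L, j), u * V / dr)
          add(a, a, -u * V / dr)
        } else if (u > 0 && i > 1) {
          add(a, a, u * V / dr)
          add(a, idx(i - 1L, j), -u * V / dr)
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr * nz, nr * nz))
  Matrix::diag(A) <- Matrix::diag(A) + diag_base
  list(A = A, Vw = Vw, zw = zw, rw = rw, robin = robin)
}

c1_system_for <- function(state, p, dt, k1, kv, u_r) {
  sig <- c(dt, state$D, k1, kv, state$r_v, length(state$r), length(state$z),
           state$delta1, state$alpha, u_r)
  cache <- state$cache
  if (!is.null(cache$sig) && length(cache$sig) == length(sig) &&
      all(cache$sig == sig)) {
    return(cache$sys)
  }
  sys <- build_c1_matrix(state, p, dt, k1, kv, u_r)
  # Conditioning scale factors: pure row scaling of the assembled system;
  # a direct solve makes the converged fields invariant to the choice.
  sf <- p$numerics$S_T / max(p$numerics$S_C * p$numerics$S_L^2, .Machine$double.eps)
  sys$scale <- sf
  sys$lu <- Matrix::lu(sys$A * sf)
  cache$sig <- sig
  cache$sys <- sys
  sys
}

#' Discrete spatial operator for the extracellular field
#'
#' Evaluates `D lap(C) - u_r dC/dr` on the cylindrical finite-volume grid
#' (axisymmetric Laplacian `d2/dr2 + (1/r) d/dr + d2/dz2`), with the wall
#' exchange flux `kv (Cv - C)` at the inner radius, and zero normal flux on
#' the remaining boundaries.
#'
#' @param C1 Field matrix (`n_r` x `n_z`).
#' @param r,z Grid coordinate vectors (strictly increasing).
#' @param D Diffusivity, m^2/s.
#' @param u_r Radial velocity per radial node, m/s (scalar or vector).
#' @param kv Wall permeability, m/s (0 seals the wall).
#' @param Cv Vessel concentration per axial node, uM (scalar or vector).
#' @return Matrix of time-derivative contributions (same shape as `C1`).
#' @export
spatial_operator <- function(C1, r, z, D, u_r = 0, kv = 0, Cv = 0) {
  nr <- length(r); nz <- length(z)
  if (is.unsorted(r, strictly = TRUE) || (nz > 1 && is.unsorted(z, strictly = TRUE))) {
    stop("grid coordinates must be strictly increasing", call. = FALSE)
  }
  stopifnot(nrow(C1) == nr, ncol(C1) == nz)
  u_r <- rep_len(u_r, nr)
  Cv <- rep_len(Cv, nz)
  rw <- cyl_weights(r); zw <- grid_weights(z)
  dr <- r[2] - r[1]
  out <- matrix(0, nr, nz)
  # radial fluxes
  rfm <- rw$faces[2:nr]
  gradr <- (C1[-1, , drop = FALSE] - C1[-nr, , drop = FALSE]) / dr
  fluxr <- D * rfm * gradr                      # per radian, per unit z
  for (j in seq_len(nz)) {
    div <- c(fluxr[1, j] + kv * r[1] * (Cv[j] - C1[1, j]),
             diff(fluxr[, j]),
             -fluxr[nr - 1, j])
    out[, j] <- out[, j] + div / rw$w
  }
  # axial fluxes
  if (nz > 1) {
    dz <- z[2] - z[1]
    gradz <- (C1[, -1, drop = FALSE] - C1[, -nz, drop = FALSE]) / dz
    for (i in seq_len(nr)) {
      div <- c(gradz[i, 1], diff(gradz[i, ]), -gradz[i, nz - 1]) * D
      out[i, ] <- out[i, ] + div
    }
  }
  # advection, upwind
  if (any(u_r != 0)) {
    for (j in seq_len(nz)) {
      dfwd <- c((C1[-1, j] - C1[-nr, j]) / dr, NA)   # (C[i+1]-C[i])/dr
      dbwd <- c(NA, (C1[-1, j] - C1[-nr, j]) / dr)   # (C[i]-C[i-1])/dr
      dd <- ifelse(u_r < 0, dfwd, dbwd)
      dd[is.na(dd)] <- 0
      out[, j] <- out[, j] - u_r * dd
    }
  }
  out
}

#' Robin wall flux
#'
#' Flux density entering the tissue across the vessel wall,
#' `kv (Cv - C1_wall)`; positive when the bloodstream concentration exceeds
#' the wall tissue concentration.  With `kv = 0` the wall is sealed.
#'
#' @param C1_wall Tissue concentration at the wall, uM.
#' @param Cv_wall Vessel concentration, uM.
#' @param kv Wall permeability, m/s.
#' @return Flux density in uM m/s.
#' @export
robin_flux <- function(C1_wall, Cv_wall, kv) {
  kv * (Cv_wall - C1_wall)
}

rel_change <- function(new, old) {
  scale <- max(abs(new), abs(old), 1e-20)
  max(abs(new - old)) / scale
}

#' Advance the coupled cord/vessel system one time step
#'
#' Solves the backward-Euler system for the three tissue fields and the
#' vessel concentration by sequential implicit solves iterated to a joint
#' fixed point (Gauss-Seidel sweeps `C1 -> C2 -> C3 -> Cv` with
#' under-relaxation `omega`), stopping when the maximum relative field
#' change drops below `gs_tol`.
#'
#' @param state A `cord_state`.
#' @param vessel Vessel state list (`z`, `Cv`, `lambda`, `Qleak`).
#' @param p A `cord_params` object.
#' @param dt Time step, s.
#' @param ep Electroporation state (see [ep_state_at()]); defaults to the
#'   baseline permeabilities.
#' @param inlet_value Inlet concentration at the new time level, uM.
#' @param u_r Radial tissue velocity per radial node (default 0).
#' @return List with updated `state`, `vessel` and the outer `iterations`.
#' @export
cord_step <- function(state, vessel, p, dt,
                      ep = list(k1 = p$transport$k1_min, kv = p$transport$kv_min),
                      inlet_value = 0, u_r = 0) {
  stopifnot(dt > 0)
  n <- p$numerics
  tr <- p$transport
  nr <- length(state$r); nz <- length(state$z)
  u_r <- rep_len(u_r, nr)
  sys <- c1_system_for(state, p, dt, ep$k1, ep$kv, u_r)
  Vw <- sys$Vw
  zww <- sys$zw$w
  dz <- if (nz > 1) state$z[2] - state$z[1] else state$z[1] + 1

  C1o <- state$C1; C2o <- state$C2; C3o <- state$C3; Cvo <- vessel$Cv
  C1 <- C1o; C2 <- C2o; C3 <- C3o; Cv <- Cvo
  omega <- n$omega
  ak1 <- state$alpha * ep$k1
  d2 <- state$delta2
  exch <- 2 * ep$kv / state$r_v
  rhs_time <- (state$delta1 / dt) * Vw * C1o

  it <- 0L
  repeat {
    it <- it + 1L
    # C1: implicit linear solve with C2 and Cv frozen
    b <- rhs_time + ak1 * Vw * C2
    b[1, ] <- b[1, ] + sys$robin * Cv
    C1new <- matrix(as.numeric(Matrix::solve(sys$lu, as.vector(b) * sys$scale)),
                    nr, nz)
    C1up <- omega * C1new + (1 - omega) * C1
    d1 <- rel_change(C1up, C1); C1 <- C1up
    # C2: pointwise implicit, linear with C1 and C3 frozen
    C2new <- (d2 / dt * C2o + ak1 * C1 + d2 * tr$k_minus2 * C3) /
      (d2 / dt + ak1 + d2 * tr$k2 * (tr$C0 - C3))
    C2up <- omega * C2new + (1 - omega) * C2
    d2c <- rel_change(C2up, C2); C2 <- C2up
    # C3: pointwise implicit, saturating at C0
    C3new <- (C3o / dt + tr$k2 * C2 * tr$C0) / (1 / dt + tr$k2 * C2 + tr$k_minus2)
    C3up <- omega * C3new + (1 - omega) * C3
    d3 <- rel_change(C3up, C3); C3 <- C3up
    # vessel line, using the freshly updated wall values
    Cvnew <- advance_vessel_concentration(Cvo, C1[1, ], exch, vessel$lambda,
                                          dt, dz, inlet_value)
    Cvup <- omega * Cvnew + (1 - omega) * Cv
    dv <- rel_change(Cvup, Cv); Cv <- Cvup

    err <- max(d1, d2c, d3, dv)
    if (err <= n$gs_tol) break
    if (it >= n$max_outer) {
      stop(sprintf(
        "cord_step failed to converge at t = %.3f s: residual %.3e after %d sweeps",
        state$t + dt, err, it), call. = FALSE)
    }
  }
  state$C1 <- C1; state$C2 <- C2; state$C3 <- C3
  state$t <- state$t + dt
  vessel$Cv <- Cv
  list(state = state, vessel = vessel, iterations = it)
}

#' Conservative remesh onto a new vessel radius
#'
#' Rebuilds the radial grid on `[rhat * rv0, R_cord]`, linearly interpolates
#' the concentration fields column by column, and refreshes the
#' geometry-dependent properties.  Uniform fields remain uniform, and the
#' conserved intracellular quantities (`delta2 * V * C`) are preserved by
#' construction because `delta2` scales inversely with the cord volume.
#'
#' @param state A `cord_state`.
#' @param rhat Target normalized vessel radius.
#' @param p A `cord_params` object.
#' @return The remeshed `cord_state`.
#' @export
remesh_cord <- function(state, rhat, p) {
  g <- p$geometry
  r_new <- seq(rhat * g$rv0, g$R_cord, length.out = length(state$r))
  interp <- function(F) {
    apply(F, 2, function(col) stats::approx(state$r, col, xout = r_new,
                                            rule = 2)$y)
  }
  C1 <- pmax(interp(state$C1), 0)
  C2 <- pmax(interp(state$C2), 0)
  C3 <- pmax(interp(state$C3), 0)
  props <- update_geometry_props(rhat, g, p$transport$D0)
  state$r <- r_new
  state$C1 <- C1; state$C2 <- C2; state$C3 <- C3
  state$r_v <- rhat * g$rv0
  state$rhat <- rhat
  state$delta1 <- props$delta1; state$delta2 <- props$delta2
  state$alpha <- props$alpha; state$D <- props$D
  state$cache <- new.env(parent = emptyenv())
  state
}

#' Total drug amount in the cord
#'
#' Cylindrical volume integral (2 pi r weighting) of
#' `delta1 C1 + delta2 (C2 + C3)` over the cord domain.
#'
#' @param state A `cord_state`.
#' @return Amount in umol.
#' @export
total_mass <- function(state) {
  rw <- cyl_weights(state$r)
  zw <- grid_weights(state$z)
  Vw <- 2 * pi * outer(rw$w, zw$w)             # m^3 per cell
  dens <- state$delta1 * state$C1 + state$delta2 * (state$C2 + state$C3)
  sum(dens * Vw) * 1e-3                        # uM * m^3 -> umol
}

#' Run a full electro-chemotherapy simulation
#'
#' Integrates the coupled cord/vessel system from all-zero initial
#' concentrations at `t = 0` to `T_chemo`, applying the electroporation
#' schedule and the configured pharmacokinetic inlet profile, and recording
#' snapshots at the configured report times.  The run is fully
#' deterministic given the configuration.
#'
#' @param p A `cord_params` object.
#' @param horizon Optional override of the simulated time, s (defaults to
#'   `p$protocol$T_chemo`).
#' @param progress Print progress every simulated hour.
#' @return A `cord_trajectory`: report times, per-time cord and vessel
#'   snapshots, a dense per-step wall series at `z = 0` (columns `t`, `Cv0`,
#'   `C1_wall0`), the configuration and solver statistics.
#' @export
run_cord_simulation <- function(p, horizon = NULL, progress = FALSE) {
  stopifnot(inherits(p, "cord_params"))
  horizon <- horizon %||% p$protocol$T_chemo
  n <- p$numerics
  dt <- n$dt
  nsteps <- ceiling(horizon / dt - 1e-9)
  profile <- pk_profile(p$pk$kind, p$pk[[p$pk$kind]])

  ep0 <- ep_state_at(0, p)
  state <- new_cord_state(p, rhat = 1)
  rhat_applied <- 1
  vessel <- vessel_flow_state(seq(0, p$geometry$L_cord, length.out = n$n_z),
                              p, r_v = state$r_v, kvc = ep0$kvc)
  vessel$Cv <- rep(0, n$n_z)

  report_times <- sort(unique(c(0, n$report_times[n$report_times <= horizon + dt / 2])))
  snapshots <- list(snapshot_of(state, vessel))
  snap_t <- 0
  next_report <- 2L  # index into report_times (first is t = 0)

  wall_t <- numeric(nsteps); wall_cv <- numeric(nsteps); wall_c1 <- numeric(nsteps)
  total_iter <- 0L
  last_kvc <- ep0$kvc

  for (k in seq_len(nsteps)) {
    t_new <- k * dt
    ep <- ep_state_at(t_new, p)
    u_r <- rep(0, length(state$r))
    geometry_active <- ep$rhat < 1 &&
      (if (n$remesh_mode == "literal") ep$rhat >= n$remesh_threshold
       else abs(ep$rhat - rhat_applied) > (1 - n$remesh_threshold))
    if (geometry_active && abs(ep$rhat - rhat_applied) > 1e-12) {
      state <- remesh_cord(state, ep$rhat, p)
      rhat_applied <- ep$rhat
      vessel_flow <- vessel_flow_state(vessel$z, p, r_v = state$r_v, kvc = ep$kvc)
      vessel$lambda <- vessel_flow$lambda; vessel$Qleak <- vessel_flow$Qleak
      u_r <- radial_tissue_velocity(state$r, state$r_v, p$geometry$R_cord,
                                    ep$drv_dt)
    } else if (abs(ep$kvc - last_kvc) > 1e-18) {
      vessel_flow <- vessel_flow_state(vessel$z, p, r_v = state$r_v, kvc = ep$kvc)
      vessel$lambda <- vessel_flow$lambda; vessel$Qleak <- vessel_flow$Qleak
    }
    last_kvc <- ep$kvc

    inlet <- pk_concentration(profile, t_new)
    res <- cord_step(state, vessel, p, dt, ep = ep, inlet_value = inlet,
                     u_r = u_r)
    state <- res$state; vessel <- res$vessel
    total_iter <- total_iter + res$iterations

    wall_t[k] <- t_new; wall_cv[k] <- vessel$Cv[1]; wall_c1[k] <- state$C1[1, 1]

    if (next_report <= length(report_times) &&
        t_new >= report_times[next_report] - dt / 2) {
      snapshots[[length(snapshots) + 1L]] <- snapshot_of(state, vessel)
      snap_t <- c(snap_t, t_new)
      next_report <- next_report + 1L
    }
    if (progress && t_new %% 3600 < dt) {
      message(sprintf("t = %5.2f h  maxC1 = %.3g  maxC3 = %.3g  it = %d",
                      t_new / 3600, max(state$C1), max(state$C3),
                      res$iterations))
    }
  }

  structure(list(
    times = snap_t,
    snapshots = snapshots,
    wall_series = tibble::tibble(t = wall_t, Cv0 = wall_cv, C1_wall0 = wall_c1),
    params = p,
    stats = list(n_steps = nsteps, mean_outer_iterations = total_iter / max(nsteps, 1))
  ), class = "cord_trajectory")
}

snapshot_of <- function(state, vessel) {
  list(t = state$t, r = state$r, z = state$z,
       C1 = state$C1, C2 = state$C2, C3 = state$C3,
       r_v = state$r_v, rhat = state$rhat,
       delta1 = state$delta1, delta2 = state$delta2,
       alpha = state$alpha, D = state$D,
       Cv = vessel$Cv, lambda = vessel$lambda, Qleak = vessel$Qleak)
}

#' @export
print.cord_trajectory <- function(x, ...) {
  cat(sprintf("<cord_trajectory: %d snapshots over %.2f h, E = %g V/m, %s, lambda_inl = %g m/s>\n",
              length(x$snapshots), max(x$times) / SEC_PER_HOUR,
              x$params$protocol$E, x$params$pk$kind, x$params$blood$lambda_inl))
  invisible(x)
}

#' Snapshot nearest to a requested time
#'
#' @param traj A `cord_trajectory`.
#' @param t_hours Requested time in hours.
#' @param tol Matching tolerance in hours.
#' @return The stored snapshot list.
#' @export
snapshot_at <- function(traj, t_hours, tol = 0.26) {
  tt <- traj$times / SEC_PER_HOUR
  i <- which.min(abs(tt - t_hours))
  if (abs(tt[i] - t_hours) > tol) {
    stop(sprintf("no snapshot within %.2f h of t = %g h", tol, t_hours),
         call. = FALSE)
  }
  traj$snapshots[[i]]
}
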