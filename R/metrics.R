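# Post-processing metrics: concentration ratios, uniformity ranges,
# transvascular ratio series, reverse-diffusion crossing, exposures.

snapshot_field <- function(snap, field) {
  if (field %in% c("C1", "C2", "C3")) return(snap[[field]])
  eps <- 1e-12
  switch(field,
         "C2/C1" = ifelse(snap$C1 > eps, snap$C2 / snap$C1, NA_real_),
         "C3/C1" = ifelse(snap$C1 > eps, snap$C3 / snap$C1, NA_real_),
         "C3/C2" = ifelse(snap$C2 > eps, snap$C3 / snap$C2, NA_real_),
         stop("unknown field: ", field, call. = FALSE))
}

#' Concentration ratio fields at a snapshot
#'
#' Element-wise C2/C1, C3/C1 and C3/C2; entries whose denominator falls
#' below `eps_div` are flagged undefined (`NA`) and excluded from extrema.
#'
#' @param snap A snapshot (element of `traj$snapshots`) or `cord_state`.
#' @param eps_div Denominator guard, uM.
#' @return List of matrices `r21`, `r31`, `r32` with `NA` where undefined.
#' @export
concentration_ratios <- function(snap, eps_div = 1e-12) {
  guard <- function(num, den) ifelse(den > eps_div, num / den, NA_real_)
  list(r21 = guard(snap$C2, snap$C1),
       r31 = guard(snap$C3, snap$C1),
       r32 = guard(snap$C3, snap$C2))
}

#' Domain uniformity range of a field at given times
#'
#' The difference between the domain maximum and minimum of a
#' concentration field or ratio at a snapshot quantifies the (radial)
#' uniformity of the associated mechanism rate: 0 means perfectly uniform.
#' Extreme locations are reported.
#'
#' @param traj A `cord_trajectory`.
#' @param field One of `"C1"`, `"C2"`, `"C3"`, `"C2/C1"`, `"C3/C1"`,
#'   `"C3/C2"`.
#' @param times_h Report times to evaluate, hours (default: all snapshot
#'   times).
#' @param boundary_only Restrict the extrema to the two radial boundaries
#'   (wall and outermost ring) instead of the full domain.
#' @return A tibble with `t_h`, `field`, `max`, `min`, `range`, and the
#'   `(r, z)` locations of the extremes.
#' @export
uniformity_range <- function(traj, field = "C2/C1", times_h = NULL,
                             boundary_only = FALSE) {
  stopifnot(inherits(traj, "cord_trajectory"))
  times_h <- times_h %||% (traj$times / SEC_PER_HOUR)
  rows <- lapply(times_h, function(th) {
    snap <- snapshot_at(traj, th)
    F <- snapshot_field(snap, field)
    if (boundary_only) F <- F[c(1, nrow(F)), , drop = FALSE]
    vals <- F[is.finite(F)]
    if (length(vals) == 0) {
      stop(sprintf("field %s undefined everywhere at t = %g h", field, th),
           call. = FALSE)
    }
    imax <- which(F == max(vals, na.rm = TRUE), arr.ind = TRUE)[1, ]
    imin <- which(F == min(vals, na.rm = TRUE), arr.ind = TRUE)[1, ]
    rr <- if (boundary_only) snap$r[c(1, length(snap$r))] else snap$r
    tibble::tibble(
      t_h = snap$t / SEC_PER_HOUR, field = field,
      max = max(vals), min = min(vals), range = max(vals) - min(vals),
      r_max = rr[imax[1]], z_max = snap$z[imax[2]],
      r_min = rr[imin[1]], z_min = snap$z[imin[2]])
  })
  dplyr::bind_rows(rows)
}

#' Axial uniformity proxy
#'
#' The maximum over radial rings of the axial spread (max over z minus min
#' over z at fixed r) of a field: 0 for z-invariant fields, larger when
#' the contour lines bend along the vessel axis.
#'
#' @inheritParams uniformity_range
#' @return A tibble with `t_h`, `field`, `axial_spread`.
#' @export
axial_uniformity <- function(traj, field = "C2/C1", times_h = NULL) {
  times_h <- times_h %||% (traj$times / SEC_PER_HOUR)
  rows <- lapply(times_h, function(th) {
    snap <- snapshot_at(traj, th)
    F <- snapshot_field(snap, field)
    if (ncol(F) < 2) stop("need at least two axial columns", call. = FALSE)
    spread <- apply(F, 1, function(row) {
      v <- row[is.finite(row)]
      if (length(v) == 0) NA_real_ else max(v) - min(v)
    })
    tibble::tibble(t_h = snap$t / SEC_PER_HOUR, field = field,
                   axial_spread = if (all(is.na(spread))) NA_real_
                                  else max(spread, na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' Transvascular ratio series at the inlet
#'
#' Time series of the bloodstream-to-wall concentration ratio
#' `Cv / C1(r_v)` at `z = 0`.  Above 1 the drug extravasates; below 1 it
#' diffuses back from the tissue into the bloodstream.  The dense per-step
#' wall series recorded by [run_cord_simulation()] is used, so the series
#' resolution equals the solver time step.
#'
#' @param traj A `cord_trajectory`.
#' @param eps_div Denominator guard, uM: the ratio is `NA` where the wall
#'   concentration is below the guard.
#' @return A tibble with `t_h`, `Cv0`, `C1_wall0`, `ratio`.
#' @export
transvascular_ratio_series <- function(traj, eps_div = NULL) {
  stopifnot(inherits(traj, "cord_trajectory"))
  eps_div <- eps_div %||% traj$params$numerics$eps_div
  ws <- traj$wall_series
  tibble::tibble(
    t_h = ws$t / SEC_PER_HOUR,
    Cv0 = ws$Cv0, C1_wall0 = ws$C1_wall0,
    ratio = ifelse(ws$C1_wall0 > eps_div, ws$Cv0 / ws$C1_wall0, NA_real_))
}

#' First reverse-diffusion crossing
#'
#' Finds the first time the transvascular ratio falls below 1, locating
#' the crossing by linear interpolation between consecutive samples.
#'
#' @param series A tibble from [transvascular_ratio_series()], or any
#'   tibble with columns `t_h` and `ratio`.
#' @return A one-row tibble with `t_cross_h` and `direction`
#'   (`"reverse_diffusion"`), or a zero-row tibble if the ratio never
#'   drops below 1.
#' @export
reverse_diffusion_time <- function(series) {
  ok <- is.finite(series$ratio)
  t <- series$t_h[ok]; x <- series$ratio[ok]
  if (length(x) < 2) {
    stop("need at least two defined ratio samples", call. = FALSE)
  }
  below <- which(x < 1)
  empty <- tibble::tibble(t_cross_h = numeric(0), direction = character(0))
  if (length(below) == 0) return(empty)
  k <- below[1]
  if (k == 1) {
    return(tibble::tibble(t_cross_h = t[1], direction = "reverse_diffusion"))
  }
  # linear interpolation between samples k-1 (>= 1) and k (< 1)
  f <- (x[k - 1] - 1) / (x[k - 1] - x[k])
  tibble::tibble(t_cross_h = t[k - 1] + f * (t[k] - t[k - 1]),
                 direction = "reverse_diffusion")
}

#' Per-point exposure integrals
#'
#' Trapezoidal time integrals of C1, C2 and C3 at every grid point up to
#' `T_h`, in uM h.
#'
#' @param traj A `cord_trajectory`.
#' @param T_h Upper integration limit, hours (defaults to the last
#'   snapshot).
#' @return A tibble with `r`, `z`, `C1exp`, `C2exp`, `C3exp` (uM h).
#' @export
exposures <- function(traj, T_h = NULL) {
  stopifnot(inherits(traj, "cord_trajectory"))
  T_h <- T_h %||% (max(traj$times) / SEC_PER_HOUR)
  keep <- which(traj$times / SEC_PER_HOUR <= T_h + 1e-9)
  if (length(keep) < 2) stop("need at least two snapshots within T_h", call. = FALSE)
  snaps <- traj$snapshots[keep]
  tt <- traj$times[keep] / SEC_PER_HOUR
  ref <- snaps[[length(snaps)]]
  acc <- list(C1 = 0 * ref$C1, C2 = 0 * ref$C2, C3 = 0 * ref$C3)
  for (k in seq_len(length(snaps) - 1L)) {
    w <- (tt[k + 1] - tt[k]) / 2
    for (f in names(acc)) {
      a <- interp_to_grid(snaps[[k]][[f]], snaps[[k]]$r, ref$r)
      b <- interp_to_grid(snaps[[k + 1]][[f]], snaps[[k + 1]]$r, ref$r)
      acc[[f]] <- acc[[f]] + w * (a + b)
    }
  }
  grid <- expand.grid(ri = seq_along(ref$r), zi = seq_along(ref$z))
  tibble::tibble(
    r = ref$r[grid$ri], z = ref$z[grid$zi],
    C1exp = acc$C1[cbind(grid$ri, grid$zi)],
    C2exp = acc$C2[cbind(grid$ri, grid$zi)],
    C3exp = acc$C3[cbind(grid$ri, grid$zi)])
}
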