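# Electroporation: conductivity sigmoid, degrees of (ir)reversible
# electroporation, permeability interpolation, vasoconstriction and the
# induced radial tissue motion.

#' Effective electrical conductivity under an applied field
#'
#' Sigmoidal interpolation between the baseline and fully permeabilized
#' conductivity, centred midway between the reversible and irreversible
#' thresholds: `sigma(E) = (sigma_max - sigma_min) /
#' (1 + alpha* exp(-(E - a*)/b*)) + sigma_min` with
#' `a* = (E_rev + E_irrev)/2` and `b* = (E_irrev - E_rev)/beta*`.
#'
#' @param E Electric field magnitude, V/m (vectorized).
#' @param elec One electrical parameter group, e.g.
#'   `default_params()$electrical$tissue`.
#' @return Conductivity in S/m, strictly increasing in `E` and bounded in
#'   `(sigma_min, sigma_max)`.
#' @export
effective_conductivity <- function(E, elec) {
  stopifnot(all(E >= 0))
  a_star <- (elec$E_rev + elec$E_irrev) / 2
  b_star <- (elec$E_irrev - elec$E_rev) / elec$beta_star
  (elec$sigma_max - elec$sigma_min) /
    (1 + elec$alpha_star * exp(-(E - a_star) / b_star)) + elec$sigma_min
}

#' Degree of electroporation
#'
#' Conductivity rise normalized to the full dynamic range:
#' `DOE(E) = (sigma(E) - sigma_min) / (sigma_max - sigma_min)`, in `[0, 1)`
#' and monotone in `E`.
#'
#' @inheritParams effective_conductivity
#' @export
doe <- function(E, elec) {
  (effective_conductivity(E, elec) - elec$sigma_min) /
    (elec$sigma_max - elec$sigma_min)
}

#' Degree of irreversible electroporation
#'
#' Zero below the irreversible threshold; above it, the conductivity rise
#' beyond `sigma(E_irrev)` normalized by the remaining range.
#'
#' @inheritParams effective_conductivity
#' @export
die <- function(E, elec) {
  sigma_irrev <- effective_conductivity(elec$E_irrev, elec)
  s <- effective_conductivity(E, elec)
  out <- ifelse(E < elec$E_irrev, 0,
                (s - sigma_irrev) / (elec$sigma_max - sigma_irrev))
  pmax(out, 0)
}

#' Transient degree of electroporation
#'
#' The permeabilized state decays towards its irreversible floor with time
#' constant `tau_i` after each pulse application:
#' `DOE_R = DOE(E) * ((1 - DIE(E)) * exp(-t_p / tau_i) + DIE(E))`.
#' At `t_p = 0` this equals `DOE(E)`; as `t_p -> Inf` it tends to
#' `DOE(E) * DIE(E)`.
#'
#' @inheritParams effective_conductivity
#' @param t_p Time elapsed since the last pulse application, s (vectorized;
#'   `Inf` allowed and gives the fully decayed state).
#' @export
doe_r <- function(E, t_p, elec) {
  stopifnot(all(t_p >= 0))
  d <- doe(E, elec)
  di <- die(E, elec)
  d * ((1 - di) * exp(-t_p / elec$tau_i) + di)
}

#' Electro-modulated permeability
#'
#' Linear interpolation between the resting and fully permeabilized
#' permeability, weighted by the transient degree of electroporation.
#' Applies identically to the cell membrane (`k1`) and the vessel wall
#' (`kv`), and optionally to the hydraulic permeability `kvc`.
#'
#' @inheritParams doe_r
#' @param k_min,k_max Permeability bounds (same units returned).
#' @return Permeability within `[k_min, k_max]`.
#' @export
ep_permeability <- function(E, t_p, k_min, k_max, elec) {
  stopifnot(k_min <= k_max)
  doe_r(E, t_p, elec) * (k_max - k_min) + k_min
}

#' Normalized vessel radius under vasoconstriction
#'
#' Double-exponential law: `rhat = (1 - rhat_min) * exp(-m_r * E) *
#' exp(-t_p / tau_r) + rhat_min`, clipped to `[rhat_min, 1]`.  The current
#' vessel radius is `rhat * rv0`.
#'
#' @param E Electric field magnitude, V/m.
#' @param t_p Time since the last session start, s.
#' @param vaso Vasoconstriction parameter group (`tau_r`, `m_r`, `rhat_min`).
#' @export
vessel_radius_fraction <- function(E, t_p, vaso) {
  stopifnot(all(t_p >= 0))
  r <- (1 - vaso$rhat_min) * exp(-vaso$m_r * E) * exp(-t_p / vaso$tau_r) +
    vaso$rhat_min
  pmin(pmax(r, vaso$rhat_min), 1)
}

#' Rate of change of the vessel radius
#'
#' Analytic time derivative of the vasoconstriction law scaled by the
#' initial radius; always non-positive.
#'
#' @inheritParams vessel_radius_fraction
#' @param rv0 Initial vessel radius, m.
#' @return `d r_v / d t` in m/s.
#' @export
vessel_radius_rate <- function(E, t_p, vaso, rv0) {
  stopifnot(all(t_p >= 0))
  -rv0 * (1 - vaso$rhat_min) * exp(-vaso$m_r * E) * exp(-t_p / vaso$tau_r) /
    vaso$tau_r
}

#' Radial tissue velocity induced by the moving vessel wall
#'
#' The wall moves with velocity `drv_dt`, the cord outer boundary is fixed,
#' and the velocity interpolates linearly in between:
#' `u_r(r) = (r - R_cord) / (r_v - R_cord) * drv_dt`.
#'
#' @param r Radial coordinates, m (vectorized); must lie in `[r_v, R_cord]`.
#' @param r_v Current vessel radius, m.
#' @param R_cord Cord outer radius, m.
#' @param drv_dt Wall velocity, m/s.
#' @export
radial_tissue_velocity <- function(r, r_v, R_cord, drv_dt) {
  stopifnot(r_v < R_cord)
  if (any(r < r_v - 1e-15 | r > R_cord + 1e-15)) {
    stop("radial coordinate outside [r_v, R_cord]", call. = FALSE)
  }
  (r - R_cord) / (r_v - R_cord) * drv_dt
}

#' Time since the last electroporation session
#'
#' Returns `t` minus the largest session time not exceeding `t`; before the
#' first session (or with an empty schedule) returns `Inf`, so the transient
#' electroporation state evaluates at its fully decayed value.
#'
#' @param t Current time, s.
#' @param session_times Sorted vector of session start times, s.
#' @export
elapsed_since_last_session <- function(t, session_times) {
  stopifnot(t >= 0)
  prior <- session_times[session_times <= t]
  if (length(prior) == 0L) return(Inf)
  t - max(prior)
}

#' Geometry-dependent tissue properties at a constricted vessel radius
#'
#' When the vessel constricts, the annular cord volume grows while the total
#' intracellular volume and membrane area are conserved, so the intracellular
#' fraction and membrane area density dilute as `V(1)/V(rhat)`; the inert
#' solid fraction is preserved and the extracellular fraction takes up the
#' rest.  The effective diffusivity scales with the extracellular porosity:
#' `D = D0 * delta1 / delta1_0`.
#'
#' @param rhat Normalized vessel radius in `(0, 1]`.
#' @param geom Geometry parameter group.
#' @param D0 Reference diffusivity, m^2/s.
#' @return List with `delta1`, `delta2`, `alpha`, `D`.
#' @export
update_geometry_props <- function(rhat, geom, D0) {
  stopifnot(rhat > 0, rhat <= 1)
  vol <- function(rh) (geom$R_cord^2 - (rh * geom$rv0)^2)
  ratio <- vol(1) / vol(rhat)
  delta2 <- geom$delta2_0 * ratio
  alpha <- geom$alpha0 * ratio
  solid <- 1 - geom$delta1_0 - geom$delta2_0
  delta1 <- 1 - delta2 - solid
  if (delta1 <= 0) {
    stop("over-constriction: extracellular fraction would be non-positive",
         call. = FALSE)
  }
  list(delta1 = delta1, delta2 = delta2, alpha = alpha,
       D = D0 * delta1 / geom$delta1_0)
}

#' Electroporation state at a given time
#'
#' Convenience wrapper evaluating the transient permeabilities, the
#' vasoconstriction state and the wall velocity for the protocol in `p` at
#' time `t`.  Vasoconstriction dynamics apply only when a field is actually
#' applied (`E > 0`) and a session has started.
#'
#' @param t Time, s.
#' @param p A `cord_params` object.
#' @return List with `t_p`, `doe_r_tissue`, `doe_r_wall`, `k1`, `kv`, `kvc`,
#'   `rhat`, `r_v`, `drv_dt`.
#' @export
ep_state_at <- function(t, p) {
  E <- p$protocol$E
  t_p <- elapsed_since_last_session(t, p$protocol$session_times)
  dr_t <- doe_r(E, min(t_p, 1e12), p$electrical$tissue)
  dr_w <- doe_r(E, min(t_p, 1e12), p$electrical$vessel_wall)
  tr <- p$transport
  k1 <- dr_t * (tr$k1_max - tr$k1_min) + tr$k1_min
  kv <- dr_w * (tr$kv_max - tr$kv_min) + tr$kv_min
  kvc <- if (isTRUE(p$numerics$kvc_interpolate)) {
    dr_w * (tr$kvc_max - tr$kvc_min) + tr$kvc_min
  } else {
    tr$kvc_min
  }
  vaso_on <- isTRUE(p$numerics$vaso_active) && E > 0 && is.finite(t_p)
  if (vaso_on) {
    rhat <- vessel_radius_fraction(E, t_p, p$vaso)
    drv <- vessel_radius_rate(E, t_p, p$vaso, p$geometry$rv0)
  } else {
    rhat <- 1
    drv <- 0
  }
  list(t_p = t_p, doe_r_tissue = dr_t, doe_r_wall = dr_w,
       k1 = k1, kv = kv, kvc = kvc,
       rhat = rhat, r_v = rhat * p$geometry$rv0, drv_dt = drv)
}
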