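# Bloodstream: porous-tube leakage flow, axial velocity, and the 1-D
# advection-exchange equation for the vessel concentration.

#' Porous-tube decay coefficient
#'
#' Inverse decay length of the pressure/flow solution for laminar flow in a
#' circular tube with a hydraulically permeable wall:
#' `theta* = sqrt(16 mu kvc / r_v^3)`.  (The square root is required by
#' dimensional analysis: the plain quotient has units 1/m^2.)
#'
#' @param mu Plasma viscosity, Pa s.
#' @param kvc Vessel-wall hydraulic permeability, m/(Pa s).
#' @param r_v Vessel radius, m.
#' @return Coefficient in 1/m.
#' @export
theta_star <- function(mu, kvc, r_v) {
  stopifnot(mu > 0, kvc >= 0, r_v > 0)
  sqrt(16 * mu * kvc / r_v^3)
}

#' Porous-tube pressure amplitude
#'
#' `A* = 128 mu Q_inl / (pi r_v^4 theta*)`, in Pa.
#'
#' @inheritParams theta_star
#' @param Q_inl Inlet volumetric flow rate, m^3/s.
#' @param theta Decay coefficient from [theta_star()], 1/m.
#' @export
a_star <- function(mu, Q_inl, r_v, theta) {
  if (theta <= 0) stop("theta* must be positive (impermeable wall is handled upstream)",
                       call. = FALSE)
  128 * mu * Q_inl / (pi * r_v^4 * theta)
}

#' Leakage flow through the vessel wall
#'
#' Cumulative flow lost through the wall between the inlet and axial
#' position `z`, from the porous-tube pressure solution.  `form = "printed"`
#' evaluates the expanded expression term by term; `form = "hyperbolic"`
#' evaluates the algebraically identical
#' `(2 pi r_v kvc / theta) * ((p_inl - p_p) sinh(theta z) -
#' 2 A* (cosh(theta z) - 1))`.  Both are kept so one can serve as an
#' internal identity check on the other.
#'
#' @param z Axial positions, m (vectorized).
#' @inheritParams a_star
#' @param p_inl,p_p Inlet and permeate pressures, Pa.
#' @param form Which algebraic form to evaluate.
#' @return Leakage flow rate in m^3/s (0 at `z = 0`).
#' @export
leakage_flow <- function(z, mu, kvc, r_v, Q_inl, p_inl, p_p,
                         form = c("printed", "hyperbolic")) {
  form <- match.arg(form)
  stopifnot(all(z >= 0))
  if (kvc <= 0 || Q_inl < 0) return(rep(0, length(z)))
  th <- theta_star(mu, kvc, r_v)
  As <- a_star(mu, Q_inl, r_v, th)
  dp <- p_inl - p_p
  if (form == "printed") {
    2 * pi * r_v * kvc * (
      dp * z -
        As / th * (exp(th * z) + exp(-th * z) - 2) -
        dp * (z - (exp(th * z) - exp(-th * z)) / (2 * th))
    )
  } else {
    2 * pi * r_v * kvc / th * (dp * sinh(th * z) - 2 * As * (cosh(th * z) - 1))
  }
}

#' Axial blood velocity with wall leakage
#'
#' `lambda(z) = lambda_inl - Q_leak(z) / (pi r_v^2)`, floored at zero (a
#' warning is issued if leakage would exceed the inflow).
#'
#' @param z Axial positions, m.
#' @param lambda_inl Inlet velocity, m/s.
#' @param Qleak Leakage flow at `z`, m^3/s (same length as `z`).
#' @param r_v Vessel radius, m.
#' @export
axial_velocity <- function(z, lambda_inl, Qleak, r_v) {
  stopifnot(r_v > 0, length(Qleak) == length(z))
  lam <- lambda_inl - Qleak / (pi * r_v^2)
  if (any(lam < 0)) {
    warning("leakage exceeds inflow; axial velocity floored at 0")
    lam <- pmax(lam, 0)
  }
  lam
}

#' Advance the vessel concentration one implicit step
#'
#' Backward-Euler in time, first-order upwind (backward) in `z` update of
#' `dCv/dt = -lambda(z) dCv/dz + rate * (C1_wall - Cv)`, with the inlet node
#' pinned to the current pharmacokinetic value.  `rate` is the volumetric
#' exchange rate in 1/s; the cord solver passes `2 kv / r_v` (wall area per
#' vessel volume times the diffusive wall permeability), which balances the
#' Robin flux received by the tissue.  Being implicit, the update is stable
#' for any time step.
#'
#' @param Cv Current vessel concentrations per axial node, uM.
#' @param C1_wall Tissue concentration at the wall per axial node, uM.
#' @param rate Volumetric exchange rate, 1/s.
#' @param lambda_z Axial velocity per node, m/s.
#' @param dt Time step, s.
#' @param dz Axial grid spacing, m (> 0).
#' @param inlet_value Pharmacokinetic concentration at `z = 0`, uM.
#' @return Updated non-negative concentration vector.
#' @export
advance_vessel_concentration <- function(Cv, C1_wall, rate, lambda_z, dt, dz,
                                         inlet_value) {
  n <- length(Cv)
  stopifnot(dt > 0, length(C1_wall) == n, length(lambda_z) == n)
  if (dz <= 0) stop("dz must be positive", call. = FALSE)
  out <- numeric(n)
  out[1] <- inlet_value
  for (i in seq_len(n)[-1]) {
    adv <- dt * lambda_z[i] / dz
    out[i] <- (Cv[i] + adv * out[i - 1] + dt * rate * C1_wall[i]) /
      (1 + adv + dt * rate)
  }
  pmax(out, 0)
}

#' Build the vessel flow state for a given radius and permeability
#'
#' Evaluates leakage flow and axial velocity on the axial grid.
#'
#' @param z Axial grid, m.
#' @param p A `cord_params` object.
#' @param r_v Current vessel radius, m.
#' @param kvc Current hydraulic wall permeability, m/(Pa s).
#' @return List with `z`, `Qleak`, `lambda`.
#' @export
vessel_flow_state <- function(z, p, r_v = p$geometry$rv0,
                              kvc = p$transport$kvc_min) {
  Qleak <- leakage_flow(z, p$blood$mu, kvc, r_v, p$blood$Q_inl,
                        p$blood$p_inl, p$blood$p_p)
  lam <- axial_velocity(z, p$blood$lambda_inl, Qleak, r_v)
  list(z = z, Qleak = Qleak, lambda = lam)
}
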