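tissue <- default_params()$electrical$tissue
wall <- default_params()$electrical$vessel_wall
vaso <- default_params()$vaso

test_that("conductivity sigmoid hits its midpoint, floor and ceiling", {
  a_star <- (tissue$E_rev + tissue$E_irrev) / 2
  # at the midpoint the sigmoid contributes 1/(1 + alpha*) of the range
  expect_equal(effective_conductivity(a_star, tissue),
               tissue$sigma_min +
                 (tissue$sigma_max - tissue$sigma_min) / (1 + tissue$alpha_star),
               tolerance = 1e-12)
  expect_lt(abs(effective_conductivity(0, tissue) - tissue$sigma_min), 1e-7)
  expect_equal(effective_conductivity(1e9, tissue), tissue$sigma_max,
               tolerance = 1e-9)
})

test_that("degrees of electroporation match independent scalar evaluation", {
  expect_equal(doe(58e3, tissue), 1 / 11, tolerance = 1e-10)
  expect_lt(doe(0, tissue), 1e-6)
  # at the irreversible threshold: 1/(1 + alpha* exp(-beta*/2))
  expect_equal(doe(70e3, tissue), 1 / (1 + 10 * exp(-4)), tolerance = 1e-10)
  expect_equal(die(46e3, tissue), 0)
  expect_equal(die(70e3, tissue), 0, tolerance = 1e-12)
  expect_gt(die(140e3, tissue), 0)
  expect_lte(die(140e3, tissue), 1)
})

test_that("transient degree composes its limits", {
  for (E in c(30e3, 46e3, 58e3)) {
    expect_equal(doe_r(E, 0, tissue), doe(E, tissue))
    expect_equal(doe_r(E, tissue$tau_i, tissue), doe(E, tissue) * exp(-1),
                 tolerance = 1e-12)           # DIE = 0 below threshold
  }
  expect_equal(doe_r(46e3, 100, tissue), doe(46e3, tissue) * exp(-1),
               tolerance = 1e-12)
  expect_equal(doe_r(50e3, Inf, tissue), 0, tolerance = 1e-15)
})

test_that("monotonicity and bounds hold across the field range", {
  # above ~120 kV/m the tissue sigmoid saturates below double resolution,
  # so strict monotonicity is asserted on the resolvable range
  E <- seq(0, 120e3, length.out = 400)
  s <- effective_conductivity(E, tissue)
  expect_true(all(diff(s) > 0))
  d <- doe(E, tissue)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0 & d < 1))
  # DOE_R non-increasing in t_p below the irreversible threshold
  tp <- seq(0, 1000, by = 5)
  dr <- doe_r(46e3, tp, tissue)
  expect_true(all(diff(dr) <= 0))
  # permeability within bounds for both tissue and wall parameter sets
  for (el in list(tissue, wall)) {
    k <- ep_permeability(runif(50, 0, 3e5), runif(50, 0, 1e4), 1e-9, 1e-6, el)
    expect_true(all(k >= 1e-9 - 1e-20 & k <= 1e-6 + 1e-20))
  }
  expect_equal(ep_permeability(0, 0, 1e-9, 1e-6, tissue), 1e-9,
               tolerance = 1e-3)
})

test_that("vasoconstriction law and its rate agree with central differences", {
  expect_equal(vessel_radius_fraction(0, 0, vaso), 1)
  expect_equal(vessel_radius_fraction(46e3, 1e9, vaso), 0.25)
  expect_equal(vessel_radius_fraction(46e3, 0, vaso),
               0.75 * exp(-6.49e-5 * 46e3) + 0.25, tolerance = 1e-12)
  expect_equal(vessel_radius_rate(0, 0, vaso, 16e-6), -16e-6 * 0.75 / 330)
  expect_equal(vessel_radius_rate(46e3, 1e9, vaso, 16e-6), 0, tolerance = 1e-18)
  h <- 1e-3
  for (E in c(0, 1e3, 46e3)) for (tp in c(10, 200, 800)) {
    num <- 16e-6 * (vessel_radius_fraction(E, tp + h, vaso) -
                    vessel_radius_fraction(E, tp - h, vaso)) / (2 * h)
    expect_equal(vessel_radius_rate(E, tp, vaso, 16e-6), num,
                 tolerance = 1e-6)
  }
})

test_that("radial tissue velocity interpolates linearly between wall and rim", {
  rv <- 12e-6; R <- 200e-6; drv <- -3e-9
  expect_equal(radial_tissue_velocity(R, rv, R, drv), 0)
  expect_equal(radial_tissue_velocity(rv, rv, R, drv), drv)
  expect_equal(radial_tissue_velocity((rv + R) / 2, rv, R, drv), drv / 2)
  expect_error(radial_tissue_velocity(1e-6, rv, R, drv), "outside")
})

test_that("elapsed time since last session follows the schedule", {
  st <- c(0, 4 * 3600)
  expect_equal(elapsed_since_last_session(2 * 3600, st), 7200)
  expect_equal(elapsed_since_last_session(4 * 3600, st), 0)
  expect_equal(elapsed_since_last_session(10, numeric(0)), Inf)
})

test_that("geometry update conserves intracellular volume and membrane area", {
  g <- default_params()$geometry
  D0 <- 5e-11
  id <- update_geometry_props(1, g, D0)
  expect_equal(id$delta1, g$delta1_0)
  expect_equal(id$delta2, g$delta2_0)
  expect_equal(id$alpha, g$alpha0)
  expect_equal(id$D, D0)
  q <- update_geometry_props(0.25, g, D0)
  vol <- function(rh) g$R_cord^2 - (rh * g$rv0)^2
  expect_equal(q$delta2, g$delta2_0 * vol(1) / vol(0.25), tolerance = 1e-12)
  # conserved products delta2*V and alpha*V across arbitrary rhat
  for (rh in c(0.9, 0.5, 0.3)) {
    u <- update_geometry_props(rh, g, D0)
    expect_equal(u$delta2 * vol(rh), g$delta2_0 * vol(1), tolerance = 1e-12)
    expect_equal(u$alpha * vol(rh), g$alpha0 * vol(1), tolerance = 1e-12)
    expect_equal(u$D, D0 * u$delta1 / g$delta1_0)
  }
})
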