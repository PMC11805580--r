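p0 <- default_params()

test_that("porous-tube coefficients follow their scaling laws", {
  th <- theta_star(1.24e-3, 2.7e-12, 16e-6)
  expect_equal(th, sqrt(16 * 1.24e-3 * 2.7e-12 / (16e-6)^3), tolerance = 1e-12)
  expect_equal(th, 3.61637, tolerance = 1e-5)     # frozen scalar arithmetic
  expect_equal(theta_star(1.24e-3, 0, 16e-6), 0)
  expect_equal(theta_star(1.24e-3, 4 * 2.7e-12, 16e-6), 2 * th)
  As <- a_star(1.24e-3, p0$blood$Q_inl, 16e-6, th)
  expect_equal(a_star(1.24e-3, 2 * p0$blood$Q_inl, 16e-6, th), 2 * As)
  expect_equal(a_star(1.24e-3, 0, 16e-6, th), 0)
  expect_equal(As, 128 * 1.24e-3 * p0$blood$Q_inl / (pi * (16e-6)^4 * th))
  expect_error(a_star(1.24e-3, 1e-13, 16e-6, 0), "positive")
})

test_that("leakage flow: printed and hyperbolic forms are identical", {
  z <- seq(0, 400e-6, length.out = 41)
  q1 <- leakage_flow(z, 1.24e-3, 2.7e-12, 16e-6, p0$blood$Q_inl,
                     p0$blood$p_inl, 0, form = "printed")
  q2 <- leakage_flow(z, 1.24e-3, 2.7e-12, 16e-6, p0$blood$Q_inl,
                     p0$blood$p_inl, 0, form = "hyperbolic")
  expect_equal(q1[1], 0)
  expect_lt(max(abs(q1 - q2)) / max(abs(q1)), 1e-12)
  expect_true(all(diff(q1) > 0))                  # cumulative loss grows
  # no driving pressure and no inflow -> no leakage
  q0 <- leakage_flow(z, 1.24e-3, 2.7e-12, 16e-6, 0, 1e4, 1e4)
  expect_true(all(abs(q0) < 1e-25))
})

test_that("axial velocity starts at the inlet value and never goes negative", {
  z <- seq(0, 400e-6, length.out = 21)
  q <- leakage_flow(z, 1.24e-3, 2.7e-12, 16e-6, p0$blood$Q_inl,
                    p0$blood$p_inl, 0)
  lam <- axial_velocity(z, 1e-4, q, 16e-6)
  expect_equal(lam[1], 1e-4)
  expect_true(all(diff(lam) < 0))                 # monotone loss for p_inl > p_p
  # full absorption floors at zero with a warning
  expect_warning(
    lam0 <- axial_velocity(0, 1e-4, pi * (16e-6)^2 * 2e-4, 16e-6),
    "floored")
  expect_equal(lam0, 0)
})

test_that("vessel advection-exchange step honours its limits", {
  n <- 8
  Cv <- rep(3, n)
  # stationary: no velocity, no exchange
  out <- advance_vessel_concentration(Cv, rep(0, n), 0, rep(0, n), 10, 1e-5, 3)
  expect_equal(out, Cv)
  # pure advection of a uniform field with matching inlet is invariant
  out <- advance_vessel_concentration(Cv, rep(0, n), 0, rep(1e-3, n), 10, 1e-5, 3)
  expect_equal(out, Cv, tolerance = 1e-12)
  # exchange-only node relaxes exponentially toward the tissue value
  rate <- 0.05; dt <- 0.01; c1 <- 2
  cv <- 0
  for (k in 1:400) {
    cv <- advance_vessel_concentration(c(0, cv), c(c1, c1), rate,
                                       c(0, 0), dt, 1e-5, 0)[2]
  }
  exact <- c1 * (1 - exp(-rate * 4))
  expect_equal(cv, exact, tolerance = 5e-3)       # O(dt) accuracy
  expect_error(advance_vessel_concentration(Cv, rep(0, n), 0, rep(0, n),
                                            10, 0, 0), "dz")
})

test_that("exchange sign follows the concentration difference at every node", {
  n <- 6
  Cv <- seq(1, 2, length.out = n)
  C1 <- rev(Cv)
  out <- advance_vessel_concentration(Cv, C1, 0.1, rep(0, n), 1, 1e-5, Cv[1])
  expect_true(all(sign(out[-1] - Cv[-1]) == sign(C1[-1] - Cv[-1])))
})

test_that("with a sealed wall and constant inlet the line converges to the inlet", {
  n <- 10
  Cv <- rep(0, n)
  for (k in 1:2000) {
    Cv <- advance_vessel_concentration(Cv, rep(0, n), 0, rep(1e-3, n), 1,
                                       400e-6 / (n - 1), 5)
  }
  expect_equal(Cv, rep(5, n), tolerance = 1e-9)
})
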