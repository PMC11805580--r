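fake_snap <- function(C1, C2, C3, r = seq(16e-6, 200e-6, length.out = nrow(C1)),
                      z = seq(0, 400e-6, length.out = ncol(C1))) {
  list(t = 3600, r = r, z = z, C1 = C1, C2 = C2, C3 = C3)
}

test_that("ratio fields guard their denominators", {
  m <- matrix(2, 4, 3)
  rt <- concentration_ratios(fake_snap(m, m, 0 * m))
  expect_true(all(rt$r21 == 1))
  expect_true(all(rt$r31 == 0))
  z <- concentration_ratios(fake_snap(0 * m, 0 * m, 0 * m))
  expect_true(all(is.na(z$r21)))
  expect_true(all(is.na(z$r32)))
})

test_that("uniformity range is zero for constant fields and finds its extremes", {
  traj <- smoke_mpk_traj()
  u <- uniformity_range(traj, "C3", times_h = 1)
  expect_gte(u$range, 0)
  expect_equal(u$max - u$min, u$range)
  # C3 is maximal at the vessel wall in this regime
  expect_equal(u$r_max, traj$snapshots[[2]]$r[1])
  frozen <- traj
  frozen$snapshots <- lapply(frozen$snapshots, function(s) { s$C3[] <- 7; s })
  expect_equal(uniformity_range(frozen, "C3", times_h = 1)$range, 0)
  # an everywhere-undefined ratio errors out
  empty <- traj
  empty$snapshots <- lapply(empty$snapshots, function(s) {
    s$C1[] <- 0; s$C2[] <- 0; s$C3[] <- 0; s })
  expect_error(uniformity_range(empty, "C2/C1", times_h = 1), "undefined")
})

test_that("axial uniformity is zero for z-invariant fields and exact for f(z)", {
  traj <- smoke_mpk_traj()
  s <- traj$snapshots[[2]]
  mod <- traj
  mod$snapshots <- lapply(mod$snapshots, function(s) {
    s$C3 <- matrix(rep(s$r, length(s$z)), length(s$r), length(s$z)); s })
  expect_equal(axial_uniformity(mod, "C3", 1)$axial_spread, 0)
  fz <- traj
  fz$snapshots <- lapply(fz$snapshots, function(s) {
    s$C3 <- matrix(rep(s$z * 1e4, each = length(s$r)), length(s$r), length(s$z)); s })
  expect_equal(axial_uniformity(fz, "C3", 1)$axial_spread,
               (max(s$z) - min(s$z)) * 1e4, tolerance = 1e-12)
})

test_that("crossing detection interpolates linearly and handles no-crossing", {
  ser <- tibble::tibble(t_h = c(0.2, 0.4), ratio = c(2, 0.5))
  ev <- reverse_diffusion_time(ser)
  expect_equal(ev$t_cross_h, 0.2 + (2 - 1) / (2 - 0.5) * 0.2, tolerance = 1e-12)
  none <- tibble::tibble(t_h = c(0.1, 0.2, 0.3), ratio = c(5, 4, 3))
  expect_equal(nrow(reverse_diffusion_time(none)), 0)
  expect_error(reverse_diffusion_time(tibble::tibble(t_h = 1, ratio = 2)),
               "two defined")
})

test_that("the transvascular series is undefined before any drug reaches the wall", {
  traj <- smoke_mpk_traj()
  ser <- transvascular_ratio_series(traj)
  expect_true(is.na(ser$ratio[1]) || ser$ratio[1] > 1)
  expect_true(any(is.finite(ser$ratio)))
  # early samples show extravasation (ratio above 1)
  early <- ser$ratio[is.finite(ser$ratio)][1]
  expect_gt(early, 1)
})

test_that("exposures integrate trapezoidally and scale linearly", {
  traj <- smoke_mpk_traj()
  zero <- traj
  zero$snapshots <- lapply(zero$snapshots, function(s) {
    s$C1[] <- 0; s$C2[] <- 0; s$C3[] <- 0; s })
  e0 <- exposures(zero)
  expect_true(all(e0$C1exp == 0))
  const <- traj
  const$snapshots <- lapply(const$snapshots, function(s) { s$C1[] <- 3; s })
  Th <- max(traj$times) / 3600
  expect_equal(unique(exposures(const)$C1exp), 3 * Th, tolerance = 1e-12)
  e1 <- exposures(traj)
  doubled <- traj
  doubled$snapshots <- lapply(doubled$snapshots, function(s) {
    s$C1 <- 2 * s$C1; s$C2 <- 2 * s$C2; s$C3 <- 2 * s$C3; s })
  e2 <- exposures(doubled)
  expect_equal(e2$C3exp, 2 * e1$C3exp, tolerance = 1e-12)
  # monotone in the horizon for non-negative fields
  eshort <- exposures(traj, T_h = 0.5)
  expect_true(all(e1$C1exp - eshort$C1exp >= -1e-15))
})
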