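test_that("spatial operator: constants are flux-free, r^2 gives the exact cylindrical Laplacian", {
  r <- seq(16e-6, 200e-6, length.out = 31)
  z <- seq(0, 400e-6, length.out = 9)
  D <- 5e-11
  Cu <- matrix(2.5, 31, 9)
  out <- spatial_operator(Cu, r, z, D)
  expect_lt(max(abs(out[2:30, 2:8])), 1e-20)
  # C = r^2: finite-volume face gradients are exact, so interior nodes give 4D
  Cr2 <- matrix(rep(r^2, 9), 31, 9)
  out <- spatial_operator(Cr2, r, z, D)
  expect_equal(out[2:30, 2:8], matrix(4 * D, 29, 7), tolerance = 1e-10)
  # inward advection of an increasing profile contributes positively
  adv <- spatial_operator(Cr2, r, z, 0, u_r = -1e-8)
  expect_true(all(adv[2:30, 2:8] > 0))
  expect_error(spatial_operator(Cu, rev(r), z, D), "increasing")
})

test_that("Robin wall: sealed equilibrium is exact and the steady profile matches the Bessel solution", {
  p <- cord_params(numerics = list(n_r = 101, n_z = 2, dt = 1,
                                   report_times = c(0, 10)))
  state <- new_cord_state(p)
  kv <- 2.8e-6; Cv <- 1
  # k1 = 0: steady state with an open wall is uniform at the vessel value
  sys <- tumorcord:::build_c1_matrix(state, p, dt = 1e15, k1 = 0, kv = kv,
                                     u_r = rep(0, 101))
  b <- matrix(0, 101, 2); b[1, ] <- sys$robin * Cv
  x <- matrix(as.numeric(Matrix::solve(sys$A, as.vector(b))), 101, 2)
  expect_equal(x, matrix(Cv, 101, 2), tolerance = 1e-10)
  # k1 > 0: compare with C(r) = A I0(qr) + B K0(qr), zero flux at R_cord,
  # Robin at r_v
  k1 <- 1e-8
  sys <- tumorcord:::build_c1_matrix(state, p, dt = 1e15, k1 = k1, kv = kv,
                                     u_r = rep(0, 101))
  b <- matrix(0, 101, 2); b[1, ] <- sys$robin * Cv
  x <- matrix(as.numeric(Matrix::solve(sys$A, as.vector(b))), 101, 2)
  g <- p$geometry; D <- p$transport$D0
  q <- sqrt(g$alpha0 * k1 / D)
  rv <- g$rv0; R <- g$R_cord
  Bfac <- besselI(q * R, 1) / besselK(q * R, 1)
  # Robin closure: -D C'(r_v) = kv (Cv - C(r_v)) fixes the amplitude
  A <- kv * Cv / (-D * q * (besselI(q * rv, 1) - Bfac * besselK(q * rv, 1)) +
                  kv * (besselI(q * rv, 0) + Bfac * besselK(q * rv, 0)))
  exact <- A * (besselI(q * state$r, 0) + Bfac * besselK(q * state$r, 0))
  expect_lt(max(abs(x[, 1] - exact)) / max(exact), 2e-3)
})

test_that("fully decoupled or balanced states do not drift", {
  p <- tiny_params()
  state <- new_cord_state(p)
  state$C1[] <- 4; state$C2[] <- 4; state$C3[] <- 0
  vessel <- vessel_flow_state(state$z, p)
  vessel$Cv <- rep(0, length(state$z))
  # k1 = 0, kv = 0, binding off: nothing can move
  p0 <- cord_params(base = p, transport = list(k2 = 1e-30, k_minus2 = 1e-30))
  res <- cord_step(state, vessel, p0, dt = 50,
                   ep = list(k1 = 0, kv = 0), inlet_value = 0)
  expect_equal(res$state$C1, state$C1, tolerance = 1e-12)
  expect_equal(res$state$C2, state$C2, tolerance = 1e-12)
  expect_equal(res$state$C3, state$C3, tolerance = 1e-12)
  # k2 = k_-2 = 0 with C1 = C2 uniform: the transmembrane term vanishes
  res2 <- cord_step(state, vessel, p0, dt = 50,
                    ep = list(k1 = 1e-7, kv = 0), inlet_value = 0)
  expect_equal(res2$state$C1, state$C1, tolerance = 1e-10)
  expect_equal(res2$state$C2, state$C2, tolerance = 1e-10)
})

test_that("spatially uniform dynamics match an independent stiff ODE solution", {
  skip_if_not_installed("deSolve")
  p <- cord_params(numerics = list(n_r = 3, n_z = 2, dt = 0.5,
                                   report_times = c(0, 2000)),
                   protocol = list(T_chemo = 2000))
  k1 <- 1e-8
  tr <- p$transport
  state <- new_cord_state(p)
  state$C1[] <- 10
  vessel <- vessel_flow_state(state$z, p)
  vessel$Cv <- rep(0, length(state$z))
  for (k in seq_len(2000 / 0.5)) {
    res <- cord_step(state, vessel, p, dt = 0.5,
                     ep = list(k1 = k1, kv = 0), inlet_value = 0)
    state <- res$state; vessel <- res$vessel
  }
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      ak1 <- p$geometry$alpha0 * k1
      d1 <- p$geometry$delta1_0; d2 <- p$geometry$delta2_0
      bind <- tr$k2 * C2 * (tr$C0 - C3) - tr$k_minus2 * C3
      list(c(C1 = ak1 * (C2 - C1) / d1,
             C2 = ak1 * (C1 - C2) / d2 - bind,
             C3 = bind))
    })
  }
  sol <- deSolve::lsoda(c(C1 = 10, C2 = 0, C3 = 0), c(0, 2000), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  final <- sol[2, -1]
  expect_equal(state$C1[1, 1], unname(final["C1"]), tolerance = 2e-2)
  expect_equal(state$C2[1, 1], unname(final["C2"]), tolerance = 2e-2)
  expect_equal(state$C3[1, 1], unname(final["C3"]), tolerance = 2e-2)
  # fields stay spatially uniform
  expect_lt(diff(range(state$C1)), 1e-10 * max(state$C1))
})

test_that("remeshing preserves uniform fields and the intracellular amount", {
  p <- tiny_params()
  state <- new_cord_state(p)
  state$C1[] <- 1; state$C2[] <- 2; state$C3[] <- 3
  g <- p$geometry
  vol <- function(rh) (g$R_cord^2 - (rh * g$rv0)^2)
  amount0 <- state$delta2 * vol(1) * (state$C2[1, 1] + state$C3[1, 1])
  out <- remesh_cord(state, 0.6, p)
  expect_equal(out$r[1], 0.6 * g$rv0)
  expect_lt(diff(range(out$C2)), 1e-14)
  amount1 <- out$delta2 * vol(0.6) * (out$C2[1, 1] + out$C3[1, 1])
  expect_equal(amount1, amount0, tolerance = 1e-10)
  # rhat = 1 leaves the grid where it is
  same <- remesh_cord(state, 1, p)
  expect_equal(same$r, state$r)
  expect_equal(same$C1, state$C1)
})

test_that("total mass has its closed forms and scales linearly", {
  p <- tiny_params()
  state <- new_cord_state(p)
  expect_equal(total_mass(state), 0)
  state$C1[] <- 3
  g <- p$geometry
  V <- pi * (g$R_cord^2 - g$rv0^2) * g$L_cord
  expect_equal(total_mass(state), g$delta1_0 * 3 * V * 1e-3, tolerance = 1e-12)
  state$C2[] <- 1; state$C3[] <- 2
  m1 <- total_mass(state)
  state$C1[] <- 6; state$C2[] <- 2; state$C3[] <- 4
  expect_equal(total_mass(state), 2 * m1, tolerance = 1e-12)
})

test_that("conditioning scale factors do not change the converged fields", {
  run_scaled <- function(S_L, S_T, S_C) {
    p <- cord_params(numerics = list(n_r = 9, n_z = 3, dt = 30,
                                     S_L = S_L, S_T = S_T, S_C = S_C,
                                     report_times = c(0, 900)),
                     protocol = list(T_chemo = 900),
                     pk = list(kind = "MPK"))
    run_cord_simulation(p)
  }
  a <- run_scaled(1, 1, 1)
  b <- run_scaled(1e3, 10, 1e6)
  sa <- a$snapshots[[length(a$snapshots)]]
  sb <- b$snapshots[[length(b$snapshots)]]
  for (f in c("C1", "C2", "C3")) {
    expect_lt(max(abs(sa[[f]] - sb[[f]])) / max(abs(sa[[f]])), 1e-9)
  }
})

test_that("a full run is deterministic and starts from an all-zero snapshot", {
  t1 <- smoke_mpk_traj()
  p <- quickrun_config("E0_L0.0001_MPK", "smoke")
  t2 <- run_cord_simulation(p)
  expect_equal(t1$snapshots[[1]]$C1, t2$snapshots[[1]]$C1)
  expect_equal(t1$times[1], 0)
  expect_true(all(t1$snapshots[[1]]$C1 == 0))
  expect_true(all(diff(t1$times) > 0))
  last1 <- t1$snapshots[[length(t1$snapshots)]]
  last2 <- t2$snapshots[[length(t2$snapshots)]]
  expect_identical(last1$C3, last2$C3)
})
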