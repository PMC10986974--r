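test_that("laplacian matches its stencil identities and the loop oracle", {
  expect_equal(laplacian(matrix(7, 5, 5), 0.1), matrix(0, 5, 5))

  # exact on quadratics at interior nodes
  x <- seq(-1, 1, by = 0.1)
  f <- outer(x, x, function(a, b) a^2 + b^2)
  lap <- laplacian(f, 0.1)
  inner <- lap[2:20, 2:20]
  expect_equal(inner, matrix(4, 19, 19), tolerance = 1e-9)

  set.seed(42)
  C <- matrix(rnorm(49), 7, 7)
  expect_equal(laplacian(C, 0.3), oracle_laplacian(C, 0.3),
               tolerance = 1e-13)

  expect_error(laplacian(matrix(0, 2, 2), 0.1), "3x3")
})

test_that("upwind advection is exact on linear fields and matches the oracle", {
  x <- seq(-1, 1, by = 0.1)
  Cx <- matrix(x, 21, 21)

  expect_equal(advection(Cx, c(0, 0), 0.1), matrix(0, 21, 21))

  adv <- advection(Cx, c(1, 0), 0.1)
  expect_equal(adv[2:20, ], matrix(1, 19, 21), tolerance = 1e-9)

  set.seed(43)
  C <- matrix(rnorm(64), 8, 8)
  for (nu in list(c(1, 0), c(-0.5, 0.25), c(0.3, -0.8))) {
    expect_equal(advection(C, nu, 0.2), oracle_advection(C, nu, 0.2),
                 tolerance = 1e-13)
  }
})

test_that("stability check reports the correct admissibility margins", {
  p <- model_params()
  ok <- stability_check(p, solver_settings(dt = 1e-3), dx = 0.1)
  expect_true(ok$ok)
  expect_equal(ok$margins$value[ok$margins$condition == "diffusion"], 0.4)

  bad <- stability_check(p, solver_settings(dt = 5e-3), dx = 0.1)
  expect_false(bad$ok)
  expect_equal(bad$margins$value[bad$margins$condition == "diffusion"], 2.0)

  still <- stability_check(model_params(D = 0), solver_settings(dt = 1e-3),
                           dx = 0.1)
  expect_true(still$ok)
})

test_that("a single Euler step from the strip matches the hand evaluation", {
  g <- tiny_grid()
  ic <- strip_initial_condition(g, n = 5)      # halfwidth 0.2
  p <- model_params(gamma = 1.2, beta_allee = 0.9)
  s <- solver_settings(dt = 1e-3, t_end = 1e-3, record_interval = 1e-3)
  st <- step_state(ic, p, s)

  # C was zero, so no diffusion: C grows only where the source acts
  strip <- abs(g$x) <= 0.2 + 1e-12
  expect_equal(st$C[strip, ], matrix(1.2 / (0.9^2 + 1) * 1e-3,
                                     sum(strip), g$n), tolerance = 1e-15)
  expect_equal(st$C[!strip, ], matrix(0, sum(!strip), g$n))

  # A update: on-strip logistic balance is zero (rho0 = kappa, A = 1)
  expect_equal(st$A[strip, ], matrix(1, sum(strip), g$n))
  expect_equal(st$t, 1e-3)

  # all-zero state is a fixed point
  z <- strip_initial_condition(g, n = 5)
  z$A[] <- 0
  stz <- step_state(z, p, s)
  expect_equal(max(abs(stz$A)), 0)
  expect_equal(max(abs(stz$C)), 0)
})

test_that("the compiled integrator reproduces repeated R reference steps", {
  g <- tiny_grid()
  ic <- strip_initial_condition(g, n = 5)
  set.seed(3)
  p <- model_params(rho0 = generate_field(dist_normal(1, 1), g$n, seed = 3),
                    gamma = 1.1, beta_allee = 0.8, nu = c(0.4, -0.2))
  s <- solver_settings(dt = 1e-3, t_end = 0.05, record_interval = 0.05)

  run <- simulate_invasion(p, ic, s)

  st <- ic
  for (k in 1:50) st <- step_state(st, p, s)
  expect_equal(run$state$A, st$A, tolerance = 1e-13)
  expect_equal(run$state$C, st$C, tolerance = 1e-13)
})

test_that("simulation is deterministic and refuses unstable timesteps", {
  g <- tiny_grid()
  ic <- strip_initial_condition(g, n = 5)
  p <- model_params()
  s <- tiny_settings(t_end = 0.5)

  r1 <- simulate_invasion(p, ic, s)
  r2 <- simulate_invasion(p, ic, s)
  expect_identical(r1$state$A, r2$state$A)
  expect_identical(r1$trace, r2$trace)

  expect_error(
    simulate_invasion(p, ic, solver_settings(dt = 5e-3, t_end = 0.5,
                                             record_interval = 5e-3)),
    "stability")
  # overriding the guard leads to detected blow-up, not silent garbage
  expect_error(
    simulate_invasion(p, ic, solver_settings(dt = 1e-2, t_end = 1,
                                             record_interval = 1e-2),
                      check_stability = FALSE),
    "non-finite")
})

test_that("homogeneous runs are exactly y-invariant and match the 1D oracle", {
  g <- grid_spec(L = 2, dx = 0.1)
  ic <- strip_initial_condition(g, n = 10)     # halfwidth 0.2
  p <- model_params()
  s <- solver_settings(dt = 1e-3, t_end = 1, record_interval = 0.1,
                       snapshot_times = c(0.5, 1))
  run <- simulate_invasion(p, ic, s)

  for (st in c(run$snapshots, list(run$state))) {
    expect_lt(max(abs(st$A - st$A[, 1])), 1e-10)
    expect_lt(max(abs(st$C - st$C[, 1])), 1e-10)
  }

  ref <- oracle_1d(g$x, g$dx, 1e-3, 1000, eps = 1e-2, rho0 = 1, kappa = 1,
                   gam = 1, D = 1, beta = 1, strip_halfwidth = 0.2)
  expect_lt(max(abs(run$state$A[, 1] - ref$A)), 1e-8)
  expect_lt(max(abs(run$state$C[, 1] - ref$C)), 1e-8)
})

test_that("states stay non-negative and bounded on heterogeneous landscapes", {
  g <- grid_spec(L = 2, dx = 0.1)
  ic <- strip_initial_condition(g, n = 10)
  rho0 <- generate_field(dist_normal(1, 1), g$n, seed = 10)
  expect_lt(min(rho0), 0)  # the landscape genuinely has hostile patches
  p <- model_params(rho0 = rho0)
  run <- simulate_invasion(p, ic, solver_settings(dt = 1e-3, t_end = 2,
                                                  record_interval = 0.1))
  expect_gte(run$min_A, 0)
  expect_gte(run$min_C, 0)
  # A bounded near max carrying capacity, C by max fecundity (5% slack)
  expect_lte(max(run$state$A), max(1, max(rho0)) * 1.05)
  expect_lte(max(run$state$C), 1 * 1.05)
})

test_that("t_end = 0 returns the initial condition with a single record", {
  g <- tiny_grid()
  ic <- strip_initial_condition(g, n = 5)
  run <- simulate_invasion(model_params(), ic,
                           solver_settings(t_end = 0))
  expect_equal(nrow(run$trace), 1L)
  expect_equal(run$trace$t, 0)
  expect_equal(run$state$A, ic$A)
  expect_equal(run$trace$mean_distance, 0)
})
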