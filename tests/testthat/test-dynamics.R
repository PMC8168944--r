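test_that("vector field matches hand-evaluated values", {
  # origin is a fixed point: every term carries a factor z
  dp <- dynamics_params(k = c(0.3, 0.2, 0.4, 0.1),
                        alpha = matrix(runif(16, -0.1, 0.1), 4, 4))
  expect_equal(unname(vector_field(rep(0, 4), dp)), rep(0, 4))

  # uncoupled logistic maximum k z (1 - z) at z = 1/2
  dp1 <- dynamics_params(k = 1)
  expect_equal(unname(vector_field(0.5, dp1)), 0.25)

  # two coordinates with a single coupling, evaluated by hand
  dp2 <- dynamics_params(k = c(1, 1),
                         alpha = matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(vector_field(c(0.4, 0.2), dp2)), c(0.24, 0.36))
})

test_that("per-coordinate and matrix forms of the field agree", {
  set.seed(11)
  for (i in 1:1000) {
    M <- sample(2:6, 1)
    dp <- dynamics_params(k = runif(M, 0.05, 1),
                          alpha = matrix(rnorm(M * M, 0, 0.3), M, M))
    z <- rnorm(M, 0.5, 0.6)
    expect_lt(max(abs(vector_field(z, dp) - vector_field_matrix(z, dp))),
              1e-12)
  }
})

test_that("dimension mismatches are rejected", {
  dp <- dynamics_params(k = c(0.3, 0.2))
  expect_error(vector_field(c(0.1, 0.2, 0.3), dp), "dimension")
  expect_error(integrate_trajectory(c(0.1, NA), 0, 0:3, dp), "finite")
})

test_that("uncoupled integration matches the logistic closed form", {
  dp <- dynamics_params(k = 1)
  tg <- seq(-5, 5, by = 0.25)
  tr <- integrate_trajectory(0.1, 0, tg, dp, step = 0.05)
  closed <- 0.1 * exp(tg) / (1 + 0.1 * (exp(tg) - 1))
  expect_lt(max(abs(tr$states[, 1] - closed) / closed), 1e-6)
})

test_that("zero field gives a constant trajectory", {
  dp <- dynamics_params(k = c(0, 0, 0))
  tr <- integrate_trajectory(c(0.2, 0.5, 0.9), 0, seq(-10, 10), dp)
  for (j in 1:3) expect_equal(unname(tr$states[, j]),
                              rep(c(0.2, 0.5, 0.9)[j], 21))
})

test_that("forward-then-backward integration returns to the start", {
  cfg <- canonical_config()
  dp <- cfg$dynamics
  z0 <- c(0.3, 0.2, 0.15, 0.1)
  fwd <- integrate_trajectory(z0, 0, c(0, 4), dp)
  back <- integrate_trajectory(fwd$states[2, ], 4, c(0, 4), dp)
  expect_lt(max(abs(back$states[1, ] - z0)), 1e-6)
})

test_that("halving the integrator step changes states below tolerance", {
  cfg <- canonical_config()
  tg <- seq(-5, 15, by = 1)
  a <- integrate_trajectory(cfg$anchor_state, 0, tg, cfg$dynamics, step = 0.1)
  b <- integrate_trajectory(cfg$anchor_state, 0, tg, cfg$dynamics, step = 0.05)
  expect_lt(max(abs(a$states - b$states)), 1e-6)
})

test_that("integration agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  cfg <- canonical_config()
  dp <- cfg$dynamics
  tg <- seq(0, 20, by = 0.5)
  mine <- integrate_trajectory(cfg$anchor_state, 0, tg, dp)
  ode_fun <- function(t, y, parms) list(unname(vector_field(y, dp)))
  ref <- deSolve::lsoda(cfg$anchor_state, tg, ode_fun, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(mine$states - ref[, -1])), 1e-6)
})

test_that("divergent integration names the blow-up time", {
  dp <- dynamics_params(k = 2)
  expect_error(integrate_trajectory(-0.5, 0, c(0, 50), dp),
               "diverged.*t = ")
})

test_that("intervention field semantics follow the damping matrix", {
  cfg <- canonical_config()
  dp <- cfg$dynamics
  z <- c(0.4, 0.3, 0.2, 0.1)

  # identity damping leaves the field untouched at any time
  iv1 <- intervention_spec(rep(1, 4), start_time = -10)
  expect_equal(apply_intervention_field(z, dp, iv1, 0), vector_field(z, dp))

  # full amyloid arrest zeroes exactly the amyloid component
  iv0 <- intervention_spec(c(0, 1, 1, 1), start_time = -10)
  f <- apply_intervention_field(z, dp, iv0, 0)
  expect_identical(unname(f[1]), 0)
  expect_equal(f[-1], vector_field(z, dp)[-1])

  # outside the active window the field is unmodified
  expect_equal(apply_intervention_field(z, dp, iv0, -11), vector_field(z, dp))

  # elementwise product with (0.5, 1) on a 2-D system
  dp2 <- dynamics_params(k = c(1, 1),
                         alpha = matrix(c(0, 0.3, 0.2, 0), 2, 2, byrow = TRUE))
  iv5 <- intervention_spec(c(0.5, 1), start_time = 0)
  expect_equal(apply_intervention_field(c(0.4, 0.2), dp2, iv5, 1),
               c(0.5, 1) * vector_field(c(0.4, 0.2), dp2))
})

test_that("gamma = 0 freezes the damped coordinate during integration", {
  cfg <- canonical_config()
  iv <- intervention_spec(c(0, 1, 1, 1), start_time = 2)
  tr <- integrate_trajectory(cfg$anchor_state, 0, seq(0, 12, by = 0.5),
                             cfg$dynamics, intervention = iv)
  frozen <- tr$states[tr$times >= 2, 1]
  expect_lt(max(abs(frozen - frozen[1])), 1e-9)
  # the other coordinates keep moving (couplings from amy stay active)
  expect_gt(diff(range(tr$states[tr$times >= 2, 2])), 0.01)
})

test_that("stronger amyloid lowering gives pointwise lower amyloid score", {
  cfg <- canonical_config()
  tg <- seq(0, 20, by = 0.5)
  run <- function(g) {
    iv <- intervention_spec(c(g, 1, 1, 1), start_time = 3)
    integrate_trajectory(cfg$anchor_state, 0, tg, cfg$dynamics,
                         intervention = iv)$states
  }
  s0 <- run(0)
  s5 <- run(0.5)
  s1 <- run(1)
  after <- tg >= 3
  expect_true(all(s0[after, 1] <= s5[after, 1] + 1e-12))
  expect_true(all(s5[after, 1] <= s1[after, 1] + 1e-12))
  # cooperative system: all coordinates ordered the same way
  expect_true(all(s0[after, ] <= s5[after, ] + 1e-12))
  # derivatives stay non-negative in this regime
  expect_true(all(diff(s0[, 1]) > -1e-12))
})

test_that("intervention with an end time releases the dynamics", {
  cfg <- canonical_config()
  iv <- intervention_spec(c(0, 1, 1, 1), start_time = 2, end_time = 5)
  tr <- integrate_trajectory(cfg$anchor_state, 0, seq(0, 10, by = 0.5),
                             cfg$dynamics, intervention = iv)
  during <- tr$states[tr$times >= 2 & tr$times <= 5, 1]
  after <- tr$states[tr$times >= 5, 1]
  expect_lt(max(abs(during - during[1])), 1e-9)
  expect_gt(after[length(after)] - after[1], 0.01)
})

test_that("intervention spec validates its contract", {
  expect_error(intervention_spec(c(1.2, 1), 0), "gammas")
  expect_error(intervention_spec(c(-0.1, 1), 0), "gammas")
  expect_error(intervention_spec(c(0.5, 1), 5, end_time = 3), "start_time")
})
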