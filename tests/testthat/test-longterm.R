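test_that("AIC arithmetic and tie-breaking follow the definition", {
  # 2p - 2 logL with logL = -100, p = 7
  expect_equal(2 * 7 - 2 * (-100), 214)
  set.seed(1)
  X <- MASS::mvrnorm(400, rep(0, 3), diag(3))
  mix <- fit_latent_mixture(X, components = 1:3, seed = 4)
  # selection equals brute-force enumeration of the candidate table
  tab <- mix$aic_table
  best <- tab[order(tab$aic, tab$n_par), ][1, ]
  expect_equal(mix$aic, best$aic)
  expect_equal(mix$G, best$G)
  expect_identical(mix$structure, best$structure)
  expect_equal(mix$aic, 2 * mix$n_par - 2 * mix$loglik)
})

test_that("single-component likelihoods match the closed-form Gaussian MLE", {
  # independent oracle for the G = 1 rows of the candidate table: the
  # maximized Gaussian log-likelihood has a closed form per structure
  set.seed(2)
  n <- 500
  X <- MASS::mvrnorm(n, c(1, 2, 3, 4), 0.05 * diag(4))
  mix <- suppressWarnings(fit_latent_mixture(X, components = 1:4, seed = 5))
  tab <- mix$aic_table
  S_ml <- stats::cov(X) * (n - 1) / n
  M <- 4
  ll_full <- -n / 2 * (M * log(2 * pi) + log(det(S_ml)) + M)
  ll_diag <- -n / 2 * (M * log(2 * pi) + sum(log(diag(S_ml))) + M)
  ll_sph <- -n / 2 * (M * log(2 * pi) + M * log(mean(diag(S_ml))) + M)
  expect_equal(tab$loglik[tab$G == 1 & tab$structure == "full"], ll_full,
               tolerance = 1e-6)
  expect_equal(tab$loglik[tab$G == 1 & tab$structure == "tied"], ll_full,
               tolerance = 1e-6)
  expect_equal(tab$loglik[tab$G == 1 & tab$structure == "diagonal"], ll_diag,
               tolerance = 1e-6)
  expect_equal(tab$loglik[tab$G == 1 & tab$structure == "spherical"], ll_sph,
               tolerance = 1e-6)
})

test_that("two well-separated Gaussians select two components", {
  set.seed(3)
  X <- rbind(MASS::mvrnorm(250, rep(0, 4), diag(4)),
             MASS::mvrnorm(250, rep(10, 4), diag(4)))
  mix <- fit_latent_mixture(X, components = 1:4, seed = 6)
  expect_equal(mix$G, 2)
})

test_that("degenerate near-zero-variance mixture reproduces direct integration", {
  mu <- c(0.6, 0.5, 0.4, 0.3)
  mix <- structure(list(weights = 1, means = matrix(mu, 1),
                        covariances = array(1e-18 * diag(4), c(4, 4, 1)),
                        structure = "spherical", G = 1L, aic = NA,
                        colnames = c("amy", "met", "atr", "cli")),
                   class = "cascade_mixture")
  dp <- canonical_config()$dynamics
  tg <- seq(-5, 5, by = 0.5)
  ens <- sample_ensemble(mix, 1, dp, t_grid = tg, seed = 7)
  direct <- integrate_trajectory(mu, 0, tg, dp)
  expect_equal(ens$states[, , 1], unname(direct$states), tolerance = 1e-6)
  ref <- build_reference(ens, anchor = "threshold", threshold = 0.3)
  expect_true(all(ref$sd == 0))
})

test_that("ensembles are seed-reproducible and mean-consistent", {
  mix <- canonical_mixture(1)
  dp <- canonical_fit(1)$dynamics
  tg <- seq(-2, 2, by = 0.5)
  e1 <- sample_ensemble(mix, 50, dp, t_grid = tg, seed = 9)
  e2 <- sample_ensemble(mix, 50, dp, t_grid = tg, seed = 9)
  expect_identical(e1$states, e2$states)

  # Monte-Carlo convergence of the anchor-time mean toward the (stable-
  # draw) population mean: error shrinks roughly as n^{-1/2}
  big <- sample_ensemble(mix, 2000, dp, t_grid = c(-0.1, 0, 0.1), seed = 10)
  target <- apply(big$states[2, , ], 1, mean)
  err <- vapply(c(10, 100, 1000), function(n) {
    e <- sample_ensemble(mix, n, dp, t_grid = c(-0.1, 0, 0.1), seed = 11)
    sqrt(mean((apply(e$states[2, , , drop = FALSE], 2, mean) - target)^2))
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("anchoring is a pure translation of the time axis", {
  mix <- canonical_mixture(1)
  m <- canonical_fit(1)
  ens <- sample_ensemble(mix, 100, m$dynamics, t_grid = seq(-20, 6, by = 0.2),
                         seed = 12)
  raw <- cascadesim:::aggregate_ensemble(ens)
  ref <- build_reference(ens, anchor = "threshold", threshold = 0.5)
  expect_equal(ref$mean, raw$mean)
  expect_equal(ref$times, raw$times - ref$anchor_shift)
  # threshold rule: the mean clinical score crosses 0.5 at t = 0
  i0 <- which.min(abs(ref$times))
  expect_gte(ref$mean[i0 + 1, 4], 0.5)
  expect_lte(ref$mean[max(1, i0 - 1), 4], 0.5 + 1e-6)
})

test_that("identity decoder maps the reference onto itself", {
  m <- identity_model(4)
  mu <- c(0.5, 0.4, 0.3, 0.2)
  mix <- structure(list(weights = 1, means = matrix(mu, 1),
                        covariances = array(1e-18 * diag(4), c(4, 4, 1)),
                        structure = "spherical", G = 1L, aic = NA,
                        colnames = m$schema$names),
                   class = "cascade_mixture")
  ens <- sample_ensemble(mix, 3, m$dynamics, t_grid = seq(-3, 3, by = 0.5),
                         seed = 3)
  ref <- build_reference(ens, anchor = "threshold", threshold = 0.25)
  dec <- decode_reference(ref, m)
  for (j in seq_along(m$schema$names)) {
    expect_equal(unname(dec[[j]]$mean[, 1]), unname(ref$mean[, j]),
                 tolerance = 1e-10)
  }
})

test_that("reference trajectory is stable in the ensemble size", {
  mix <- canonical_mixture(1)
  dp <- canonical_fit(1)$dynamics
  tg <- seq(-15, 5, by = 0.5)
  r1 <- cascadesim:::aggregate_ensemble(sample_ensemble(mix, 1000, dp,
                                                        t_grid = tg, seed = 5))
  r2 <- cascadesim:::aggregate_ensemble(sample_ensemble(mix, 2000, dp,
                                                        t_grid = tg, seed = 5))
  expect_lt(mean(abs(r1$mean - r2$mean)), 0.02)
  expect_lt(max(abs(r1$mean - r2$mean)), 0.1)
})

test_that("empty mixtures and ensembles are rejected", {
  expect_error(fit_latent_mixture(matrix(0, 2, 4)), "at least")
  mix <- canonical_mixture(1)
  expect_error(sample_ensemble(mix, 0, canonical_fit(1)$dynamics), "n >= 1")
})
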