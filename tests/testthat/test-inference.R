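test_that("analytic ELBO gradients match central finite differences", {
  set.seed(42)
  sc <- tiny_schema()
  coh <- tiny_cohort(3)
  cfg <- training_config(step = 0.1, seed = 1)
  cols <- schema_columns(sc)
  st <- list(center = setNames(rep(0, 4), cols),
             scale = setNames(rep(1, 4), cols),
             sign = schema_signs(sc))
  prep <- cascadesim:::build_prep(coh, sc, st, 0.1)
  th <- cascadesim:::init_theta(prep, cfg)
  set.seed(7)
  th$vmu <- th$vmu + matrix(rnorm(6, 0, 0.2), 3, 2)
  th$rho <- rnorm(2, log(0.15), 0.1)
  th$log_k <- rnorm(2, log(0.3), 0.2)
  th$alpha[1, 2] <- 0.08
  th$alpha[2, 1] <- -0.05
  fl <- cascadesim:::flatten_theta(th)
  eps <- matrix(rnorm(3 * 2 * 2), 6, 2)   # two MC samples, fixed
  out <- cascadesim:::elbo_engine(th, prep, eps, cfg, kl_weight = 0.7)
  g <- cascadesim:::flatten_theta(out$grad)
  fd <- vapply(seq_along(fl), function(i) {
    e <- 1e-5
    up <- fl; up[i] <- up[i] + e
    dn <- fl; dn[i] <- dn[i] - e
    vu <- cascadesim:::elbo_engine(cascadesim:::unflatten_theta(up, sc, 3),
                                   prep, eps, cfg, 0.7, want_grad = FALSE)$value
    vd <- cascadesim:::elbo_engine(cascadesim:::unflatten_theta(dn, sc, 3),
                                   prep, eps, cfg, 0.7, want_grad = FALSE)$value
    (vu - vd) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-4)
})

test_that("subjects without a complete visit are rejected by name", {
  sc <- tiny_schema()
  bad <- list(list(subject_id = "S_BAD", diagnosis = "NL stable",
                   visits = list(list(time = 0, visit_dx = "NL",
                                      blocks = list(a = c(a_0 = 0.5),
                                                    b = NULL)))))
  expect_error(fit_model(bad, sc, training_config(epochs = 1)), "S_BAD")
})

test_that("the objective never uses absent modality blocks", {
  # masking audit: poisoning absent blocks with NaN sentinels must not
  # change the ELBO (absent data contribute exactly zero)
  coh <- tiny_cohort(4)
  coh[[1]]$visits[[2]]$blocks$b <- NULL
  coh[[2]]$visits[[3]]$blocks$a <- NULL
  m <- fit_model(coh, tiny_schema(),
                 training_config(epochs = 5, batch_size = Inf, seed = 3))
  v1 <- elbo(coh[[1]], m, mc_samples = 3, seed = 9)
  v2 <- elbo(coh[[2]], m, mc_samples = 3, seed = 9)
  poisoned <- coh
  poisoned[[1]]$visits[[2]]$blocks$b <- c(b_0 = NaN, b_1 = NaN)
  poisoned[[2]]$visits[[3]]$blocks$a <- c(a_0 = NaN)
  expect_identical(as.numeric(elbo(poisoned[[1]], m, 3, seed = 9)),
                   as.numeric(v1))
  expect_identical(as.numeric(elbo(poisoned[[2]], m, 3, seed = 9)),
                   as.numeric(v2))
})

test_that("single complete visit ELBO needs no integration", {
  m <- canonical_fit(1)
  s <- canonical_gen(1)$cohort[[1]]
  s$visits <- s$visits[1]
  v <- elbo(s, m, mc_samples = 1, seed = 4)
  expect_true(is.finite(v))
  expect_lt(attr(v, "kl") + 1e-9, Inf)
  # reconstruction term dominates a single visit's bound
  expect_equal(as.numeric(v), attr(v, "recon") - attr(v, "kl"))
})

test_that("more Monte-Carlo samples shrink the ELBO estimator variance", {
  m <- canonical_fit(1)
  s <- canonical_gen(1)$cohort[[2]]
  v_small <- vapply(1:20, function(sd) as.numeric(elbo(s, m, 1, seed = sd)),
                    numeric(1))
  v_big <- vapply(1:20, function(sd) as.numeric(elbo(s, m, 25, seed = sd)),
                  numeric(1))
  expect_lt(stats::var(v_big), stats::var(v_small))
})

test_that("ELBO prefers the generating rates over doubled rates", {
  # comparative Monte-Carlo evaluation on one-modality subjects
  set.seed(10)
  sc <- modality_schema("a", 1L)
  k_true <- 0.4
  mk_subj <- function(i) {
    z0 <- runif(1, 0.1, 0.4)
    times <- c(0, 1, 2, 3.5, 5)
    visits <- lapply(times, function(t) {
      zt <- z0 * exp(k_true * t) / (1 + z0 * (exp(k_true * t) - 1))
      list(time = t, visit_dx = "NL",
           blocks = list(a = c(a_0 = zt + rnorm(1, 0, 0.02))))
    })
    list(subject_id = sprintf("K%02d", i), diagnosis = "NL stable",
         visits = visits)
  }
  coh <- lapply(1:20, mk_subj)
  cfg <- training_config(epochs = 300, batch_size = Inf, seed = 2,
                         learning_rate = 0.05, kl_warmup_frac = 0.05)
  m <- fit_model(coh, sc, cfg)
  m_double <- m
  m_double$dynamics <- dynamics_params(2 * m$dynamics$k, names = "a")
  wins <- vapply(1:40, function(sd) {
    sum(vapply(coh[1:10], function(s) as.numeric(elbo(s, m, 1, seed = sd)),
               numeric(1))) >
      sum(vapply(coh[1:10], function(s)
        as.numeric(elbo(s, m_double, 1, seed = sd)), numeric(1)))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("fitting is reproducible bitwise given the seed", {
  coh <- tiny_cohort(5)
  cfg <- training_config(epochs = 15, batch_size = 2, seed = 11,
                         learning_rate = 0.03)
  m1 <- fit_model(coh, tiny_schema(), cfg)
  m2 <- fit_model(coh, tiny_schema(), cfg)
  expect_identical(m1$trace$objective, m2$trace$objective)
  expect_identical(m1$dynamics$W, m2$dynamics$W)
  expect_identical(m1$decoder$sigma2, m2$decoder$sigma2)
})

test_that("training emits a per-epoch objective log", {
  coh <- tiny_cohort(5)
  m <- fit_model(coh, tiny_schema(),
                 training_config(epochs = 30, batch_size = Inf, seed = 1))
  expect_equal(nrow(m$trace), 30)
  expect_true(all(c("epoch", "objective", "recon", "kl", "kl_weight") %in%
                    names(m$trace)))
  # KL warm-up ramps from below 1 to the full weight
  expect_lt(m$trace$kl_weight[1], 1)
  expect_equal(m$trace$kl_weight[30], 1)
})

test_that("fitted couplings beat a coupling-free model on coupled data", {
  # held-out reconstruction comparison on canonical (coupled) data
  m <- canonical_fit(1)
  gen <- canonical_gen(1)
  m_nocoup <- m
  m_nocoup$dynamics <- dynamics_params(m$dynamics$k, names = m$schema$names)
  held <- gen$cohort[251:300]
  ll_full <- sum(vapply(held, function(s)
    as.numeric(elbo(s, m, 5, seed = 77)), numeric(1)))
  ll_nc <- sum(vapply(held, function(s)
    as.numeric(elbo(s, m_nocoup, 5, seed = 77)), numeric(1)))
  expect_gt(ll_full, ll_nc)
})

test_that("model archives reload to identical outputs", {
  m <- canonical_fit(1)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  b <- canonical_gen(1)$cohort[[3]]$visits[[1]]$blocks
  expect_equal(encode_subject(m2, b)$mean, encode_subject(m, b)$mean)
  z <- c(0.3, 0.2, 0.2, 0.1)
  expect_equal(decode_subject(m2, z), decode_subject(m, z))
  expect_equal(vector_field(z, m2$dynamics), vector_field(z, m$dynamics))
})
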