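# Shared fixtures, computed lazily and cached for the whole test run.
# The canonical generator/fit/reference chain is expensive (~1 min), so
# every test file reuses the same objects.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

canonical_gen <- function(seed = 1) {
  cached(paste0("gen", seed), generate_cohort(canonical_config(seed = seed)))
}

canonical_fit <- function(seed = 1) {
  cached(paste0("fit", seed), {
    gen <- canonical_gen(seed)
    fit_model(gen$cohort, gen$config$schema,
              canonical_training_config(seed = seed))
  })
}

canonical_mixture <- function(seed = 1) {
  cached(paste0("mix", seed), {
    m <- canonical_fit(seed)
    lat <- project_cohort(canonical_gen(seed)$cohort, m, group = "AD")
    fit_latent_mixture(lat, seed = 2)
  })
}

canonical_reference <- function(seed = 1) {
  cached(paste0("ref", seed), {
    m <- canonical_fit(seed)
    ens <- sample_ensemble(canonical_mixture(seed), 1000, m$dynamics, seed = 3)
    build_reference(ens, anchor = "staging", model = m,
                    cohort = canonical_gen(seed)$cohort)
  })
}

# A tiny two-modality cohort for fast unit tests of the fitting machinery.
tiny_schema <- function() modality_schema(c("a", "b"), c(1L, 2L))

tiny_cohort <- function(n = 8, seed = 42) {
  set.seed(seed)
  sc <- tiny_schema()
  lapply(seq_len(n), function(i) {
    z <- runif(1, 0.1, 0.8)
    times <- c(0, cumsum(runif(2, 0.8, 1.2)))
    visits <- lapply(times, function(t) {
      zt <- z * exp(0.3 * t) / (1 + z * (exp(0.3 * t) - 1))
      list(time = t, visit_dx = "NL",
           blocks = list(a = c(a_0 = 0.8 * zt + 0.1 + rnorm(1, 0, 0.03)),
                         b = c(b_0 = 1.1 * zt + rnorm(1, 0, 0.03),
                               b_1 = 0.9 * zt - 0.2 + rnorm(1, 0, 0.03))))
    })
    list(subject_id = sprintf("T%02d", i), diagnosis = "NL stable",
         visits = visits)
  })
}

# identity 1-D-per-modality model: encoder/decoder are identity maps so
# latent states equal the (single) feature values
identity_model <- function(M = 4) {
  sc <- modality_schema(paste0("m", seq_len(M)), rep(1L, M))
  enc <- encoder_params(sc, weights = rep(list(1), M), bias = rep(0, M),
                        link = "identity")
  dec <- decoder_params(sc, slopes = rep(list(1), M),
                        intercepts = rep(list(0), M),
                        sigma2 = rep(1e-4, M))
  stdz <- list(center = setNames(rep(0, M), schema_columns(sc)),
               scale = setNames(rep(1, M), schema_columns(sc)),
               sign = schema_signs(sc))
  structure(list(schema = sc, encoder = enc, decoder = dec,
                 dynamics = dynamics_params(rep(0.3, M), names = sc$names),
                 standardize = stdz, theta = NULL,
                 config = training_config(), objective = NA, trace = NULL),
            class = "cascade_model")
}
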