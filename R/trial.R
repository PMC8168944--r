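#' Two-arm in-silico trial design
#'
#' @param intervention a `cascade_intervention` (applied to the treated
#'   arm only).
#' @param n_per_arm subjects per arm.
#' @param endpoints character vector of clinical feature names (defaults
#'   to every feature of the clinical block).
#' @param eval_time evaluation time in years (default 0 = conversion).
#' @param alpha two-sided significance level (default 0.01).
#' @param replicates Monte-Carlo trial replicates for power estimation.
#' @param seed integer seed.
#' @param pooled use the pooled-variance Student t-test instead of the
#'   default Welch (unequal variance) test.
#' @return An object of class `cascade_trial_design`.
#' @export
trial_design <- function(intervention, n_per_arm = 100, endpoints = NULL,
                         eval_time = 0, alpha = 0.01, replicates = 500,
                         seed = 1L, pooled = FALSE) {
  stopifnot(inherits(intervention, "cascade_intervention"),
            n_per_arm >= 2, alpha > 0, alpha < 1, replicates >= 1)
  structure(list(intervention = intervention,
                 n_per_arm = as.integer(n_per_arm), endpoints = endpoints,
                 eval_time = eval_time, alpha = alpha,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 pooled = pooled),
            class = "cascade_trial_design")
}

clinical_modality <- function(schema) schema$names[length(schema$names)]

resolve_endpoints <- function(design, schema) {
  cli <- clinical_modality(schema)
  eps <- design$endpoints
  if (is.null(eps)) eps <- schema$features[[cli]]
  if (!all(eps %in% schema$features[[cli]])) {
    stop("unknown endpoint(s): ",
         paste(setdiff(eps, schema$features[[cli]]), collapse = ", "))
  }
  eps
}

## Integrate n sampled anchor states to the evaluation time, optionally
## through the intervention-modulated field, and decode the clinical
## endpoints with measurement noise.  Fully vectorized over subjects.
## Anchor draws whose natural *or* treated scenario trajectory leaves the
## model's valid range are rejected and redrawn -- with the identical
## criterion for both arms, so rejection cannot create an arm difference.
simulate_endpoints <- function(model, mix, ref, design, treated, n_total,
                               seed, z_max = 5) {
  schema <- model$schema
  cli <- clinical_modality(schema)
  eps_names <- resolve_endpoints(design, schema)
  W <- model$dynamics$W
  k <- model$dynamics$k
  step <- model$config$step
  t_a <- ref$anchor_state_time
  t_eval <- design$eval_time
  iv <- design$intervention
  relevant <- iv$start_time < t_eval && any(iv$gammas != 1)
  active <- treated && relevant
  eq <- equilibrium_state(model$dynamics, colMeans(mix$means))
  M <- length(eq)

  set.seed(seed)
  Z <- matrix(NA_real_, n_total, M)
  filled <- 0L
  for (round in 1:30) {
    n_cand <- min((n_total - filled) * 4L, max(n_total - filled, 50000L))
    Z0 <- sample_mixture(mix, n_cand)
    Z0 <- pmin(Z0, matrix(eq * (1 - 1e-2), n_cand, M, byrow = TRUE))
    bad <- rep(FALSE, n_cand)
    prop <- function(Zb, from, to, gamma = NULL) {
      span <- to - from
      if (abs(span) < 1e-12) return(Zb)
      n_steps <- max(1L, ceiling(abs(span) / step - 1e-9))
      h <- span / n_steps
      for (s in seq_len(n_steps)) {
        Zb <- rk4_step_mat(Zb, h, W, k, gamma)
        off <- !is.finite(Zb) | abs(Zb) > z_max
        if (any(off)) {
          ro <- unique(which(off) %% nrow(Zb))
          ro[ro == 0] <- nrow(Zb)
          bad[ro] <<- TRUE
          Zb[ro, ] <- 0
        }
      }
      Zb
    }
    ## placebo path (natural history to the evaluation time)
    Z_pl <- prop(Z0, t_a, t_eval)
    Z_arm <- Z_pl
    if (relevant) {
      t_on <- iv$start_time
      t_off <- min(iv$end_time, t_eval)
      Z_tr <- prop(Z0, t_a, t_on)
      Z_tr <- prop(Z_tr, t_on, t_off, gamma = iv$gammas)
      if (t_off < t_eval) Z_tr <- prop(Z_tr, t_off, t_eval)
      if (active) Z_arm <- Z_tr
    }
    good <- utils::head(which(!bad), n_total - filled)
    if (length(good)) {
      Z[(filled + 1):(filled + length(good)), ] <- Z_arm[good, , drop = FALSE]
      filled <- filled + length(good)
    }
    if (filled == n_total) break
  }
  if (filled < n_total) {
    stop("could not simulate ", n_total,
         " scenario-attainable subjects (", filled, " attained)")
  }

  ## decode the clinical block on the standardized scale, add noise,
  ## return native-scale endpoint values
  mi <- match(cli, schema$names)
  a <- model$decoder$slopes[[cli]]
  cc <- model$decoder$intercepts[[cli]]
  sd_m <- sqrt(model$decoder$sigma2[[cli]])
  Xstd <- outer(Z[, mi], a) + matrix(cc, n_total, length(a), byrow = TRUE) +
    matrix(stats::rnorm(n_total * length(a), 0, sd_m), n_total)
  cols <- schema$features[[cli]]
  colnames(Xstd) <- cols
  stdz <- model$standardize
  Xnat <- sweep(sweep(Xstd, 2, stdz$scale[cols], `*`), 2, stdz$center[cols], `+`)
  Xnat <- sweep(Xnat, 2, stdz$sign[cols], `*`)
  Xnat[, eps_names, drop = FALSE]
}

#' Simulate one trial arm
#'
#' Samples `n_per_arm` initial latent states from the fitted mixture of
#' pathological states, integrates each to the evaluation time -- through
#' the intervention-damped field from the intervention start onwards for
#' the treated arm -- decodes the clinical block and adds measurement
#' noise.
#'
#' @param model a fitted `cascade_model`.
#' @param mix a `cascade_mixture` over pathological latent states.
#' @param ref a `cascade_reference` (fixes where the sampled states sit on
#'   the conversion-anchored time axis).
#' @param design a `cascade_trial_design`.
#' @param treated logical: apply the intervention?
#' @param seed integer seed.
#' @return Matrix `n_per_arm x n_endpoints` of native-scale endpoint
#'   values at the evaluation time.
#' @export
simulate_arm <- function(model, mix, ref, design, treated = FALSE,
                         seed = design$seed) {
  simulate_endpoints(model, mix, ref, design, treated, design$n_per_arm, seed)
}

## Row-wise two-sample t-tests between matrices A and B (replicates in
## rows); Welch by default, pooled variance optionally.  Cross-checked
## against stats::t.test in the unit tests.
welch_rows <- function(A, B, pooled = FALSE) {
  n1 <- ncol(A)
  n2 <- ncol(B)
  m1 <- rowMeans(A)
  m2 <- rowMeans(B)
  v1 <- apply(A, 1, stats::var)
  v2 <- apply(B, 1, stats::var)
  if (pooled) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Run a replicated two-arm trial and estimate power
#'
#' Each replicate draws fresh placebo and treated arms, compares every
#' clinical endpoint at the evaluation time with a two-sided two-sample
#' t-test (Welch by default), and records the placebo-minus-treated
#' improvement with a benefit-positive sign convention (polarity-flipped
#' scores are reported as native-scale point improvements as well).
#' Power is the fraction of replicates rejecting at `alpha`, with its
#' binomial Monte-Carlo standard error.
#'
#' @inheritParams simulate_arm
#' @return An object of class `cascade_trial_result`: data frame
#'   `endpoints` with per-endpoint mean/sd improvement, median p-value,
#'   `power` and `mc_se`, plus the design echo.
#' @export
run_trial <- function(model, mix, ref, design) {
  R <- design$replicates
  n <- design$n_per_arm
  eps_names <- resolve_endpoints(design, model$schema)
  seed <- design$seed
  placebo <- simulate_endpoints(model, mix, ref, design, treated = FALSE,
                                n_total = R * n, seed = seed * 2L + 1L)
  treated <- simulate_endpoints(model, mix, ref, design, treated = TRUE,
                                n_total = R * n, seed = seed * 2L + 2L)
  sgn <- model$standardize$sign[eps_names]
  rows <- lapply(seq_along(eps_names), function(j) {
    P <- matrix(placebo[, j], R, n)
    Tr <- matrix(treated[, j], R, n)
    zero_var <- apply(P, 1, stats::var) + apply(Tr, 1, stats::var) == 0
    tt <- welch_rows(P, Tr, pooled = design$pooled)
    pvals <- tt$p
    pvals[zero_var] <- NA_real_
    ## severity scale = native * sign; improvement = benefit-positive
    imp <- (tt$mean1 - tt$mean2) * sgn[j]
    pw <- mean(pvals < design$alpha, na.rm = TRUE)
    if (all(is.na(pvals))) pw <- NA_real_
    data.frame(endpoint = eps_names[j],
               improvement_mean = mean(imp),
               improvement_sd = stats::sd(imp),
               p_median = stats::median(pvals, na.rm = TRUE),
               power = pw,
               mc_se = sqrt(pw * (1 - pw) / sum(!is.na(pvals))),
               n_skipped = sum(zero_var),
               stringsAsFactors = FALSE)
  })
  structure(list(endpoints = do.call(rbind, rows), design = design),
            class = "cascade_trial_result")
}

#' @export
print.cascade_trial_result <- function(x, ...) {
  d <- x$design
  cat("<cascade_trial_result> n/arm =", d$n_per_arm, ", replicates =",
      d$replicates, ", intervention from t =", d$intervention$start_time,
      "\n")
  print(x$endpoints, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Map statistical power over intervention time, sample size and dose
#'
#' Full factorial sweep: every combination of intervention start time,
#' per-arm sample size and amyloid damping factor is evaluated with
#' [run_trial()] under an independent seeded stream, yielding a tidy
#' long-format table.  Cells whose simulation fails are flagged rather
#' than aborting the sweep.
#'
#' @inheritParams simulate_arm
#' @param base_design a `cascade_trial_design` providing endpoints, alpha
#'   and replicate count.
#' @param intervention_times numeric vector of start times (years).
#' @param sample_sizes integer vector of per-arm sizes.
#' @param gamma_levels numeric vector of amyloid damping factors
#'   (0 = 100\% lowering, 0.5 = 50\%, 1 = none).
#' @param amy_index latent coordinate damped by the intervention
#'   (default 1 = amyloid).
#' @return Data frame: `endpoint`, `gamma_amy`, `time`, `n`, `power`,
#'   `mc_se`, `improvement`, `failed`.
#' @export
power_surface <- function(model, mix, ref, base_design, intervention_times,
                          sample_sizes, gamma_levels, amy_index = 1) {
  stopifnot(length(intervention_times) > 0, length(sample_sizes) > 0,
            length(gamma_levels) > 0)
  M <- n_modalities(model$schema)
  grid <- expand.grid(time = intervention_times, n = sample_sizes,
                      gamma_amy = gamma_levels)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- rep(1, M)
    g[amy_index] <- grid$gamma_amy[i]
    iv <- intervention_spec(g, start_time = grid$time[i])
    d <- trial_design(iv, n_per_arm = grid$n[i],
                      endpoints = base_design$endpoints,
                      eval_time = base_design$eval_time,
                      alpha = base_design$alpha,
                      replicates = base_design$replicates,
                      seed = base_design$seed + 13L * i,
                      pooled = base_design$pooled)
    res <- tryCatch(run_trial(model, mix, ref, d), error = function(e) e)
    out[[i]] <- if (inherits(res, "error")) {
      data.frame(endpoint = resolve_endpoints(base_design, model$schema),
                 gamma_amy = grid$gamma_amy[i], time = grid$time[i],
                 n = grid$n[i], power = NA_real_, mc_se = NA_real_,
                 improvement = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(endpoint = res$endpoints$endpoint,
                 gamma_amy = grid$gamma_amy[i], time = grid$time[i],
                 n = grid$n[i], power = res$endpoints$power,
                 mc_se = res$endpoints$mc_se,
                 improvement = res$endpoints$improvement_mean,
                 failed = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
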