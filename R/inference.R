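#' Training configuration for variational model estimation
#'
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the cohort.
#' @param batch_size subjects per minibatch (`Inf` = full batch).
#' @param kl_weight weight of the KL term after warm-up.
#' @param kl_warmup_frac fraction of epochs over which the KL weight ramps
#'   linearly from 0 to `kl_weight`.
#' @param mc_samples Monte-Carlo samples per subject and iteration.
#' @param step integrator step (years) for the latent ODE during fitting.
#' @param seed integer seed controlling all training randomness.
#' @param beta sharpness of the softplus link mapping the pre-link
#'   posterior scale to the latent z-score.
#' @param prior_mean,prior_sd Gaussian prior on the pre-link latent at the
#'   anchor visit.
#' @param alpha_prior_sd standard deviation of the zero-centred Gaussian
#'   prior on the cross-modality couplings (regularizes the otherwise
#'   nearly flat affine-reparameterization direction of the likelihood).
#' @param avg_frac fraction of final epochs over which parameters are
#'   Polyak-averaged to damp stochastic-gradient noise.
#' @param tol convergence tolerance on the relative change of the
#'   smoothed objective (0 disables early stopping).
#' @return An object of class `cascade_training_config`.
#' @export
training_config <- function(learning_rate = 1e-2, epochs = 2000,
                            batch_size = 32, kl_weight = 1,
                            kl_warmup_frac = 0.1, mc_samples = 1,
                            step = 0.1, seed = 1L, beta = 0.05,
                            prior_mean = 0.5, prior_sd = 0.5,
                            alpha_prior_sd = 0.05, avg_frac = 0.25,
                            tol = 0) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, kl_weight >= 0,
            mc_samples >= 1, step > 0, prior_sd > 0, beta > 0,
            alpha_prior_sd > 0, avg_frac >= 0, avg_frac <= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, kl_weight = kl_weight,
                 kl_warmup_frac = kl_warmup_frac,
                 mc_samples = as.integer(mc_samples), step = step,
                 seed = as.integer(seed), beta = beta,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 alpha_prior_sd = alpha_prior_sd, avg_frac = avg_frac,
                 tol = tol),
            class = "cascade_training_config")
}

## ---- internal parameter container -------------------------------------
## theta: vmu (N x M free per-subject posterior means on the pre-link
## scale), rho (shared per-modality log posterior sd), decoder affine
## parameters, per-modality log noise variance, log progression rates and
## coupling matrix.

theta_template <- function(schema, N) {
  M <- n_modalities(schema)
  D <- schema$dims
  list(vmu = matrix(0, N, M), rho = numeric(M),
       dec_a = lapply(schema$names, function(m) numeric(D[[m]])),
       dec_c = lapply(schema$names, function(m) numeric(D[[m]])),
       log_s2 = numeric(M), log_k = numeric(M), alpha = matrix(0, M, M))
}

flatten_theta <- function(theta) {
  off <- which(row(theta$alpha) != col(theta$alpha))
  c(as.numeric(theta$vmu), theta$rho, unlist(theta$dec_a),
    unlist(theta$dec_c), theta$log_s2, theta$log_k, theta$alpha[off])
}

unflatten_theta <- function(v, schema, N) {
  M <- n_modalities(schema)
  D <- as.integer(schema$dims)
  th <- theta_template(schema, N)
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  th$vmu <- matrix(take(N * M), N, M)
  th$rho <- take(M)
  for (i in seq_len(M)) th$dec_a[[i]] <- take(D[i])
  for (i in seq_len(M)) th$dec_c[[i]] <- take(D[i])
  th$log_s2 <- take(M); th$log_k <- take(M)
  off <- which(row(th$alpha) != col(th$alpha))
  th$alpha[off] <- take(length(off))
  th
}

## ---- cohort preprocessing ---------------------------------------------

visit_present_mask <- function(visit, schema) {
  vapply(schema$names, function(m) {
    b <- visit$blocks[[m]]
    !is.null(b) && !all(is.na(b))
  }, logical(1))
}

## Build the fitting structure: standardized baseline features, per-
## modality visit records on the rounded time grid, and grid extents.
## The anchor visit t0 is the earliest visit with all blocks present.
build_prep <- function(cohort, schema, stats, step) {
  M <- n_modalities(schema)
  N <- length(cohort)
  if (N == 0) stop("cohort is empty")
  B <- lapply(schema$names, function(m) matrix(0, N, schema$dims[[m]]))
  names(B) <- schema$names
  rec_subj <- rec_g <- stats::setNames(vector("list", M), schema$names)
  rec_X <- stats::setNames(vector("list", M), schema$names)
  for (m in schema$names) {
    rec_subj[[m]] <- rec_g[[m]] <- list()
    rec_X[[m]] <- list()
  }

  for (i in seq_len(N)) {
    subj <- cohort[[i]]
    times <- vapply(subj$visits, `[[`, numeric(1), "time")
    complete <- vapply(subj$visits, function(v) all(visit_present_mask(v, schema)),
                       logical(1))
    if (!any(complete)) {
      stop("subject ", subj$subject_id,
           " has no visit with all modality blocks present")
    }
    t0 <- min(times[complete])
    for (v in seq_along(subj$visits)) {
      vis <- subj$visits[[v]]
      g <- as.integer(round((vis$time - t0) / step))
      for (m in schema$names) {
        b <- vis$blocks[[m]]
        if (is.null(b) || all(is.na(b))) next
        xs <- standardize_block(b, m, schema, stats)
        rec_subj[[m]] <- c(rec_subj[[m]], i)
        rec_g[[m]] <- c(rec_g[[m]], g)
        rec_X[[m]] <- c(rec_X[[m]], list(xs))
      }
      if (abs(vis$time - t0) < 1e-9) {
        for (m in schema$names) {
          B[[m]][i, ] <- standardize_block(vis$blocks[[m]], m, schema, stats)
        }
      }
    }
  }
  records <- lapply(schema$names, function(m) {
    list(subj = as.integer(unlist(rec_subj[[m]])),
         g = as.integer(unlist(rec_g[[m]])),
         X = do.call(rbind, rec_X[[m]]))
  })
  names(records) <- schema$names
  gs <- unlist(lapply(records, `[[`, "g"))
  list(schema = schema, M = M, N = N, step = step, B = B, records = records,
       Gf = max(0L, gs), Gb = max(0L, -gs),
       ids = vapply(cohort, `[[`, character(1), "subject_id"))
}

prep_subset <- function(prep, idx) {
  remap <- integer(prep$N)
  remap[idx] <- seq_along(idx)
  records <- lapply(prep$records, function(r) {
    keep <- r$subj %in% idx
    list(subj = remap[r$subj[keep]], g = r$g[keep],
         X = r$X[keep, , drop = FALSE])
  })
  gs <- unlist(lapply(records, `[[`, "g"))
  list(schema = prep$schema, M = prep$M, N = length(idx), step = prep$step,
       B = lapply(prep$B, function(b) b[idx, , drop = FALSE]),
       records = records, Gf = max(0L, gs), Gb = max(0L, -gs),
       ids = prep$ids[idx])
}

## ---- reverse-mode pieces ----------------------------------------------

vjp_field_z <- function(G, Z, W, k) {
  G %*% W - 2 * (G * Z) %*% diag(k, length(k))
}

vjp_field_w <- function(G, Z) {
  cr <- crossprod(G, Z)
  diag(cr) <- diag(cr) - colSums(G * Z * Z)
  cr
}

## vector-Jacobian product through one RK4 step Z -> Z_next of step h
rk4_vjp <- function(Z, h, W, k, Gnext) {
  K1 <- field_mat(Z, W, k)
  Y1 <- Z + (h / 2) * K1
  K2 <- field_mat(Y1, W, k)
  Y2 <- Z + (h / 2) * K2
  K3 <- field_mat(Y2, W, k)
  Y3 <- Z + h * K3
  A <- (h / 6) * Gnext
  B4 <- vjp_field_z(A, Y3, W, k)
  Wb <- vjp_field_w(A, Y3)
  K3b <- 2 * A + h * B4
  B3 <- vjp_field_z(K3b, Y2, W, k)
  Wb <- Wb + vjp_field_w(K3b, Y2)
  K2b <- 2 * A + (h / 2) * B3
  B2 <- vjp_field_z(K2b, Y1, W, k)
  Wb <- Wb + vjp_field_w(K2b, Y1)
  K1b <- A + (h / 2) * B2
  B1 <- vjp_field_z(K1b, Z, W, k)
  Wb <- Wb + vjp_field_w(K1b, Z)
  list(Gprev = Gnext + B1 + B2 + B3 + B4, Wbar = Wb)
}

accumulate_at <- function(vec, idx, val) {
  agg <- rowsum(val, idx)
  where <- as.numeric(rownames(agg))
  vec[where] <- vec[where] + agg[, 1]
  vec
}

## ---- the ELBO engine ---------------------------------------------------
## Monte-Carlo ELBO (and its exact gradient w.r.t. all parameters) of the
## generative model: z(t0) sampled from the per-subject Gaussian posterior
## on the pre-link scale and pushed through the softplus link, latent
## trajectory by fixed-step RK4 through the coupled-logistic field,
## per-modality affine decoding with Gaussian noise.  Discretize-then-
## optimize: gradients are back-propagated through the integrator steps.
elbo_engine <- function(theta, prep, eps, cfg, kl_weight = 1,
                        want_grad = TRUE) {
  M <- prep$M
  N <- prep$N
  S <- nrow(eps) / N
  stopifnot(S == round(S))
  h <- prep$step
  W <- theta$alpha
  diag(W) <- 0
  k <- exp(theta$log_k)
  diag(W) <- k
  n_rows <- N * S
  beta <- cfg$beta

  MU <- theta$vmu
  rep_idx <- rep(seq_len(N), times = S)
  sq <- exp(theta$rho)
  U <- MU[rep_idx, , drop = FALSE] + eps * matrix(sq, n_rows, M, byrow = TRUE)
  Z0 <- beta * softplus(U / beta)

  Gf <- prep$Gf
  Gb <- prep$Gb
  Af <- array(0, c(n_rows, M, Gf + 1L))
  Af[, , 1L] <- Z0
  if (Gf > 0) {
    for (g in seq_len(Gf)) {
      Af[, , g + 1L] <- rk4_step_mat(Af[, , g], h, W, k)
    }
  }
  if (Gb > 0) {
    Ab <- array(0, c(n_rows, M, Gb + 1L))
    Ab[, , 1L] <- Z0
    for (g in seq_len(Gb)) {
      Ab[, , g + 1L] <- rk4_step_mat(Ab[, , g], -h, W, k)
    }
  }
  if (!all(is.finite(Af)) || (Gb > 0 && !all(is.finite(Ab)))) {
    ## soft failure: the caller decides whether to abort or roll back
    return(list(value = NA_real_, recon = NA_real_, kl = NA_real_,
                diverged = TRUE))
  }

  grad <- if (want_grad) theta_template(prep$schema, N) else NULL
  GFv <- numeric(n_rows * M * (Gf + 1L))
  GBv <- if (Gb > 0) numeric(n_rows * M * (Gb + 1L)) else NULL
  ll <- 0

  for (mi in seq_len(M)) {
    rec <- prep$records[[mi]]
    n_rec <- length(rec$subj)
    if (n_rec == 0) next
    rows <- rep(rec$subj, times = S) + N * rep(seq_len(S) - 1L, each = n_rec)
    gg <- rep(rec$g, times = S)
    Xe <- rec$X[rep(seq_len(n_rec), times = S), , drop = FALSE]
    zv <- numeric(length(rows))
    fsel <- gg >= 0
    if (any(fsel)) zv[fsel] <- Af[cbind(rows[fsel], mi, gg[fsel] + 1L)]
    if (any(!fsel)) zv[!fsel] <- Ab[cbind(rows[!fsel], mi, -gg[!fsel] + 1L)]
    a <- theta$dec_a[[mi]]
    cc <- theta$dec_c[[mi]]
    s2 <- exp(theta$log_s2[mi])
    R <- Xe - outer(zv, a) - matrix(cc, length(zv), length(a), byrow = TRUE)
    ll <- ll - 0.5 * length(R) * log(2 * pi * s2) - 0.5 * sum(R * R) / s2
    if (want_grad) {
      gz <- drop(R %*% a) / s2 / S
      grad$dec_a[[mi]] <- grad$dec_a[[mi]] + drop(crossprod(R, zv)) / s2 / S
      grad$dec_c[[mi]] <- grad$dec_c[[mi]] + colSums(R) / s2 / S
      grad$log_s2[mi] <- grad$log_s2[mi] +
        (-0.5 * length(R) + 0.5 * sum(R * R) / s2) / S
      lin_f <- rows[fsel] + n_rows * (mi - 1L) + n_rows * M * gg[fsel]
      GFv <- accumulate_at(GFv, lin_f, gz[fsel])
      if (any(!fsel)) {
        lin_b <- rows[!fsel] + n_rows * (mi - 1L) + n_rows * M * (-gg[!fsel])
        GBv <- accumulate_at(GBv, lin_b, gz[!fsel])
      }
    }
  }

  ## KL(q || prior) on the pre-link scale, closed form
  p_mu <- cfg$prior_mean
  p_sd <- cfg$prior_sd
  kl_mat <- log(p_sd) - matrix(theta$rho, N, M, byrow = TRUE) +
    (matrix(sq^2, N, M, byrow = TRUE) + (MU - p_mu)^2) / (2 * p_sd^2) - 0.5
  kl <- sum(kl_mat)
  value <- ll / S - kl_weight * kl

  if (!want_grad) {
    return(list(value = value, recon = ll / S, kl = kl))
  }

  GFa <- array(GFv, c(n_rows, M, Gf + 1L))
  Wbar <- matrix(0, M, M)
  Gbar <- matrix(0, n_rows, M)
  if (Gf > 0) {
    for (g in rev(seq_len(Gf))) {
      Gbar <- Gbar + GFa[, , g + 1L]
      st <- rk4_vjp(Af[, , g], h, W, k, Gbar)
      Gbar <- st$Gprev
      Wbar <- Wbar + st$Wbar
    }
  }
  Z0bar <- Gbar + GFa[, , 1L]
  if (Gb > 0) {
    GBa <- array(GBv, c(n_rows, M, Gb + 1L))
    Gbar <- matrix(0, n_rows, M)
    for (g in rev(seq_len(Gb))) {
      Gbar <- Gbar + GBa[, , g + 1L]
      st <- rk4_vjp(Ab[, , g], -h, W, k, Gbar)
      Gbar <- st$Gprev
      Wbar <- Wbar + st$Wbar
    }
    Z0bar <- Z0bar + Gbar
  }

  Ubar <- Z0bar * stats::plogis(U / beta)
  arr <- array(Ubar, c(N, S, M))
  MUbar <- apply(arr, c(1, 3), sum)
  grad$rho <- colSums(Ubar * eps) * sq
  grad$vmu <- MUbar - kl_weight * (MU - p_mu) / p_sd^2
  grad$rho <- grad$rho - kl_weight * N * (sq^2 / p_sd^2 - 1)
  grad$log_k <- diag(Wbar) * k
  alpha_bar <- Wbar
  diag(alpha_bar) <- 0
  grad$alpha <- alpha_bar
  list(value = value, recon = ll / S, kl = kl, grad = grad)
}

## ---- initialization -----------------------------------------------------
## Data-driven warm start: the per-subject posterior mean is seeded from
## the mean standardized baseline feature of its modality, affinely mapped
## so the cohort spans the nominal [0, 1] pathological range (the latent
## z-score is defined on that scale); decoder slopes and noise come from
## per-feature regressions on that seed.
init_theta <- function(prep, cfg) {
  schema <- prep$schema
  M <- prep$M
  th <- theta_template(schema, prep$N)
  for (i in seq_len(M)) {
    pc <- rowMeans(prep$B[[i]])
    qs <- stats::quantile(pc, c(0.02, 0.98))
    u0 <- 1.05 * (pc - qs[1]) / max(qs[2] - qs[1], 1e-8)
    u0 <- pmin(pmax(u0, -0.1), 1.3)
    th$vmu[, i] <- u0
    z0 <- cfg$beta * softplus(u0 / cfg$beta)
    D <- ncol(prep$B[[i]])
    for (d in seq_len(D)) {
      fit <- stats::lm.fit(cbind(1, z0), prep$B[[i]][, d])
      th$dec_c[[i]][d] <- fit$coefficients[1]
      th$dec_a[[i]][d] <- fit$coefficients[2]
    }
    res <- prep$B[[i]] - cbind(1, z0) %*% rbind(th$dec_c[[i]], th$dec_a[[i]])
    th$log_s2[i] <- log(max(mean(res^2), 1e-3))
  }
  th$rho <- rep(log(0.2), M)
  th$log_k <- rep(log(0.2), M)
  th
}

## ---- optimizer -----------------------------------------------------------

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

## ---- public API ----------------------------------------------------------

#' Monte-Carlo evidence lower bound for one subject
#'
#' Forms the variational posterior over the anchor-visit latent state from
#' the fitted modality-wise encoder (earliest complete visit), samples it,
#' integrates the latent ODE to every visit time and scores all present
#' modality blocks under the decoder, minus the KL divergence between
#' posterior and prior.
#'
#' @param subject a cohort subject (list with `subject_id`, `visits`).
#' @param model a fitted `cascade_model`.
#' @param mc_samples number of Monte-Carlo samples.
#' @param seed integer seed for the posterior draws.
#' @return Scalar ELBO estimate with attributes `recon` and `kl`.
#' @export
elbo <- function(subject, model, mc_samples = 1, seed = 1L) {
  stopifnot(mc_samples >= 1)
  prep <- build_prep(list(subject), model$schema, model$standardize,
                     model$config$step)
  ## rebuild the engine parameter set from the public model components so
  ## that reloaded archives (without fitting state) evaluate identically
  M <- prep$M
  al <- model$dynamics$W
  diag(al) <- 0
  th <- list(vmu = NULL, rho = unname(model$encoder$rho),
             dec_a = lapply(model$decoder$slopes, unname),
             dec_c = lapply(model$decoder$intercepts, unname),
             log_s2 = unname(log(model$decoder$sigma2)),
             log_k = unname(log(model$dynamics$k)), alpha = al)
  th$vmu <- matrix(0, 1, M)
  for (i in seq_len(M)) {
    th$vmu[1, i] <- drop(prep$B[[i]] %*% model$encoder$weights[[i]]) +
      model$encoder$bias[i]
  }
  set.seed(seed)
  eps <- matrix(stats::rnorm(mc_samples * M), mc_samples, M)
  out <- elbo_engine(th, prep, eps, model$config, kl_weight = 1,
                     want_grad = FALSE)
  structure(out$value, recon = out$recon, kl = out$kl)
}

#' Fit the latent progression model by stochastic variational inference
#'
#' Estimates decoder, observation noise, dynamics parameters and
#' per-subject posteriors over the anchor-visit latent state jointly by
#' maximizing a Monte-Carlo ELBO with Adam; parameters are Polyak-averaged
#' over the final epochs.  Gradients are computed by exact reverse-mode
#' differentiation through the fixed-step RK4 integrator (discretize-
#' then-optimize), so runs are bitwise reproducible given the seed.  The
#' modality-wise encoder exposed by the fitted model is obtained by
#' regressing the converged posterior means on the standardized anchor
#' blocks; it is the projection used for staging and long-term simulation.
#'
#' @param cohort list of subjects (each with at least one complete visit).
#' @param schema a `cascade_schema`.
#' @param config a `cascade_training_config`.
#' @param verbose print progress every 10\% of epochs.
#' @return An object of class `cascade_model` with elements `schema`,
#'   `encoder`, `decoder`, `dynamics`, `standardize`, `theta`, `config`,
#'   `objective` and a per-epoch training `trace`.
#' @export
fit_model <- function(cohort, schema, config = training_config(),
                      verbose = FALSE) {
  stopifnot(length(cohort) > 0)
  X <- do.call(rbind, lapply(cohort, function(s) {
    do.call(rbind, lapply(s$visits, function(v) {
      row <- rep(NA_real_, sum(schema$dims))
      names(row) <- schema_columns(schema)
      for (m in schema$names) {
        if (!is.null(v$blocks[[m]])) row[schema$features[[m]]] <- v$blocks[[m]]
      }
      row
    }))
  }))
  stats <- standardization_stats(X, schema)

  prep <- build_prep(cohort, schema, stats, config$step)
  set.seed(config$seed)
  theta <- init_theta(prep, config)
  flat <- flatten_theta(theta)
  opt <- adam_new(length(flat))
  N <- prep$N
  bs <- min(config$batch_size, N)
  n_batches <- ceiling(N / bs)
  warm_epochs <- max(1, round(config$kl_warmup_frac * config$epochs))
  trace <- data.frame(epoch = integer(0), objective = numeric(0),
                      recon = numeric(0), kl = numeric(0),
                      kl_weight = numeric(0))
  avg <- NULL
  n_avg <- 0L
  avg_from <- floor((1 - config$avg_frac) * config$epochs) + 1L
  smoothed <- NA_real_
  last_good <- flat
  n_diverged <- 0L

  for (ep in seq_len(config$epochs)) {
    klw <- config$kl_weight * min(1, ep / warm_epochs)
    perm <- if (n_batches > 1) sample.int(N) else seq_len(N)
    ep_val <- ep_recon <- ep_kl <- 0
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1) * bs + 1):min(b * bs, N)]
      bprep <- if (n_batches > 1) prep_subset(prep, idx) else prep
      btheta <- theta
      if (n_batches > 1) btheta$vmu <- theta$vmu[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * config$mc_samples * prep$M),
                    length(idx) * config$mc_samples, prep$M)
      out <- elbo_engine(btheta, bprep, eps, config, kl_weight = klw)
      if (!is.finite(out$value)) {
        ## a too-aggressive step pushed the dynamics into the unstable
        ## region: roll back to the last finite iterate and drop momentum
        n_diverged <- n_diverged + 1L
        if (n_diverged > 100L) {
          stop("objective repeatedly non-finite (epoch ", ep, ", batch ", b,
               "; subjects ", paste(bprep$ids[seq_len(min(3, length(idx)))],
                                    collapse = ", "), " ...)")
        }
        flat <- last_good
        theta <- unflatten_theta(flat, schema, N)
        opt$m <- 0 * opt$m
        next
      }
      last_good <- flat
      g <- out$grad
      ## weakly-informative Gaussian prior on the couplings (MAP term,
      ## not part of the per-subject bound; spread across batches)
      g$alpha <- g$alpha - btheta$alpha / config$alpha_prior_sd^2 / n_batches
      out$value <- out$value -
        sum(btheta$alpha^2) / (2 * config$alpha_prior_sd^2) / n_batches
      if (n_batches > 1) {
        gfull <- matrix(0, N, prep$M)
        gfull[idx, ] <- g$vmu
        g$vmu <- gfull
      }
      opt <- adam_step(opt, -flatten_theta(g), config$learning_rate)
      flat <- flat - opt$delta
      theta <- unflatten_theta(flat, schema, N)
      ep_val <- ep_val + out$value
      ep_recon <- ep_recon + out$recon
      ep_kl <- ep_kl + out$kl
    }
    trace <- rbind(trace, data.frame(epoch = ep, objective = ep_val,
                                     recon = ep_recon, kl = ep_kl,
                                     kl_weight = klw))
    if (ep >= avg_from) {
      avg <- if (is.null(avg)) flat else avg + flat
      n_avg <- n_avg + 1L
    }
    if (verbose && (ep %% max(1, config$epochs %/% 10) == 0)) {
      message(sprintf("epoch %d/%d  elbo %.2f  (recon %.2f, kl %.2f)",
                      ep, config$epochs, ep_val, ep_recon, ep_kl))
    }
    if (config$tol > 0) {
      prev <- smoothed
      smoothed <- if (is.na(smoothed)) ep_val else 0.9 * smoothed + 0.1 * ep_val
      if (ep > warm_epochs + 10 && !is.na(prev) &&
          abs(smoothed - prev) < config$tol * abs(prev)) break
    }
  }

  if (!is.null(avg)) theta <- unflatten_theta(avg / n_avg, schema, N)
  final <- {
    set.seed(config$seed + 1L)
    eps <- matrix(stats::rnorm(N * prep$M), N, prep$M)
    elbo_engine(theta, prep, eps, config, kl_weight = config$kl_weight,
                want_grad = FALSE)
  }
  model_from_theta(theta, prep, stats, config, final$value, trace)
}

## Assemble the public model object; the encoder is the regression of the
## converged pre-link posterior means on the standardized anchor blocks.
model_from_theta <- function(theta, prep, stats, config, objective, trace) {
  schema <- prep$schema
  M <- prep$M
  enc_w <- vector("list", M)
  enc_b <- numeric(M)
  for (i in seq_len(M)) {
    fit <- stats::lm.fit(cbind(1, prep$B[[i]]), theta$vmu[, i])
    cf <- fit$coefficients
    cf[!is.finite(cf)] <- 0
    enc_b[i] <- cf[1]
    enc_w[[i]] <- cf[-1]
  }
  enc <- encoder_params(schema, enc_w, enc_b, theta$rho, link = "softplus",
                        beta = config$beta)
  dec <- decoder_params(schema, theta$dec_a, theta$dec_c, exp(theta$log_s2))
  k <- exp(theta$log_k)
  al <- theta$alpha
  diag(al) <- 0
  dyn <- dynamics_params(stats::setNames(k, schema$names), al,
                         names = schema$names)
  structure(list(schema = schema, encoder = enc, decoder = dec,
                 dynamics = dyn, standardize = stats, theta = theta,
                 config = config, objective = objective, trace = trace),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model> objective", format(x$objective, digits = 6), "\n")
  print(x$dynamics)
  cat("noise sd per modality (standardized units):",
      paste(sprintf("%s=%.3g", x$schema$names, sqrt(x$decoder$sigma2)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Encode a subject's blocks with a fitted model (native-scale input)
#'
#' @param model a `cascade_model`.
#' @param blocks named list of per-modality native-scale vectors (absent
#'   modalities `NULL`).
#' @return See [encode()].
#' @export
encode_subject <- function(model, blocks) {
  encode(blocks, model$encoder, model$standardize)
}

#' Decode a latent state with a fitted model to native-scale features
#'
#' @param model a `cascade_model`.
#' @param z latent state (length M).
#' @return Named list of per-modality native-scale mean vectors.
#' @export
decode_subject <- function(model, z) {
  decode(z, model$decoder, model$standardize)
}
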