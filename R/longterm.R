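#' Fit a Gaussian mixture to pathological latent states, AIC-selected
#'
#' Enumerates every (component count, covariance structure) candidate,
#' fits each by EM and returns the candidate minimizing
#' AIC = 2p - 2 log L, where p counts free mixture parameters under the
#' structure; ties break toward fewer parameters.  Structures map onto
#' the standard mixture covariance families: `full` (per-component
#' unrestricted), `diagonal` (per-component diagonal), `tied` (shared
#' unrestricted) and `spherical` (per-component isotropic).
#'
#' @param latents numeric matrix (rows = subjects, columns = latent
#'   coordinates).
#' @param components integer vector of candidate component counts.
#' @param structures subset of `c("full", "diagonal", "tied", "spherical")`.
#' @param seed integer seed (EM initialization).
#' @return An object of class `cascade_mixture` with weights, means,
#'   covariance array, the selected structure/count, its AIC, and the full
#'   candidate table (`aic_table`).
#' @export
fit_latent_mixture <- function(latents, components = 1:5,
                               structures = c("full", "diagonal", "tied",
                                              "spherical"),
                               seed = 1L) {
  latents <- as.matrix(latents)
  M <- ncol(latents)
  n <- nrow(latents)
  if (n < M + 1) stop("need at least M + 1 latent points to fit a mixture")
  stopifnot(length(components) >= 1)
  structures <- match.arg(structures, several.ok = TRUE)
  model_map <- c(full = "VVV", diagonal = "VVI", tied = "EEE",
                 spherical = "VII")

  n_cov_par <- function(structure, G, M) {
    switch(structure,
           full = G * M * (M + 1) / 2,
           diagonal = G * M,
           tied = M * (M + 1) / 2,
           spherical = G)
  }

  ## Mclust() resolves mclustBIC in the caller's environment
  mclustBIC <- mclust::mclustBIC

  candidates <- expand.grid(G = components, structure = structures,
                            stringsAsFactors = FALSE)
  rows <- vector("list", nrow(candidates))
  fits <- vector("list", nrow(candidates))
  set.seed(seed)
  for (i in seq_len(nrow(candidates))) {
    G <- candidates$G[i]
    structure <- candidates$structure[i]
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(latents, G = G,
                                      modelNames = model_map[[structure]],
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) {
      warning("mixture candidate G=", G, " structure=", structure,
              " failed and was skipped")
      next
    }
    p <- (G - 1) + G * M + n_cov_par(structure, G, M)
    rows[[i]] <- data.frame(G = G, structure = structure,
                            loglik = fit$loglik, n_par = p,
                            aic = 2 * p - 2 * fit$loglik)
    fits[[i]] <- fit
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all mixture candidates failed")
  tab <- do.call(rbind, rows[ok])
  fits <- fits[ok]
  ord <- order(tab$aic, tab$n_par)
  best <- ord[1]
  fit <- fits[[best]]
  G <- tab$G[best]

  pars <- fit$parameters
  means <- t(matrix(pars$mean, M, G))
  sigma <- pars$variance$sigma
  if (is.null(dim(sigma)) || length(dim(sigma)) == 2) {
    sigma <- array(sigma, c(M, M, G))
  }
  structure(list(weights = as.numeric(pars$pro), means = means,
                 covariances = sigma, structure = tab$structure[best],
                 G = G, aic = tab$aic[best], loglik = tab$loglik[best],
                 n_par = tab$n_par[best], aic_table = tab,
                 colnames = colnames(latents)),
            class = "cascade_mixture")
}

#' @export
print.cascade_mixture <- function(x, ...) {
  cat("<cascade_mixture> ", x$G, " component(s), structure '", x$structure,
      "', AIC ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Draw latent anchor states from a fitted mixture
#'
#' Samples are truncated by rejection to the box `bounds` (the latent
#' pathological range): the coupled-logistic field is only guaranteed
#' forward/backward bounded for non-negative states, and mixture tails
#' would otherwise occasionally produce unphysical negative scores.
#'
#' @param mix a `cascade_mixture`.
#' @param n number of draws.
#' @param bounds length-2 truncation box applied to every coordinate.
#' @return Matrix `n x M` of latent states.
#' @export
sample_mixture <- function(mix, n, bounds = c(1e-4, 3)) {
  M <- ncol(mix$means)
  out <- matrix(NA_real_, n, M)
  need <- seq_len(n)
  for (attempt in 1:100) {
    comp <- sample.int(mix$G, length(need), replace = TRUE, prob = mix$weights)
    draw <- matrix(NA_real_, length(need), M)
    for (g in unique(comp)) {
      idx <- which(comp == g)
      draw[idx, ] <- MASS::mvrnorm(length(idx), mix$means[g, ],
                                   mix$covariances[, , g])
    }
    ok <- apply(draw >= bounds[1] & draw <= bounds[2], 1, all)
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) {
    ## pathological mixtures only: clamp the stragglers
    comp <- sample.int(mix$G, length(need), replace = TRUE, prob = mix$weights)
    draw <- t(vapply(comp, function(g) MASS::mvrnorm(1, mix$means[g, ],
                                                     mix$covariances[, , g]),
                     numeric(M)))
    out[need, ] <- pmin(pmax(draw, bounds[1]), bounds[2])
  }
  colnames(out) <- mix$colnames
  out
}

#' Integrate an ensemble of mixture draws over a common time grid
#'
#' Each sampled pathological anchor state is integrated forward and
#' backward from grid time 0 across `t_grid`, yielding the collection of
#' long-term latent trajectories that summarizes the disease course.
#'
#' @param mix a `cascade_mixture`.
#' @param n ensemble size.
#' @param params a `cascade_dynamics`.
#' @param t_grid increasing time grid containing 0 (years; anchors sit at
#'   grid time 0).
#' @param step integrator step (years).
#' @param seed integer seed.
#' @param z_max bound defining the valid latent range; draws whose
#'   time-reversed trajectory exceeds it (mixture tail states that are
#'   unattainable under the fitted dynamics) are rejected and redrawn.
#' @return An object of class `cascade_ensemble`: list with `times` and a
#'   `length(t_grid) x M x n` state array.
#' @export
sample_ensemble <- function(mix, n, params, t_grid = seq(-30, 10, by = 0.1),
                            step = 0.1, seed = 1L, z_max = 5) {
  stopifnot(n >= 1, !is.unsorted(t_grid, strictly = TRUE), any(t_grid >= 0))
  set.seed(seed)
  M <- ncol(mix$means)
  W <- params$W
  k <- params$k
  Tn <- length(t_grid)
  i0 <- which.min(abs(t_grid))
  ## saturation cap: scores above the equilibrium are unphysical and make
  ## the time-reversed flow diverge immediately
  eq <- equilibrium_state(params, colMeans(mix$means))

  ## integrate a batch over the full grid, flagging rows whose
  ## time-reversed trajectory leaves the pathological range (those mixture
  ## tail draws are rejected and redrawn below)
  run_batch <- function(Z0b) {
    nb <- nrow(Z0b)
    st <- array(NA_real_, c(Tn, M, nb))
    bad <- rep(FALSE, nb)
    prop <- function(Z, from, to) {
      span <- to - from
      n_steps <- max(1L, ceiling(abs(span) / step - 1e-9))
      h <- span / n_steps
      for (s in seq_len(n_steps)) {
        Z <- rk4_step_mat(Z, h, W, k)
        off <- !is.finite(Z) | abs(Z) > z_max
        if (any(off)) {
          rows_off <- unique(which(off) %% nrow(Z))
          rows_off[rows_off == 0] <- nrow(Z)
          bad[rows_off] <<- TRUE
          Z[rows_off, ] <- 0   # keep the batch finite; rows are discarded
        }
      }
      Z
    }
    Z <- prop(Z0b, 0, t_grid[i0])
    st[i0, , ] <- t(Z)
    if (i0 < Tn) {
      Zc <- Z
      for (j in (i0 + 1):Tn) {
        Zc <- prop(Zc, t_grid[j - 1], t_grid[j])
        st[j, , ] <- t(Zc)
      }
    }
    if (i0 > 1) {
      Zc <- Z
      for (j in (i0 - 1):1) {
        Zc <- prop(Zc, t_grid[j + 1], t_grid[j])
        st[j, , ] <- t(Zc)
      }
    }
    list(states = st, bad = bad)
  }

  states <- array(NA_real_, c(Tn, M, n))
  pending <- seq_len(n)
  for (round in 1:30) {
    n_cand <- min(length(pending) * 4L, max(length(pending), 20000L))
    Z0 <- sample_mixture(mix, n_cand)
    Z0 <- pmin(Z0, matrix(eq * (1 - 1e-2), n_cand, M, byrow = TRUE))
    res <- run_batch(Z0)
    good <- utils::head(which(!res$bad), length(pending))
    if (length(good)) {
      fill <- pending[seq_along(good)]
      states[, , fill] <- res$states[, , good]
      pending <- pending[-seq_along(good)]
    }
    if (!length(pending)) break
  }
  if (length(pending)) {
    stop("ensemble draws diverged during integration despite resampling ",
         "(draw indices ", paste(utils::head(pending, 5), collapse = ", "),
         " ...)")
  }

  structure(list(times = t_grid, states = states, n = n,
                 names = params$names),
            class = "cascade_ensemble")
}

## Stable equilibrium of the coupled-logistic field reached from `from`
## (long forward integration).
equilibrium_state <- function(params, from, horizon = 300, step = 0.1) {
  Z <- integrate_mat(matrix(pmax(from, 1e-3), 1), 0, horizon, step,
                     params$W, params$k)
  drop(Z)
}

#' @export
print.cascade_ensemble <- function(x, ...) {
  cat("<cascade_ensemble> n =", x$n, "trajectories on t in [",
      min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}

#' Aggregate an ensemble into the long-term reference trajectory
#'
#' Computes the pointwise mean and standard deviation of the ensemble and
#' shifts the time axis so that t = 0 matches clinical conversion.  The
#' default anchor rule stages the conversion visits of MCI-converter
#' subjects against the (unshifted) mean trajectory and sets t = 0 to
#' their average; the fallback anchors at the time where the mean clinical
#' score crosses `threshold`.
#'
#' @param ensemble a `cascade_ensemble`.
#' @param anchor `"staging"` or `"threshold"`.
#' @param model fitted `cascade_model` (required for `"staging"`).
#' @param cohort cohort list (required for `"staging"`; the MCI-converter
#'   subjects' first dementia visits are staged).
#' @param threshold clinical z-score defining conversion under the
#'   threshold rule.
#' @param keep_ensemble retain the (decodable) ensemble array in the
#'   result.
#' @return An object of class `cascade_reference`: `times`, `mean`
#'   (T x M), `sd` (T x M), ensemble size `n`, the applied `anchor_shift`
#'   (years) and `anchor_state_time` (anchored time at which the sampled
#'   mixture states sit).
#' @export
build_reference <- function(ensemble, anchor = c("staging", "threshold"),
                            model = NULL, cohort = NULL, threshold = 0.5,
                            keep_ensemble = TRUE) {
  anchor <- match.arg(anchor)
  ref0 <- aggregate_ensemble(ensemble)
  mean_mat <- ref0$mean

  shift <- if (anchor == "staging") {
    if (is.null(model) || is.null(cohort)) {
      stop("anchor = 'staging' requires both model and cohort")
    }
    taus <- conversion_stages(cohort, model, ref0)
    if (!length(taus)) {
      stop("no MCI-converter conversion visits found for staging anchor")
    }
    mean(taus)
  } else {
    zc <- mean_mat[, ncol(mean_mat)]
    cross <- which(zc >= threshold)[1]
    if (is.na(cross)) {
      stop("mean clinical trajectory never crosses the conversion threshold")
    }
    ensemble$times[cross]
  }

  out <- ref0
  out$times <- ensemble$times - shift
  out$anchor_shift <- shift
  out$anchor_state_time <- -shift
  if (keep_ensemble) out$ensemble <- ensemble$states
  out
}

## Pointwise ensemble statistics on the unshifted time axis.
aggregate_ensemble <- function(ensemble) {
  if (length(dim(ensemble$states)) != 3 || ensemble$n < 1) {
    stop("empty or malformed ensemble")
  }
  mean_mat <- apply(ensemble$states, c(1, 2), mean)
  sd_mat <- apply(ensemble$states, c(1, 2), stats::sd)
  if (ensemble$n == 1) sd_mat[] <- 0
  colnames(mean_mat) <- colnames(sd_mat) <- ensemble$names
  structure(list(times = ensemble$times, mean = mean_mat, sd = sd_mat,
                 n = ensemble$n, anchor_shift = 0, anchor_state_time = 0,
                 names = ensemble$names),
            class = "cascade_reference")
}

## Stage the first dementia visit of each MCI-converter subject against an
## (unshifted) reference; used by the staging-based anchor rule.
conversion_stages <- function(cohort, model, ref) {
  taus <- numeric(0)
  for (subj in cohort) {
    if (!identical(subj$diagnosis, "MCI converter")) next
    vis <- NULL
    for (v in subj$visits) {
      if (identical(v$visit_dx, "Dementia")) {
        vis <- v
        break
      }
    }
    if (is.null(vis)) vis <- subj$visits[[length(subj$visits)]]
    taus <- c(taus, stage(vis$blocks, model, ref)$tau)
  }
  taus
}

#' @export
print.cascade_reference <- function(x, ...) {
  cat("<cascade_reference> t in [", min(x$times), ",", max(x$times),
      "], n =", x$n, ", anchor shift", format(x$anchor_shift, digits = 4),
      "\n")
  invisible(x)
}

#' Decode the reference trajectory into biomarker space
#'
#' Pushes every ensemble member through the decoder and aggregates
#' pointwise (mean and sd on the decoded scale, not by linearization).
#' When the ensemble was not retained, only the decoded mean trajectory is
#' returned with zero sd.
#'
#' @param ref a `cascade_reference`.
#' @param model a fitted `cascade_model` (or a bare `cascade_decoder` for
#'   decoder-scale output).
#' @return Named list of per-modality lists with `times`, `mean`
#'   (T x D_m) and `sd` (T x D_m) on the native scale.
#' @export
decode_reference <- function(ref, model) {
  decoder <- if (inherits(model, "cascade_model")) model$decoder else model
  stdz <- if (inherits(model, "cascade_model")) model$standardize else NULL
  schema <- decoder$schema
  Tn <- length(ref$times)
  out <- stats::setNames(vector("list", length(schema$names)), schema$names)
  has_ens <- !is.null(ref$ensemble)
  for (mi in seq_along(schema$names)) {
    m <- schema$names[mi]
    D <- schema$dims[[m]]
    a <- decoder$slopes[[m]]
    cc <- decoder$intercepts[[m]]
    lnk <- function(z) if (decoder$link == "sigmoid") stats::plogis(z) else z
    if (has_ens) {
      zm <- lnk(ref$ensemble[, mi, ])          # T x n
      dec_mean <- outer(rowMeans(zm), a) +
        matrix(cc, Tn, D, byrow = TRUE)
      zsd <- apply(zm, 1, stats::sd)
      dec_sd <- outer(zsd, abs(a))
    } else {
      dec_mean <- outer(lnk(ref$mean[, mi]), a) + matrix(cc, Tn, D, byrow = TRUE)
      dec_sd <- matrix(0, Tn, D)
    }
    colnames(dec_mean) <- colnames(dec_sd) <- schema$features[[m]]
    if (!is.null(stdz)) {
      cols <- schema$features[[m]]
      sgn <- stdz$sign[cols]
      dec_mean <- sweep(sweep(dec_mean, 2, stdz$scale[cols], `*`), 2,
                        stdz$center[cols], `+`)
      dec_mean <- sweep(dec_mean, 2, sgn, `*`)
      dec_sd <- sweep(dec_sd, 2, stdz$scale[cols], `*`)
    }
    out[[m]] <- list(times = ref$times, mean = dec_mean, sd = dec_sd)
  }
  out
}

#' Project a cohort's anchor visits into the latent space
#'
#' Encodes the earliest complete visit of each subject (optionally
#' restricted to a diagnostic group) with the fitted encoder.
#'
#' @param cohort list of subjects.
#' @param model a fitted `cascade_model`.
#' @param group optional diagnosis label filter (e.g. `"AD"`).
#' @return Matrix of latent coordinates (rows = subjects).
#' @export
project_cohort <- function(cohort, model, group = NULL) {
  keep <- if (is.null(group)) cohort else
    Filter(function(s) identical(s$diagnosis, group), cohort)
  if (!length(keep)) stop("no subjects to project")
  schema <- model$schema
  out <- t(vapply(keep, function(s) {
    times <- vapply(s$visits, `[[`, numeric(1), "time")
    complete <- vapply(s$visits, function(v) all(visit_present_mask(v, schema)),
                       logical(1))
    v <- s$visits[[which(complete)[which.min(times[complete])]]]
    encode_subject(model, v$blocks)$mean
  }, numeric(n_modalities(schema))))
  rownames(out) <- vapply(keep, `[[`, character(1), "subject_id")
  out
}
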