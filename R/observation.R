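#' Modality-wise encoder parameters
#'
#' The encoder maps each modality block independently to a single latent
#' coordinate, preserving the interpretability of the latent space (one
#' coordinate per modality).  Each coordinate is an affine map of the
#' block composed with a link function.  The default softplus link is
#' linear over the pathological range but smoothly floored at zero, so
#' encoded states stay inside the forward-invariant positive region of the
#' coupled-logistic dynamics (negative states can blow up in finite time).
#' A scaled-logistic link and a plain identity link are also available.
#' The posterior scale of the latent coordinate (used by variational
#' inference) is a free per-modality parameter on the pre-link scale.
#'
#' @param schema a `cascade_schema`.
#' @param weights list of per-modality weight vectors (length `D_m`).
#' @param bias numeric M-vector of per-modality intercepts.
#' @param rho numeric M-vector of log posterior standard deviations.
#' @param link `"softplus"` (default), `"logit"` (scaled logistic,
#'   bounded by `z_scale`) or `"identity"`.
#' @param z_scale upper bound of the latent range under the logit link.
#' @param beta sharpness of the softplus floor (years of z; smaller =
#'   closer to exactly linear-with-floor).
#' @return An object of class `cascade_encoder`.
#' @export
encoder_params <- function(schema, weights, bias, rho = rep(log(0.2), length(schema$names)),
                           link = c("softplus", "logit", "identity"),
                           z_scale = 2, beta = 0.05) {
  link <- match.arg(link)
  M <- n_modalities(schema)
  stopifnot(length(weights) == M, length(bias) == M, length(rho) == M,
            all(lengths(weights) == schema$dims))
  structure(list(schema = schema, weights = stats::setNames(weights, schema$names),
                 bias = stats::setNames(as.numeric(bias), schema$names),
                 rho = stats::setNames(as.numeric(rho), schema$names),
                 link = link, z_scale = z_scale, beta = beta),
            class = "cascade_encoder")
}

## numerically stable softplus
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

apply_link <- function(u, enc) {
  switch(enc$link,
         softplus = enc$beta * softplus(u / enc$beta),
         logit = enc$z_scale * stats::plogis(u),
         identity = u)
}

link_deriv <- function(u, enc) {
  switch(enc$link,
         softplus = stats::plogis(u / enc$beta),
         logit = {
           p <- stats::plogis(u)
           enc$z_scale * p * (1 - p)
         },
         identity = rep(1, length(u)))
}

#' Modality-wise decoder parameters
#'
#' The decoder maps latent coordinate `z_m` back to the `D_m` features of
#' modality m through a per-feature affine map (optionally composed with a
#' logistic saturation), with isotropic Gaussian observation noise
#' `sigma2[m]` per modality.  Restricting decoder m to `z_m` alone keeps
#' each latent coordinate tied to a single data modality.
#'
#' @param schema a `cascade_schema`.
#' @param slopes list of per-modality slope vectors (length `D_m`).
#' @param intercepts list of per-modality intercept vectors.
#' @param sigma2 numeric M-vector of positive noise variances.
#' @param link `"identity"` (default) or `"sigmoid"` (logistic saturation
#'   of z before the affine map).
#' @return An object of class `cascade_decoder`.
#' @export
decoder_params <- function(schema, slopes, intercepts, sigma2,
                           link = c("identity", "sigmoid")) {
  link <- match.arg(link)
  M <- n_modalities(schema)
  stopifnot(length(slopes) == M, length(intercepts) == M, length(sigma2) == M,
            all(lengths(slopes) == schema$dims),
            all(lengths(intercepts) == schema$dims))
  if (any(sigma2 <= 0)) stop("noise variances sigma2 must be strictly positive")
  structure(list(schema = schema, slopes = stats::setNames(slopes, schema$names),
                 intercepts = stats::setNames(intercepts, schema$names),
                 sigma2 = stats::setNames(as.numeric(sigma2), schema$names),
                 link = link),
            class = "cascade_decoder")
}

#' Feature standardization statistics
#'
#' Per-feature center/scale computed on a training cohort, together with
#' the polarity signs from the schema.  Applied before encoding so that
#' modalities with very different native units share a common scale.
#'
#' @param X numeric matrix of raw feature values (columns in schema order).
#' @param schema a `cascade_schema`.
#' @return List with `center`, `scale` and `sign` named vectors.
#' @export
standardization_stats <- function(X, schema) {
  cols <- schema_columns(schema)
  stopifnot(ncol(X) == length(cols))
  colnames(X) <- cols
  sg <- schema_signs(schema)
  Xs <- sweep(X, 2, sg, `*`)
  ctr <- colMeans(Xs, na.rm = TRUE)
  scl <- apply(Xs, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  list(center = ctr, scale = stats::setNames(scl, cols), sign = sg)
}

## raw named block vector -> working scale (flip polarity, center, scale)
standardize_block <- function(x, m, schema, stats) {
  cols <- schema$features[[m]]
  (stats$sign[cols] * x - stats$center[cols]) / stats$scale[cols]
}

unstandardize_block <- function(x, m, schema, stats) {
  cols <- schema$features[[m]]
  stats$sign[cols] * (x * stats$scale[cols] + stats$center[cols])
}

encoder_mean_one <- function(enc, m, x) {
  u <- sum(enc$weights[[m]] * x) + enc$bias[[m]]
  apply_link(u, enc)
}

#' Encode multimodal blocks into latent z-score coordinates
#'
#' Coordinate m of the output depends only on block m.  Absent blocks
#' (`NULL` entries) are masked out; at least one block must be present.
#'
#' @param blocks named list of per-modality numeric vectors; absent
#'   modalities are `NULL` or missing from the list.
#' @param encoder a `cascade_encoder`.
#' @param standardize optional standardization statistics (see
#'   [standardization_stats()]); when supplied, blocks are taken on the
#'   native scale and standardized before encoding.
#' @return List with `mean` (named M-vector, `NA` where absent), `scale`
#'   (posterior scales on the pre-link scale) and `mask` (logical
#'   presence flags).
#' @export
encode <- function(blocks, encoder, standardize = NULL) {
  schema <- encoder$schema
  M <- n_modalities(schema)
  mask <- vapply(schema$names, function(m) {
    !is.null(blocks[[m]]) && !all(is.na(blocks[[m]]))
  }, logical(1))
  if (!any(mask)) stop("cannot encode: all modality blocks are absent")
  mean <- rep(NA_real_, M)
  names(mean) <- schema$names
  for (m in schema$names[mask]) {
    x <- blocks[[m]]
    if (length(x) != schema$dims[[m]]) {
      stop("block '", m, "' has length ", length(x), ", expected ",
           schema$dims[[m]])
    }
    if (!is.null(standardize)) x <- standardize_block(x, m, schema, standardize)
    mean[m] <- encoder_mean_one(encoder, m, x)
  }
  list(mean = mean, scale = exp(encoder$rho), mask = mask)
}

#' Decode latent z-scores into per-modality feature means
#'
#' @param z numeric latent state (length M); names optional.
#' @param decoder a `cascade_decoder`.
#' @param standardize optional standardization statistics; when supplied
#'   the decoded means are returned on the native scale (unflipped).
#' @return Named list of per-modality mean vectors.
#' @export
decode <- function(z, decoder, standardize = NULL) {
  schema <- decoder$schema
  stopifnot(length(z) == n_modalities(schema), all(is.finite(z)))
  out <- vector("list", length(schema$names))
  names(out) <- schema$names
  for (i in seq_along(schema$names)) {
    m <- schema$names[i]
    zz <- if (decoder$link == "sigmoid") stats::plogis(z[i]) else z[i]
    mu <- decoder$slopes[[m]] * zz + decoder$intercepts[[m]]
    names(mu) <- schema$features[[m]]
    if (!is.null(standardize)) mu <- unstandardize_block(mu, m, schema, standardize)
    out[[m]] <- mu
  }
  out
}

#' Gaussian log-likelihood of observed blocks given a latent state
#'
#' Sum over present modalities of independent Gaussian log-densities with
#' decoder means and per-modality variance; absent blocks contribute
#' exactly zero.
#'
#' @inheritParams decode
#' @param blocks named list of observed blocks (absent = `NULL`).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(blocks, z, decoder) {
  schema <- decoder$schema
  if (any(decoder$sigma2 <= 0)) stop("sigma2 must be strictly positive")
  mu <- decode(z, decoder)
  ll <- 0
  present <- FALSE
  for (m in schema$names) {
    x <- blocks[[m]]
    if (is.null(x) || all(is.na(x))) next
    present <- TRUE
    ll <- ll + sum(stats::dnorm(x, mu[[m]], sqrt(decoder$sigma2[[m]]), log = TRUE))
  }
  if (!present) stop("log_likelihood requires at least one present block")
  ll
}
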