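#' Coupled-logistic dynamics parameters
#'
#' The latent disease state z evolves according to a system of coupled
#' logistic ordinary differential equations: each modality z-score follows
#' a sigmoidal self-dynamic with progression rate `k[m]` (units 1/year)
#' while cross-modality couplings `alpha[m, j]` feed the level of score j
#' into the growth of score m,
#' \deqn{dz_m/dt = k_m z_m (1 - z_m) + \sum_{j \ne m} \alpha_{m,j} z_j.}
#' In matrix form this is \eqn{dz/dt = W z - V z^2} with `W` holding the
#' rates on its diagonal and the couplings off-diagonal, and `V` diagonal
#' with the same rates (z^2 taken elementwise).
#'
#' @param k numeric vector of per-modality progression rates (1/year).
#' @param alpha square coupling matrix (rows = receiving modality); its
#'   diagonal is ignored.  Defaults to no coupling.
#' @param names modality names; defaults to `names(k)` or `m1..mM`.
#' @return An object of class `cascade_dynamics` with elements `W`
#'   (rates + couplings) and `k`.
#' @examples
#' dp <- dynamics_params(k = c(amy = 0.35, cli = 0.3),
#'                       alpha = matrix(c(0, 0, 0.1, 0), 2, 2, byrow = TRUE))
#' vector_field(c(0.5, 0.1), dp)
#' @export
dynamics_params <- function(k, alpha = NULL, names = NULL) {
  M <- length(k)
  if (is.null(names)) {
    names <- if (!is.null(base::names(k))) base::names(k) else paste0("m", seq_len(M))
  }
  if (is.null(alpha)) alpha <- matrix(0, M, M)
  stopifnot(is.matrix(alpha), all(dim(alpha) == M), all(is.finite(k)),
            all(is.finite(alpha)))
  W <- alpha
  diag(W) <- k
  dimnames(W) <- list(names, names)
  structure(list(W = W, k = stats::setNames(as.numeric(k), names), names = names),
            class = "cascade_dynamics")
}

#' @export
print.cascade_dynamics <- function(x, ...) {
  cat("<cascade_dynamics> M =", length(x$k), "\n")
  cat("rates k:", paste(sprintf("%s=%.3g", x$names, x$k), collapse = ", "), "\n")
  off <- x$W; diag(off) <- 0
  if (any(off != 0)) {
    idx <- which(off != 0, arr.ind = TRUE)
    cat("couplings:",
        paste(sprintf("%s<-%s: %.3g", x$names[idx[, 1]], x$names[idx[, 2]],
                      off[idx]), collapse = ", "), "\n")
  }
  invisible(x)
}

check_state <- function(z, params) {
  if (length(z) != length(params$k)) {
    stop("state length ", length(z), " does not match dynamics dimension ",
         length(params$k))
  }
  if (!all(is.finite(z))) stop("latent state contains non-finite values")
  invisible(TRUE)
}

#' Evaluate the latent vector field dz/dt
#'
#' Per-coordinate form: `k[m] z[m] (1 - z[m]) + sum_{j != m} alpha[m, j] z[j]`.
#'
#' @param z numeric latent state (length M).
#' @param params a `cascade_dynamics`.
#' @return Numeric M-vector dz/dt.
#' @export
vector_field <- function(z, params) {
  check_state(z, params)
  M <- length(z)
  k <- params$k
  out <- numeric(M)
  for (m in seq_len(M)) {
    coupling <- sum(params$W[m, -m] * z[-m])
    out[m] <- k[m] * z[m] * (1 - z[m]) + coupling
  }
  stats::setNames(out, params$names)
}

#' Matrix form W z - V z^2 of the latent vector field
#'
#' Algebraically identical to [vector_field()]; kept as an independent
#' evaluation route (`V` diagonal with the progression rates, z^2
#' elementwise).
#'
#' @inheritParams vector_field
#' @return Numeric M-vector dz/dt.
#' @export
vector_field_matrix <- function(z, params) {
  check_state(z, params)
  V <- diag(params$k, length(z))
  drop(params$W %*% z - V %*% (z * z))
}

## Row-vectorized field for a batch of states (rows of Z); workhorse for
## ensembles, trials and inference.  f_{nm} = sum_j W[m,j] Z[n,j] - k_m Z[n,m]^2.
field_mat <- function(Z, W, k) {
  Z %*% t(W) - (Z * Z) %*% diag(k, length(k))
}

rk4_step_mat <- function(Z, h, W, k, gamma = NULL) {
  g <- function(S) {
    F <- field_mat(S, W, k)
    if (!is.null(gamma)) F <- F %*% diag(gamma, length(k)) else F
  }
  K1 <- g(Z)
  K2 <- g(Z + (h / 2) * K1)
  K3 <- g(Z + (h / 2) * K2)
  K4 <- g(Z + h * K3)
  Z + (h / 6) * (K1 + 2 * K2 + 2 * K3 + K4)
}

## Integrate a batch of states from time `from` to `to` (either direction)
## with uniform sub-steps of at most `step`, constant per-segment gamma.
integrate_mat <- function(Z, from, to, step, W, k, gamma = NULL) {
  span <- to - from
  if (abs(span) < 1e-12) return(Z)
  n_steps <- max(1L, ceiling(abs(span) / step - 1e-9))
  h <- span / n_steps
  for (i in seq_len(n_steps)) {
    Z <- rk4_step_mat(Z, h, W, k, gamma)
    if (!all(is.finite(Z))) {
      stop(sprintf("latent state diverged during integration near t = %.3f",
                   from + i * h))
    }
  }
  Z
}

#' Specify a hypothetical intervention on the latent dynamics
#'
#' An intervention damps the time derivative of selected latent coordinates
#' by multiplying the vector field with a diagonal matrix
#' \eqn{\Gamma = diag(\gamma_1, ..., \gamma_M)} while active.  A 100\%
#' amyloid-lowering intervention sets `gamma` for the amyloid coordinate to
#' 0 (complete arrest of accumulation); 50\% lowering uses 0.5.  By default
#' the intervention never ends (irreversible lowering).
#'
#' @param gammas numeric M-vector of damping factors in `[0, 1]`.
#' @param start_time years (relative to conversion, t = 0) at which the
#'   intervention begins.
#' @param end_time optional end of the active window (default `Inf`).
#' @return An object of class `cascade_intervention`.
#' @export
intervention_spec <- function(gammas, start_time, end_time = Inf) {
  stopifnot(all(is.finite(gammas)), all(gammas >= 0), all(gammas <= 1),
            is.finite(start_time), start_time < end_time)
  structure(list(gammas = as.numeric(gammas), start_time = start_time,
                 end_time = end_time),
            class = "cascade_intervention")
}

#' Intervention-modulated vector field
#'
#' Returns `Gamma %*% vector_field(z)` when `t` lies in the intervention's
#' active window `[start_time, end_time)`, and the unmodified field
#' otherwise.
#'
#' @inheritParams vector_field
#' @param spec a `cascade_intervention`.
#' @param t evaluation time in years.
#' @return Numeric M-vector.
#' @export
apply_intervention_field <- function(z, params, spec, t) {
  f <- vector_field(z, params)
  if (length(spec$gammas) != length(z)) {
    stop("intervention dimension does not match state dimension")
  }
  if (t >= spec$start_time && t < spec$end_time) f <- spec$gammas * f
  f
}

#' Integrate the latent dynamics over a time grid
#'
#' Solves the coupled-logistic system with a fixed-step fourth-order
#' Runge-Kutta scheme (default step 0.1 year), forward from `t0` for grid
#' times after `t0` and backward (time-reversed field) for grid times
#' before `t0`.  When an intervention is supplied, the vector field is
#' multiplied by the diagonal damping matrix at every integration step
#' whose time lies in the active window.
#'
#' @param z0 numeric latent state at `t0`.
#' @param t0 anchor time in years.
#' @param t_grid increasing vector of output times (may span times before
#'   `t0`).
#' @param params a `cascade_dynamics`.
#' @param intervention optional `cascade_intervention`.
#' @param step integrator step size in years.
#' @return An object of class `cascade_trajectory`: list with `times` and
#'   a `length(t_grid) x M` state matrix `states`.
#' @examples
#' dp <- dynamics_params(k = 1)
#' tr <- integrate_trajectory(0.1, 0, seq(-2, 5, by = 0.5), dp)
#' @export
integrate_trajectory <- function(z0, t0, t_grid, params, intervention = NULL,
                                 step = 0.1) {
  stopifnot(all(is.finite(t_grid)), !is.unsorted(t_grid, strictly = TRUE))
  check_state(z0, params)
  M <- length(z0)
  W <- params$W
  k <- params$k
  out <- matrix(NA_real_, length(t_grid), M,
                dimnames = list(NULL, params$names))

  gamma_for <- function(ta, tb) {
    # constant damping over a sub-segment; segments are split at the
    # intervention boundaries so the window edge falls on a step boundary
    if (is.null(intervention)) return(NULL)
    mid <- (ta + tb) / 2
    if (mid >= intervention$start_time && mid < intervention$end_time) {
      intervention$gammas
    } else NULL
  }

  run_direction <- function(targets) {
    # targets: output times on one side of t0, ordered moving away from t0
    Z <- matrix(z0, 1, M)
    t_cur <- t0
    res <- matrix(NA_real_, length(targets), M)
    for (i in seq_along(targets)) {
      tt <- targets[i]
      cuts <- c(t_cur, tt)
      if (!is.null(intervention)) {
        edges <- c(intervention$start_time, intervention$end_time)
        edges <- edges[is.finite(edges)]
        lo <- min(t_cur, tt); hi <- max(t_cur, tt)
        edges <- edges[edges > lo & edges < hi]
        cuts <- if (t_cur <= tt) sort(c(t_cur, edges, tt)) else
          sort(c(t_cur, edges, tt), decreasing = TRUE)
      }
      for (s in seq_len(length(cuts) - 1)) {
        Z <- integrate_mat(Z, cuts[s], cuts[s + 1], step, W, k,
                           gamma_for(cuts[s], cuts[s + 1]))
      }
      t_cur <- tt
      res[i, ] <- Z
    }
    res
  }

  fwd <- which(t_grid >= t0)
  bwd <- which(t_grid < t0)
  if (length(fwd)) out[fwd, ] <- run_direction(t_grid[fwd])
  if (length(bwd)) out[bwd, ] <- run_direction(rev(t_grid[bwd]))[length(bwd):1, , drop = FALSE]

  structure(list(times = t_grid, states = out), class = "cascade_trajectory")
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat("<cascade_trajectory> ", length(x$times), " time points, t in [",
      min(x$times), ", ", max(x$times), "], M = ", ncol(x$states), "\n", sep = "")
  invisible(x)
}
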