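#' Configuration of the synthetic longitudinal cohort generator
#'
#' The generator emulates an ADNI-like amyloid-positive cohort: every
#' subject is a time-shifted observer of one common latent disease
#' trajectory (the solution of the coupled-logistic system started from an
#' early-pathology anchor state), observed at irregular visit times
#' through a known decoder with Gaussian measurement noise, with whole
#' modality blocks missing at random on follow-up visits.  The baseline
#' visit is always complete, matching the estimation requirement of at
#' least one fully observed visit per subject.
#'
#' @param schema a `cascade_schema`.
#' @param dynamics a `cascade_dynamics` (ground-truth rates/couplings).
#' @param anchor_state latent state at disease time 0 (early pathology).
#' @param slopes,intercepts true decoder affine parameters (lists per
#'   modality, native scale).
#' @param sigma per-modality measurement noise standard deviations
#'   (native feature units).
#' @param n_subjects number of subjects.
#' @param tau_range range (years) of the uniform per-subject time-shift
#'   relative to the anchor state.
#' @param visit_range integer range of visits per subject.
#' @param visit_spacing range (years) of the uniform gap between
#'   consecutive visits.
#' @param max_followup cap (years) on total follow-up length.
#' @param missing_rates per-modality probability that a follow-up visit
#'   lacks that block.
#' @param thresholds length-2 increasing thresholds on the true clinical
#'   z-score separating NL / MCI / dementia states.
#' @param seed integer random seed.
#' @param step integrator step (years) used for the ground-truth
#'   trajectory.
#' @return An object of class `cascade_generator_config`.
#' @export
generator_config <- function(schema, dynamics, anchor_state, slopes, intercepts,
                             sigma, n_subjects = 300, tau_range = c(-5, 20),
                             visit_range = c(1L, 8L), visit_spacing = c(0.5, 1.5),
                             max_followup = 16, missing_rates = rep(0, length(schema$names)),
                             thresholds = c(0.25, 1.0), seed = 1L, step = 0.02) {
  M <- n_modalities(schema)
  stopifnot(length(anchor_state) == M, length(sigma) == M,
            length(missing_rates) == M, all(missing_rates >= 0),
            all(missing_rates < 1), length(thresholds) == 2,
            thresholds[1] < thresholds[2], diff(tau_range) > 0,
            visit_range[1] >= 1, max_followup <= 16)
  structure(list(schema = schema, dynamics = dynamics,
                 anchor_state = as.numeric(anchor_state),
                 slopes = slopes, intercepts = intercepts,
                 sigma = stats::setNames(as.numeric(sigma), schema$names),
                 n_subjects = as.integer(n_subjects),
                 tau_range = tau_range, visit_range = as.integer(visit_range),
                 visit_spacing = visit_spacing, max_followup = max_followup,
                 missing_rates = stats::setNames(missing_rates, schema$names),
                 thresholds = thresholds, seed = as.integer(seed), step = step),
            class = "cascade_generator_config")
}

#' Canonical synthetic study configuration
#'
#' The frozen reference fixture used throughout the package's experiments:
#' four modalities with two features each, progression rates
#' k = (0.35, 0.25, 0.25, 0.30) per year, and a positive coupling chain
#' amy -> met, amy -> atr, met -> atr, met -> cli, atr -> cli that
#' reproduces the amyloid-cascade ordering (amyloid saturates first, the
#' clinical score accelerates last).  300 subjects, per-subject time
#' shifts uniform over a 25-year span, 1--8 visits about a year apart,
#' follow-up blocks missing at 15\% (imaging) / 5\% (clinical), and
#' measurement noise of about 5\% (imaging) / 10\% (clinical) of the
#' latent dynamic range.
#'
#' @param n_subjects number of subjects (default 300).
#' @param seed integer seed (default 1).
#' @return A `cascade_generator_config`.
#' @export
canonical_config <- function(n_subjects = 300, seed = 1L) {
  schema <- reduced_schema()
  k <- c(amy = 0.35, met = 0.25, atr = 0.25, cli = 0.30)
  alpha <- matrix(0, 4, 4)
  alpha[2, 1] <- 0.15  # met <- amy
  alpha[3, 1] <- 0.05  # atr <- amy
  alpha[3, 2] <- 0.08  # atr <- met
  alpha[4, 2] <- 0.05  # cli <- met
  alpha[4, 3] <- 0.05  # cli <- atr
  dyn <- dynamics_params(k, alpha, names = names(k))
  generator_config(
    schema = schema, dynamics = dyn,
    anchor_state = c(0.10, 0.02, 0.02, 0.005),
    slopes = list(amy = c(1.00, 0.85), met = c(0.90, 1.10),
                  atr = c(1.05, 0.95), cli = c(1.00, 1.20)),
    intercepts = list(amy = c(1.05, 1.10), met = c(1.20, 1.15),
                      atr = c(3.50, 9.80), cli = c(0.10, 0.05)),
    sigma = c(amy = 0.05, met = 0.05, atr = 0.05, cli = 0.10),
    n_subjects = n_subjects, tau_range = c(-5, 20),
    visit_range = c(1L, 8L), visit_spacing = c(0.5, 1.5),
    missing_rates = c(amy = 0.15, met = 0.15, atr = 0.15, cli = 0.05),
    thresholds = c(0.25, 1.0), seed = seed
  )
}

true_decoder <- function(config) {
  decoder_params(config$schema, config$slopes, config$intercepts,
                 sigma2 = pmax(config$sigma^2, 1e-12))
}

clinical_state <- function(z_cli, thresholds) {
  ifelse(z_cli < thresholds[1], "NL",
         ifelse(z_cli < thresholds[2], "MCI", "Dementia"))
}

group_label <- function(first_dx, last_dx) {
  if (first_dx == "Dementia") return("AD")
  if (first_dx == "MCI") {
    return(if (last_dx == "Dementia") "MCI converter" else "MCI stable")
  }
  if (last_dx != "NL") "NL converter" else "NL stable"
}

#' Generate a synthetic longitudinal multimodal cohort
#'
#' Draws per-subject time shifts, evaluates the shared ground-truth latent
#' trajectory at irregular visit times, decodes it with the true decoder,
#' adds Gaussian noise, applies block-wise missingness (never to the
#' baseline visit) and assigns the five clinical stage labels from the
#' true clinical z-score (stable/converter logic between baseline and last
#' visit).  Fully determined by the seed in the configuration.
#'
#' @param config a `cascade_generator_config`.
#' @return A list with `cohort` (list of subjects, each with `subject_id`,
#'   `diagnosis`, and `visits` carrying `time`, `visit_dx`, `blocks`),
#'   `truth` (data frame with per-subject true time shift, baseline latent
#'   state and stage label) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cascade_generator_config"))
  schema <- config$schema
  M <- n_modalities(schema)
  set.seed(config$seed)
  N <- config$n_subjects

  tau <- stats::runif(N, config$tau_range[1], config$tau_range[2])
  n_visits <- sample(seq(config$visit_range[1], config$visit_range[2]), N,
                     replace = TRUE)
  visit_times <- lapply(seq_len(N), function(i) {
    nv <- n_visits[i]
    if (nv == 1) return(0)
    tt <- c(0, cumsum(stats::runif(nv - 1, config$visit_spacing[1],
                                   config$visit_spacing[2])))
    tt[tt <= config$max_followup]
  })

  # the common ground-truth trajectory, evaluated at all needed times
  s_all <- sort(unique(round(unlist(Map(`+`, visit_times, tau)), 6)))
  master <- integrate_trajectory(config$anchor_state, 0, s_all,
                                 config$dynamics, step = config$step)
  z_at <- function(s) master$states[match(round(s, 6), round(master$times, 6)), ,
                                    drop = FALSE]

  dec <- true_decoder(config)
  cohort <- vector("list", N)
  truth <- data.frame(subject_id = sprintf("S%04d", seq_len(N)),
                      true_tau = tau, stringsAsFactors = FALSE)
  zb <- matrix(NA_real_, N, M, dimnames = list(NULL, paste0("z_", schema$names)))
  stage <- character(N)

  for (i in seq_len(N)) {
    tt <- visit_times[[i]]
    Zi <- z_at(tau[i] + tt)
    dx <- clinical_state(Zi[, M], config$thresholds)
    stage[i] <- group_label(dx[1], dx[length(dx)])
    visits <- vector("list", length(tt))
    for (v in seq_along(tt)) {
      blocks <- stats::setNames(vector("list", M), schema$names)
      for (mi in seq_len(M)) {
        m <- schema$names[mi]
        drop_block <- v > 1 && stats::runif(1) < config$missing_rates[[m]]
        if (drop_block) next
        mu <- config$slopes[[m]] * Zi[v, mi] + config$intercepts[[m]]
        x <- mu + stats::rnorm(length(mu), 0, config$sigma[[m]])
        names(x) <- schema$features[[m]]
        blocks[[m]] <- x
      }
      visits[[v]] <- list(time = tt[v], visit_dx = dx[v], blocks = blocks)
    }
    cohort[[i]] <- list(subject_id = truth$subject_id[i], diagnosis = stage[i],
                        visits = visits)
    zb[i, ] <- Zi[1, ]
  }
  truth <- cbind(truth, as.data.frame(zb))
  truth$stage <- stage
  attr(truth, "dynamics") <- config$dynamics
  attr(truth, "decoder") <- dec
  list(cohort = cohort, truth = truth, config = config)
}
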