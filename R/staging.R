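#' Stage an individual against the reference trajectory
#'
#' Estimates the time-shift tau as the minimizer, over the reference time
#' grid, of the L1 distance between the encoded observation and the
#' reference mean latent trajectory, summed over the modalities that are
#' present:
#' \deqn{\tau = \arg\min_t \sum_{m\ present} | f_m(x_m) - \bar z_m(t) |.}
#' Missing modalities simply drop out of the sum, so a subject can be
#' staged from any non-empty subset of blocks.  The search is a dense grid
#' search (exact to grid resolution); ties break toward the earliest time.
#'
#' @param blocks named list of per-modality native-scale vectors (absent
#'   modalities `NULL`).
#' @param model a fitted `cascade_model`.
#' @param ref a `cascade_reference`.
#' @return An object of class `cascade_timeshift`: list with `tau`
#'   (years relative to conversion), `objective` (L1 distance at the
#'   optimum), and the modality `mask` used.
#' @export
stage <- function(blocks, model, ref) {
  enc <- encode_subject(model, blocks)
  z <- enc$mean[enc$mask]
  zbar <- ref$mean[, enc$mask, drop = FALSE]
  obj <- rowSums(abs(sweep(zbar, 2, z, `-`)))
  i <- which.min(obj)          # first minimum = earliest time
  structure(list(tau = ref$times[i], objective = obj[i], mask = enc$mask),
            class = "cascade_timeshift")
}

#' @export
print.cascade_timeshift <- function(x, ...) {
  cat("<cascade_timeshift> tau =", format(x$tau, digits = 4),
      "years (L1 =", format(x$objective, digits = 4), ", modalities:",
      paste(names(x$mask)[x$mask], collapse = "+"), ")\n")
  invisible(x)
}

#' Stage every subject of a cohort at a chosen visit
#'
#' @param cohort list of subjects.
#' @param model a fitted `cascade_model`.
#' @param ref a `cascade_reference`.
#' @param at `"baseline"` (earliest visit) or `"last"`.
#' @return Data frame with `subject_id`, `diagnosis`, `tau`, `objective`.
#' @export
stage_cohort <- function(cohort, model, ref, at = c("baseline", "last")) {
  at <- match.arg(at)
  rows <- lapply(cohort, function(s) {
    times <- vapply(s$visits, `[[`, numeric(1), "time")
    v <- s$visits[[if (at == "baseline") which.min(times) else which.max(times)]]
    ts <- stage(v$blocks, model, ref)
    data.frame(subject_id = s$subject_id, diagnosis = s$diagnosis,
               tau = ts$tau, objective = ts$objective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare estimated disease severity across clinical groups
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum tests between each adjacent
#' pair of clinical stages (NL stable, NL converter, MCI stable, MCI
#' converter, AD), with group medians and a significance flag.
#'
#' @param taus_by_group named list mapping group label to a numeric vector
#'   of time shifts; names are matched against the canonical stage order,
#'   unknown groups keep their given order at the end.
#' @param alpha significance level (default 0.01, two-sided).
#' @return Data frame with one row per adjacent pair: group labels, sizes,
#'   medians, `p_value` and `significant`.
#' @export
compare_groups <- function(taus_by_group, alpha = 0.01) {
  keep <- vapply(taus_by_group, length, integer(1)) >= 2
  if (any(!keep)) {
    warning("excluding groups with fewer than 2 members: ",
            paste(names(taus_by_group)[!keep], collapse = ", "))
  }
  taus_by_group <- taus_by_group[keep]
  if (length(taus_by_group) < 2) stop("need at least two non-empty groups")
  order_ref <- allowed_diagnoses()
  nm <- names(taus_by_group)
  nm <- c(intersect(order_ref, nm), setdiff(nm, order_ref))
  rows <- lapply(seq_len(length(nm) - 1), function(i) {
    a <- nm[i]
    b <- nm[i + 1]
    wt <- suppressWarnings(stats::wilcox.test(taus_by_group[[a]],
                                              taus_by_group[[b]],
                                              alternative = "two.sided"))
    data.frame(group1 = a, group2 = b,
               n1 = length(taus_by_group[[a]]), n2 = length(taus_by_group[[b]]),
               median1 = stats::median(taus_by_group[[a]]),
               median2 = stats::median(taus_by_group[[b]]),
               p_value = wt$p.value, significant = wt$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
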