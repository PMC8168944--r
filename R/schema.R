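#' Define the multimodal measurement schema
#'
#' A schema names the modality blocks of the latent disease-progression
#' model and fixes their feature dimensions and column names.  The
#' canonical configuration has four modalities -- amyloid burden (`amy`),
#' glucose metabolism (`met`), grey-matter atrophy (`atr`) and clinical
#' assessment (`cli`) -- but any number of modalities is accepted.
#'
#' Features listed in `flip` decrease with disease severity on their native
#' scale (e.g. MMSE, RAVLT immediate/learning) and are sign-flipped at
#' ingest so that every working-scale feature increases with pathology.
#'
#' @param names character vector of unique modality identifiers.
#' @param dims integer vector of per-modality feature dimensions.
#' @param features optional named list of feature-name vectors; defaults to
#'   `<modality>_<0-based index>`.
#' @param flip character vector of feature column names with
#'   severity-decreasing native polarity.
#' @return An object of class `cascade_schema`.
#' @examples
#' sc <- modality_schema(c("amy", "cli"), c(2, 2))
#' schema_columns(sc)
#' @export
modality_schema <- function(names, dims, features = NULL, flip = character()) {
  stopifnot(length(names) == length(dims), !anyDuplicated(names), all(dims >= 1))
  dims <- as.integer(dims)
  if (is.null(features)) {
    features <- lapply(seq_along(names), function(m) {
      paste0(names[m], "_", seq_len(dims[m]) - 1L)
    })
    names(features) <- names
  }
  stopifnot(identical(unname(lengths(features[names])), unname(as.integer(dims))))
  feats <- unlist(features[names], use.names = FALSE)
  if (!all(flip %in% feats)) {
    stop("flip lists unknown feature columns: ",
         paste(setdiff(flip, feats), collapse = ", "))
  }
  structure(
    list(names = names, dims = stats::setNames(dims, names),
         features = features[names], flip = flip),
    class = "cascade_schema"
  )
}

#' Canonical four-modality schema (41/41/41/7)
#'
#' Mirrors an ADNI-like layout: 41 regional amyloid-PET, FDG-PET and
#' grey-matter density values plus seven neuropsychological scores.  MMSE
#' and RAVLT immediate/learning decrease with severity and are flagged for
#' polarity flipping.
#'
#' @return A `cascade_schema`.
#' @export
canonical_schema <- function() {
  cli_feats <- c("cli_ADAS11", "cli_MMSE", "cli_RAVLT_immediate",
                 "cli_RAVLT_learning", "cli_RAVLT_forgetting",
                 "cli_FAQ", "cli_CDRSB")
  modality_schema(
    names = c("amy", "met", "atr", "cli"),
    dims = c(41L, 41L, 41L, 7L),
    features = list(amy = paste0("amy_", 0:40), met = paste0("met_", 0:40),
                    atr = paste0("atr_", 0:40), cli = cli_feats),
    flip = c("cli_MMSE", "cli_RAVLT_immediate", "cli_RAVLT_learning")
  )
}

#' Reduced four-modality schema (2/2/2/2) for fast experiments
#'
#' @return A `cascade_schema`.
#' @export
reduced_schema <- function() {
  modality_schema(c("amy", "met", "atr", "cli"), c(2L, 2L, 2L, 2L))
}

#' Flat feature column names of a schema, in modality order
#'
#' @param schema a `cascade_schema`.
#' @return Character vector of feature column names.
#' @export
schema_columns <- function(schema) {
  unlist(schema$features, use.names = FALSE)
}

#' Signs applied at ingest (+1, or -1 for polarity-flipped features)
#' @param schema a `cascade_schema`.
#' @return Named numeric vector over feature columns.
#' @keywords internal
schema_signs <- function(schema) {
  cols <- schema_columns(schema)
  s <- rep(1, length(cols))
  s[cols %in% schema$flip] <- -1
  stats::setNames(s, cols)
}

n_modalities <- function(schema) length(schema$names)

#' @export
print.cascade_schema <- function(x, ...) {
  cat("<cascade_schema> ", length(x$names), " modalities: ",
      paste0(x$names, "(", x$dims, ")", collapse = " "), "\n", sep = "")
  if (length(x$flip)) cat("  polarity-flipped: ", paste(x$flip, collapse = ", "), "\n", sep = "")
  invisible(x)
}

allowed_diagnoses <- function() {
  c("NL stable", "NL converter", "MCI stable", "MCI converter", "AD")
}
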