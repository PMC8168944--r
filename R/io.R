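#' Convert an in-memory cohort to the long-format table
#'
#' One row per subject-visit: `subject_id`, `time` (years), `diagnosis`
#' (five-level stage label), `visit_dx` (per-visit clinical state when
#' available) and one column per feature, named `<modality>_<index>` (or
#' the schema's clinical score names).  An absent modality block is a run
#' of empty cells spanning the whole block.
#'
#' @param cohort list of subjects.
#' @param schema a `cascade_schema`.
#' @return A data frame.
#' @export
cohort_to_table <- function(cohort, schema) {
  cols <- schema_columns(schema)
  rows <- lapply(cohort, function(s) {
    do.call(rbind, lapply(s$visits, function(v) {
      row <- data.frame(subject_id = s$subject_id, time = v$time,
                        diagnosis = s$diagnosis,
                        visit_dx = if (is.null(v$visit_dx)) NA_character_ else v$visit_dx,
                        stringsAsFactors = FALSE)
      feat <- rep(NA_real_, length(cols))
      names(feat) <- cols
      for (m in schema$names) {
        if (!is.null(v$blocks[[m]])) feat[schema$features[[m]]] <- v$blocks[[m]]
      }
      cbind(row, as.data.frame(as.list(feat), check.names = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$time), , drop = FALSE]
}

#' Write a cohort to CSV
#'
#' @param cohort list of subjects.
#' @param schema a `cascade_schema`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, schema, path) {
  utils::write.csv(cohort_to_table(cohort, schema), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema layout: block presence must be all-or-none per
#' modality per visit, visit times must be finite, and diagnosis labels
#' must belong to the five-level stage vocabulary.  Subjects are returned
#' ordered by identifier, visits by time.
#'
#' @param path CSV file path.
#' @param schema a `cascade_schema`.
#' @return List of subjects (see [generate_cohort()] for the layout).
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- schema_columns(schema)
  missing_cols <- setdiff(c("subject_id", "time", "diagnosis", cols),
                          names(tab))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(tab$time))) {
    bad <- which(!is.finite(tab$time))[1]
    stop("non-finite visit time in row ", bad, " (subject ",
         tab$subject_id[bad], ")")
  }
  ok_dx <- tab$diagnosis %in% allowed_diagnoses()
  if (!all(ok_dx)) {
    bad <- which(!ok_dx)[1]
    stop("unknown diagnosis label '", tab$diagnosis[bad], "' (subject ",
         tab$subject_id[bad], "); allowed: ",
         paste(allowed_diagnoses(), collapse = ", "))
  }
  has_vdx <- "visit_dx" %in% names(tab)
  tab <- tab[order(tab$subject_id, tab$time), , drop = FALSE]

  split_rows <- split(seq_len(nrow(tab)), tab$subject_id)
  cohort <- lapply(names(split_rows), function(id) {
    idx <- split_rows[[id]]
    visits <- lapply(idx, function(r) {
      blocks <- stats::setNames(vector("list", length(schema$names)),
                                schema$names)
      for (m in schema$names) {
        vals <- as.numeric(tab[r, schema$features[[m]]])
        n_na <- sum(is.na(vals))
        if (n_na == 0) {
          names(vals) <- schema$features[[m]]
          blocks[[m]] <- vals
        } else if (n_na < length(vals)) {
          stop("partial '", m, "' block for subject ", id, " at time ",
               tab$time[r], ": block presence is all-or-none per modality")
        }
      }
      list(time = tab$time[r],
           visit_dx = if (has_vdx) tab$visit_dx[r] else NULL,
           blocks = blocks)
    })
    list(subject_id = id, diagnosis = tab$diagnosis[idx[1]], visits = visits)
  })
  cohort
}

## ---- model and reference serialization ---------------------------------

SERIAL_VERSION <- "1.0"

#' Serialize a fitted model to a versioned JSON archive
#'
#' The archive holds the schema, standardization statistics, encoder,
#' decoder, dynamics and training configuration at full numeric
#' precision; [load_model()] reproduces identical encode/decode and
#' vector-field outputs.
#'
#' @param model a `cascade_model`.
#' @param path output file path (JSON).
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "cascadesim-model", version = SERIAL_VERSION,
    schema = list(names = model$schema$names,
                  dims = as.integer(model$schema$dims),
                  features = model$schema$features,
                  flip = model$schema$flip),
    standardize = model$standardize,
    encoder = list(weights = model$encoder$weights,
                   bias = model$encoder$bias, rho = model$encoder$rho,
                   link = model$encoder$link, z_scale = model$encoder$z_scale,
                   beta = model$encoder$beta),
    decoder = list(slopes = model$decoder$slopes,
                   intercepts = model$decoder$intercepts,
                   sigma2 = model$decoder$sigma2, link = model$decoder$link),
    dynamics = list(k = model$dynamics$k,
                    W = as.numeric(model$dynamics$W),
                    names = model$dynamics$names),
    config = unclass(model$config),
    objective = model$objective
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path JSON file path.
#' @return A `cascade_model` (without the per-subject posterior state of
#'   the original fit).
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cascadesim-model")) {
    stop("not a cascadesim model archive: ", path)
  }
  schema <- modality_schema(obj$schema$names, obj$schema$dims,
                            features = obj$schema$features,
                            flip = unlist(obj$schema$flip))
  M <- length(schema$names)
  ## JSON arrays drop names; statistics are stored in schema column order
  cols <- schema_columns(schema)
  stdz <- list(center = stats::setNames(as.numeric(unlist(obj$standardize$center)), cols),
               scale = stats::setNames(as.numeric(unlist(obj$standardize$scale)), cols),
               sign = stats::setNames(as.numeric(unlist(obj$standardize$sign)), cols))
  enc <- encoder_params(schema, lapply(obj$encoder$weights, as.numeric),
                        as.numeric(obj$encoder$bias),
                        as.numeric(obj$encoder$rho),
                        link = obj$encoder$link,
                        z_scale = obj$encoder$z_scale,
                        beta = obj$encoder$beta)
  dec <- decoder_params(schema, lapply(obj$decoder$slopes, as.numeric),
                        lapply(obj$decoder$intercepts, as.numeric),
                        as.numeric(obj$decoder$sigma2),
                        link = obj$decoder$link)
  W <- matrix(obj$dynamics$W, M, M)
  al <- W
  diag(al) <- 0
  dyn <- dynamics_params(stats::setNames(as.numeric(obj$dynamics$k),
                                         schema$names),
                         al, names = schema$names)
  cfg <- obj$config
  class(cfg) <- "cascade_training_config"
  structure(list(schema = schema, encoder = enc, decoder = dec,
                 dynamics = dyn, standardize = stdz, theta = NULL,
                 config = cfg, objective = obj$objective, trace = NULL),
            class = "cascade_model")
}

#' Write the reference trajectory as a tidy CSV
#'
#' Columns: `time`, then `mean_<modality>` and `sd_<modality>` per
#' coordinate.
#'
#' @param ref a `cascade_reference`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(time = ref$times)
  for (i in seq_along(ref$names)) {
    df[[paste0("mean_", ref$names[i])]] <- ref$mean[, i]
    df[[paste0("sd_", ref$names[i])]] <- ref$sd[, i]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-trajectory CSV written by [write_reference()]
#'
#' @param path CSV file path.
#' @return A `cascade_reference` (without the ensemble array).
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path)
  nm <- sub("^mean_", "", grep("^mean_", names(df), value = TRUE))
  mean_mat <- as.matrix(df[paste0("mean_", nm)])
  sd_mat <- as.matrix(df[paste0("sd_", nm)])
  colnames(mean_mat) <- colnames(sd_mat) <- nm
  structure(list(times = df$time, mean = mean_mat, sd = sd_mat,
                 n = NA_integer_, anchor_shift = NA_real_,
                 anchor_state_time = NA_real_, names = nm),
            class = "cascade_reference")
}

#' Write a run manifest next to an output file
#'
#' Records the package version, the seed, the configuration (hashed and
#' verbatim) and the md5 checksums of the listed output files, enough to
#' regenerate them bit-for-bit.
#'
#' @param path manifest path (JSON).
#' @param config any serializable configuration object.
#' @param seed the seed used.
#' @param files character vector of produced files.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character()) {
  cfg_json <- jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    tool = "cascadesim",
    version = as.character(utils::packageVersion("cascadesim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    files = lapply(files[file.exists(files)], function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
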