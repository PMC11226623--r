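# Validated readers and writers for the package's file schemas. All files are
# comma-separated UTF-8 with a mandatory header row and `.` decimal point:
#   probability file: subject_id,point_id[,activity][,stratum_*],p_<c1>,...,p_<cK>
#   training file:    subject_id,point_id[,activity],label,f_1,...,f_L
#   score file:       subject_id[,subset_tag],cobra_score,m_relevant,m_total
#   clinical file:    subject_id,clinical_score,group[,stratum_*]
# Models are stored as JSON; run configs as YAML or JSON.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  # base read.csv parses doubles with correctly-rounded strtod, so a
  # write -> read -> write cycle is byte-identical
  x <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x
}

#' Read and write probability tables
#'
#' @param path File path.
#' @param classes Optional declared vocabulary; the file's `p_` columns must
#'   match it in order.
#' @return `read_probability_table()` returns a validated probability tibble.
#' @export
read_probability_table <- function(path, classes = NULL) {
  x <- read_csv_strict(path, c("subject_id", "point_id"))
  x$subject_id <- as.character(x$subject_id)
  x$point_id <- as.character(x$point_id)
  resolve_classes(x, classes)
  x
}

#' @rdname read_probability_table
#' @param probs Probability tibble to write.
#' @export
write_probability_table <- function(probs, path) {
  resolve_classes(probs)
  readr::write_csv(probs, path, progress = FALSE)
  invisible(path)
}

#' Read and write labeled training tables
#'
#' @param path File path.
#' @return A tibble with `subject_id`, `point_id`, `label` and `f_*` columns.
#' @export
read_training_table <- function(path) {
  x <- read_csv_strict(path, c("subject_id", "point_id", "label"))
  if (length(feature_col_names(x)) == 0) {
    abort(paste0(path, " has no `f_*` feature columns."))
  }
  x$subject_id <- as.character(x$subject_id)
  x$point_id <- as.character(x$point_id)
  x$label <- as.character(x$label)
  x
}

#' @rdname read_training_table
#' @param train Training tibble to write.
#' @export
write_training_table <- function(train, path) {
  readr::write_csv(train, path, progress = FALSE)
  invisible(path)
}

#' Read and write subject score tables
#'
#' @param path File path.
#' @return A tibble with `subject_id`, optional `subset_tag`, `cobra_score`,
#'   `m_relevant`, `m_total`.
#' @export
read_score_table <- function(path) {
  x <- read_csv_strict(path, c("subject_id", "cobra_score",
                               "m_relevant", "m_total"))
  x$subject_id <- as.character(x$subject_id)
  x
}

#' @rdname read_score_table
#' @param scores Score tibble to write.
#' @export
write_score_table <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' Read and write clinical tables
#'
#' @param path File path.
#' @return A tibble with `subject_id`, `clinical_score`, `group` and any
#'   stratification columns.
#' @export
read_clinical_table <- function(path) {
  x <- read_csv_strict(path, c("subject_id", "clinical_score"))
  x$subject_id <- as.character(x$subject_id)
  if (!is.numeric(x$clinical_score) || anyNA(x$clinical_score)) {
    abort(paste0(path, ": `clinical_score` must be numeric and complete."))
  }
  x
}

#' @rdname read_clinical_table
#' @param clinical Clinical tibble to write.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_csv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Serialize a fitted backend to JSON and back
#'
#' The file records the vocabulary, configuration, standardisation
#' statistics, the weight matrix (row-major with documented shape) and the
#' training diagnostics. A round-tripped model emits identical probabilities.
#'
#' @param model A `cobra_backend`.
#' @param path Output path.
#' @export
write_backend <- function(model, path) {
  if (!inherits(model, "cobra_backend")) abort("`model` must be a `cobra_backend`.")
  # numeric arrays are stored as %.17g strings so reloads are bit-exact
  payload <- list(
    format = "cobrascore-backend",
    schema_version = 1L,
    classes = model$classes,
    config = unclass(model$config),
    center = sprintf("%.17g", model$center),
    scale = sprintf("%.17g", model$scale),
    n_features = model$n_features,
    weights = list(
      n_rows = nrow(model$weights),
      n_cols = ncol(model$weights),
      row_major = sprintf("%.17g", as.vector(t(model$weights)))
    ),
    diagnostics = model$diagnostics
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_backend
#' @return `read_backend()` returns the restored `cobra_backend`.
#' @export
read_backend <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "cobrascore-backend")) {
    abort(paste0(path, " is not a cobrascore backend file."))
  }
  cfg <- payload$config
  config <- backend_config(
    l2_penalty = cfg$l2_penalty, max_iterations = cfg$max_iterations,
    convergence_tolerance = cfg$convergence_tolerance,
    context_window = cfg$context_window, seed = cfg$seed,
    standardize = cfg$standardize
  )
  W <- matrix(as.numeric(payload$weights$row_major),
              nrow = payload$weights$n_rows,
              ncol = payload$weights$n_cols, byrow = TRUE,
              dimnames = list(NULL, payload$classes))
  structure(
    list(weights = W, classes = payload$classes, config = config,
         center = as.numeric(payload$center),
         scale = as.numeric(payload$scale),
         n_features = payload$n_features,
         diagnostics = as.list(payload$diagnostics)),
    class = "cobra_backend"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits `train.csv` (labeled training table), `test.csv` (labeled feature
#' table for the test cohort), `clinical.csv`, and `manifest.json` recording
#' the full generator configuration including the seed.
#'
#' @param cohort A `cobra_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "cobra_cohort")) {
    abort("`cohort` must come from `simulate_cohort()`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_training_table(cohort$train, file.path(dir, "train.csv"))
  write_training_table(cohort$test, file.path(dir, "test.csv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  cfg <- unclass(cohort$config)
  cfg$class_means <- lapply(seq_len(nrow(cfg$class_means)),
                            function(i) cfg$class_means[i, ])
  if (!is.null(cfg$shift_directions)) {
    cfg$shift_directions <- lapply(seq_len(nrow(cfg$shift_directions)),
                                   function(i) cfg$shift_directions[i, ])
  }
  jsonlite::write_json(list(format = "cobrascore-cohort-manifest",
                            schema_version = 1L, config = cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config file must be .yaml, .yml or .json.")
  }
}

#' Write a correlation report to JSON
#'
#' @param report A `cobra_correlation`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "cobra_correlation")) {
    abort("`report` must be a `cobra_correlation`.")
  }
  payload <- list(
    format = "cobrascore-report", schema_version = 1L,
    r = report$r, ci_low = report$ci_low, ci_high = report$ci_high,
    n = report$n, ci_method = report$ci_method, level = report$level
  )
  if (!is.null(report$breakdown)) payload$breakdown <- report$breakdown
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
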