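#' Predicted class and confidence for every datapoint
#'
#' For each row of a per-datapoint class-probability table, returns the
#' predicted class (the argmax over the K class probabilities) and the model
#' confidence (the maximum probability itself, the usual maximum-softmax
#'-probability notion). Ties are broken toward the earliest class in the
#' vocabulary order so results are deterministic.
#'
#' Rows whose probabilities sum to 1 within `simplex_tolerance` are
#' renormalized by their sum before taking the maximum; rows further from the
#' simplex, or containing negative or non-finite entries, raise an error that
#' names the offending row.
#'
#' @param probs Probability table: a data frame with `subject_id`, `point_id`,
#'   optional tag columns (e.g. `activity`), and one `p_<class>` column per
#'   class, in vocabulary order.
#' @param classes Optional character vector declaring the vocabulary; must
#'   match the `p_` columns in order. Defaults to the vocabulary encoded by
#'   the columns.
#' @param simplex_tolerance Maximum tolerated deviation of a row sum from 1.
#' @return A tibble with the id/tag columns of `probs` plus `predicted_class`
#'   and `confidence` (in `[1/K, 1]`), one row per input row, in input order.
#'   The vocabulary is attached as attribute `"classes"`.
#' @examples
#' probs <- tibble::tibble(
#'   subject_id = "s1", point_id = c("a", "b"),
#'   p_reach = c(0.7, 0.1), p_idle = c(0.2, 0.6), p_rest = c(0.1, 0.3)
#' )
#' predict_confidence(probs)
#' @export
predict_confidence <- function(probs, classes = NULL, simplex_tolerance = 1e-6) {
  chk <- check_prob_table(probs, classes, simplex_tolerance)
  idx <- argmax_first(chk$P)
  out <- chk$meta
  out$predicted_class <- chk$classes[idx]
  out$confidence <- chk$P[cbind(seq_len(nrow(chk$P)), idx)]
  attr(out, "classes") <- chk$classes
  out
}

#' Indices of datapoints predicted to belong to the clinically relevant classes
#'
#' @param predictions Output of [predict_confidence()] (or any data frame with
#'   a `predicted_class` column).
#' @param relevant Character vector of clinically relevant class names.
#' @param classes Vocabulary used to validate `relevant`; defaults to the
#'   `"classes"` attribute attached by [predict_confidence()].
#' @return Integer vector of row indices whose predicted class is relevant,
#'   in input order.
#' @export
select_relevant <- function(predictions, relevant, classes = NULL) {
  classes <- classes %||% attr(predictions, "classes")
  if (is.null(classes)) {
    abort("Supply `classes`: `predictions` carries no vocabulary attribute.")
  }
  relevant <- check_relevant(relevant, classes)
  if (!"predicted_class" %in% names(predictions)) {
    abort("`predictions` must have a `predicted_class` column.")
  }
  which(predictions$predicted_class %in% relevant)
}

#' COBRA score of a single test subject
#'
#' The COBRA score is the arithmetic mean of the model confidence over the
#' subject's datapoints *predicted* to belong to the clinically relevant
#' classes. Lower scores indicate larger deviation from the healthy training
#' population, i.e. greater impairment or disease severity. The score lies in
#' `[1/K, 1]` whenever at least one datapoint is predicted relevant.
#'
#' @inheritParams predict_confidence
#' @param relevant Character vector of clinically relevant class names (a
#'   nonempty subset of the vocabulary).
#' @param on_empty What to do when no datapoint is predicted relevant:
#'   `"error"` (default) raises an error, `"missing"` returns `NA` with a
#'   warning. A silently missing score could bias downstream correlations,
#'   hence the strict default.
#' @return A single number in `[1/K, 1]` (or `NA` under
#'   `on_empty = "missing"`).
#' @examples
#' probs <- tibble::tibble(
#'   subject_id = "s1", point_id = as.character(1:4),
#'   p_A = c(0.7, 0.1, 0.2, 0.5), p_B = c(0.2, 0.6, 0.3, 0.25),
#'   p_C = c(0.1, 0.3, 0.5, 0.25)
#' )
#' cobra_score(probs, relevant = c("A", "B"))  # (0.7 + 0.6 + 0.5) / 3 = 0.6
#' @export
cobra_score <- function(probs, relevant, classes = NULL,
                        simplex_tolerance = 1e-6,
                        on_empty = c("error", "missing")) {
  on_empty <- arg_match(on_empty)
  pred <- predict_confidence(probs, classes, simplex_tolerance)
  if (n_distinct(pred$subject_id) != 1) {
    abort("`cobra_score()` expects a single subject; use `score_cohort()`.")
  }
  idx <- select_relevant(pred, relevant)
  if (length(idx) == 0) {
    msg <- paste0("Subject ", pred$subject_id[1],
                  " has no datapoints predicted in the relevant classes.")
    if (on_empty == "error") abort(msg)
    warn(msg)
    return(NA_real_)
  }
  mean(pred$confidence[idx])
}

#' COBRA scores for every subject in a cohort
#'
#' Computes one pooled COBRA score per subject over all of that subject's
#' datapoints, or, with `subset_by`, one score per (subject, tag value) pair —
#' e.g. per rehabilitation activity. Pooled scores average over the whole
#' relevant set of a subject (a single average, not an average of per-tag
#' averages); the pooled score equals the `m_relevant`-weighted mean of the
#' per-tag scores.
#'
#' @inheritParams cobra_score
#' @param subset_by Optional name of a tag column of `probs` (e.g.
#'   `"activity"`) to score within.
#' @return A tibble with columns `subject_id`, optionally `subset_tag`,
#'   `cobra_score`, `m_relevant` (number of datapoints predicted relevant) and
#'   `m_total`. `cobra_score` is `NA` exactly when `m_relevant` is 0 (only
#'   reachable under `on_empty = "missing"`).
#' @export
score_cohort <- function(probs, relevant, classes = NULL, subset_by = NULL,
                         simplex_tolerance = 1e-6,
                         on_empty = c("error", "missing")) {
  on_empty <- arg_match(on_empty)
  pred <- predict_confidence(probs, classes, simplex_tolerance)
  vocab <- attr(pred, "classes")
  relevant <- check_relevant(relevant, vocab)
  if (!is.null(subset_by)) {
    if (!is.character(subset_by) || length(subset_by) != 1) {
      abort("`subset_by` must be a single column name.")
    }
    if (!subset_by %in% names(pred)) {
      abort(paste0("Tag column `", subset_by, "` not found in `probs`."))
    }
    if (anyNA(pred[[subset_by]])) {
      abort(paste0("Tag column `", subset_by, "` has missing values."))
    }
    pred$subset_tag <- as.character(pred[[subset_by]])
    keys <- c("subject_id", "subset_tag")
  } else {
    keys <- "subject_id"
  }
  pred$.relevant <- pred$predicted_class %in% relevant
  out <- pred %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise(
      cobra_score = if (any(.data$.relevant)) {
        mean(.data$confidence[.data$.relevant])
      } else NA_real_,
      m_relevant = sum(.data$.relevant),
      m_total = n(),
      .groups = "drop"
    )
  empty <- out$m_relevant == 0
  if (any(empty)) {
    who <- unique(out$subject_id[empty])
    msg <- paste0("No datapoints predicted in the relevant classes for ",
                  "subject(s): ", paste(who, collapse = ", "), ".")
    if (on_empty == "error") abort(msg) else warn(msg)
  }
  out
}
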