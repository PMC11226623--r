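# Internal validation helpers shared across the scoring, backend and
# evaluation layers. Probability tables are plain tibbles with id columns
# (`subject_id`, `point_id`, optional `activity` and `stratum_*` tags) and one
# `p_<class>` column per class; the column order of the `p_` columns defines
# the class index, mirroring the declared vocabulary.

prob_col_names <- function(classes) paste0("p_", classes)

feature_col_names <- function(x) {
  nm <- names(x)
  nm[startsWith(nm, "f_")]
}

#' Extract the class vocabulary of a probability table
#'
#' The vocabulary is the ordered set of class names encoded by the `p_<class>`
#' columns. Column order defines the class index.
#'
#' @param probs A probability table (data frame with `p_<class>` columns).
#' @return Character vector of class names, in column order.
#' @export
prob_classes <- function(probs) {
  nm <- names(probs)
  sub("^p_", "", nm[startsWith(nm, "p_")])
}

# Resolve a user-supplied vocabulary against the p_ columns of a table.
resolve_classes <- function(probs, classes = NULL) {
  found <- prob_classes(probs)
  if (length(found) < 2) {
    abort("A probability table needs at least two `p_<class>` columns.")
  }
  if (is.null(classes)) return(found)
  classes <- as.character(classes)
  if (!identical(found, classes)) {
    abort(paste0(
      "Probability columns (", paste(found, collapse = ", "),
      ") do not match the declared vocabulary (",
      paste(classes, collapse = ", "), ") in order."
    ))
  }
  classes
}

# Validate a probability table and return list(meta = tibble, P = matrix).
# Rows whose sum deviates from 1 by more than `tolerance` are rejected;
# rows within tolerance are renormalized so each row sums to exactly 1.
check_prob_table <- function(probs, classes = NULL, tolerance = 1e-6) {
  if (!is.data.frame(probs)) abort("`probs` must be a data frame.")
  required <- c("subject_id", "point_id")
  missing_cols <- setdiff(required, names(probs))
  if (length(missing_cols) > 0) {
    abort(paste0("Probability table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  classes <- resolve_classes(probs, classes)
  probs <- as_tibble(probs)
  dup <- duplicated(probs[, c("subject_id", "point_id")])
  if (any(dup)) {
    abort(paste0("Duplicate (subject_id, point_id) pairs, e.g. row ",
                 which(dup)[1], "."))
  }
  P <- as.matrix(probs[, prob_col_names(classes)])
  storage.mode(P) <- "double"
  bad <- which(!is.finite(P), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Non-finite probability in row ", bad[1, 1],
                 " (point_id ", probs$point_id[bad[1, 1]], ")."))
  }
  neg <- which(P < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(paste0("Negative probability in row ", neg[1, 1],
                 " (point_id ", probs$point_id[neg[1, 1]], ")."))
  }
  rs <- rowSums(P)
  off <- which(abs(rs - 1) > tolerance)
  if (length(off) > 0) {
    abort(paste0("Row ", off[1], " (point_id ", probs$point_id[off[1]],
                 ") sums to ", format(rs[off[1]], digits = 8),
                 ", outside the simplex tolerance ", tolerance, "."))
  }
  P <- P / rs
  colnames(P) <- classes
  meta <- probs[, setdiff(names(probs), prob_col_names(classes))]
  list(meta = meta, P = P, classes = classes)
}

# Validate a clinically-relevant class set against a vocabulary.
check_relevant <- function(relevant, classes) {
  relevant <- as.character(relevant)
  if (length(relevant) == 0) abort("`relevant` must name at least one class.")
  if (anyDuplicated(relevant)) abort("`relevant` contains duplicate classes.")
  unknown <- setdiff(relevant, classes)
  if (length(unknown) > 0) {
    abort(paste0("Relevant class(es) not in the vocabulary: ",
                 paste(unknown, collapse = ", "), "."))
  }
  relevant
}

# Row-wise argmax with ties broken toward the earliest class (lowest column
# index), so results are reproducible across platforms.
argmax_first <- function(P) max.col(P, ties.method = "first")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (x < lower || x > upper) {
    abort(paste0("`", name, "` must be in [", lower, ", ", upper, "]."))
  }
  invisible(x)
}
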