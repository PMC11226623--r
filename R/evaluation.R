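# Evaluation of COBRA scores against a clinical scale: Pearson correlation
# with Fisher z-transform or bootstrap confidence intervals, per-stratum and
# per-partition breakdowns, and subject-level confidence-distribution
# summaries.

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around the standard product-moment correlation.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return The correlation coefficient, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("`x` and `y` must be finite and complete.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant input.")
  }
  cor(x, y)
}

#' Fisher z-transform confidence interval for a Pearson correlation
#'
#' The correlation is mapped through `atanh`, under which its sampling
#' distribution is approximately normal with standard error `1/sqrt(n - 3)`;
#' the symmetric normal interval is mapped back through `tanh`. This is the
#' package's default interval for all correlation reports.
#'
#' @param r Correlation coefficient with `|r| < 1`.
#' @param n Number of paired observations, at least 4.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`, both in `(-1, 1)`.
#' @examples
#' fisher_ci(0.814, 55)   # approx c(0.700, 0.888)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  check_scalar_number(r, "r")
  check_scalar_number(n, "n", lower = 4)
  check_scalar_number(level, "level", lower = .Machine$double.eps,
                      upper = 1 - .Machine$double.eps)
  if (abs(r) >= 1) abort("`r` must satisfy |r| < 1.")
  q <- qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  half <- q / sqrt(n - 3)
  c(low = tanh(z - half), high = tanh(z + half))
}

# Join a subject score table with a clinical table; drops incomplete pairs
# with a warning and returns the joined tibble.
join_scores_clinical <- function(scores, clinical) {
  for (nm in c("subject_id", "cobra_score")) {
    if (!nm %in% names(scores)) {
      abort(paste0("`scores` is missing column `", nm, "`."))
    }
  }
  for (nm in c("subject_id", "clinical_score")) {
    if (!nm %in% names(clinical)) {
      abort(paste0("`clinical` is missing column `", nm, "`."))
    }
  }
  if ("subset_tag" %in% names(scores) &&
      n_distinct(scores$subset_tag) > 1) {
    abort(paste0("`scores` mixes several subset tags; filter to one ",
                 "subset (or rescore pooled) before correlating."))
  }
  if (anyDuplicated(scores$subject_id)) {
    abort("`scores` has more than one row per subject.")
  }
  if (anyDuplicated(clinical$subject_id)) {
    abort("`clinical` has more than one row per subject.")
  }
  joined <- inner_join(
    as_tibble(scores)[, intersect(names(scores),
                                  c("subject_id", "cobra_score"))],
    as_tibble(clinical),
    by = "subject_id"
  )
  n_unmatched <- n_distinct(scores$subject_id) +
    n_distinct(clinical$subject_id) - 2 * nrow(joined)
  complete <- is.finite(joined$cobra_score) & is.finite(joined$clinical_score)
  n_incomplete <- sum(!complete)
  if (n_unmatched > 0 || n_incomplete > 0) {
    warn(paste0(n_unmatched, " subject(s) present in only one table and ",
                n_incomplete, " with a missing value were excluded."))
  }
  joined[complete, , drop = FALSE]
}

#' Percentile bootstrap confidence interval for the score-clinical correlation
#'
#' Resamples subjects with replacement `B` times, recomputes the Pearson
#' correlation on each resample, and returns the percentile interval.
#' Resamples in which either variable is constant are redrawn (at most 100
#' attempts per resample). Deterministic given `seed`.
#'
#' @param scores Subject score table ([score_cohort()] output).
#' @param clinical Clinical table with `subject_id` and `clinical_score`.
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, clinical, B = 2000, seed = 1L, level = 0.95) {
  check_scalar_number(B, "B", lower = 100)
  check_scalar_number(level, "level", lower = .Machine$double.eps,
                      upper = 1 - .Machine$double.eps)
  joined <- join_scores_clinical(scores, clinical)
  n <- nrow(joined)
  if (n < 4) abort("Need at least 4 joined subjects.")
  x <- joined$cobra_score
  y <- joined$clinical_score
  rs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      for (attempt in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 0 && sd(y[idx]) > 0) {
          return(cor(x[idx], y[idx]))
        }
      }
      abort("Could not draw a non-degenerate bootstrap resample.")
    }, numeric(1))
  })
  alpha <- 1 - level
  out <- unname(quantile(rs, c(alpha / 2, 1 - alpha / 2)))
  c(low = out[1], high = out[2])
}

new_cobra_correlation <- function(r, ci, n, ci_method, level,
                                  breakdown = NULL, data = NULL) {
  structure(
    list(r = r, ci_low = unname(ci[1]), ci_high = unname(ci[2]), n = n,
         ci_method = ci_method, level = level, breakdown = breakdown,
         data = data),
    class = "cobra_correlation"
  )
}

#' Correlation report between COBRA scores and a clinical assessment
#'
#' Joins the subject score table with the clinical table on `subject_id`,
#' excludes subjects missing from either side (with a warning), and reports
#' the Pearson correlation with a confidence interval.
#'
#' @inheritParams bootstrap_ci
#' @param ci_method `"fisher"` (default) or `"bootstrap"`.
#' @return A `cobra_correlation` object with fields `r`, `ci_low`, `ci_high`,
#'   `n`, `ci_method`, `level`, an optional `breakdown` tibble and the joined
#'   `data`. Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @export
correlation_report <- function(scores, clinical,
                               ci_method = c("fisher", "bootstrap"),
                               level = 0.95, B = 2000, seed = 1L) {
  ci_method <- arg_match(ci_method)
  joined <- join_scores_clinical(scores, clinical)
  if (nrow(joined) < 4) {
    abort(paste0("Only ", nrow(joined),
                 " complete subject pairs after the join; need at least 4."))
  }
  r <- pearson_r(joined$cobra_score, joined$clinical_score)
  ci <- if (abs(r) >= 1 - 1e-12) {
    # perfectly collinear data: the interval degenerates onto r
    c(low = r, high = r)
  } else if (ci_method == "fisher") {
    fisher_ci(r, nrow(joined), level)
  } else {
    bootstrap_ci(scores, clinical, B = B, seed = seed, level = level)
  }
  new_cobra_correlation(r, ci, nrow(joined), ci_method, level, data = joined)
}

#' Stratified correlation report
#'
#' Computes the pooled score-clinical correlation plus one entry per level of
#' a stratification covariate (e.g. a known confounder such as object color).
#' When a severity-independent confounder shifts confidences in one stratum,
#' the pooled correlation is diluted while the per-stratum correlations
#' recover it.
#'
#' @inheritParams correlation_report
#' @param stratum Name of the stratification column of `clinical`.
#' @return A `cobra_correlation` whose `breakdown` tibble has one row per
#'   stratum (`stratum`, `r`, `ci_low`, `ci_high`, `n`). Strata with fewer
#'   than 4 subjects are reported with `NA` entries and a warning.
#' @export
stratified_report <- function(scores, clinical, stratum,
                              ci_method = c("fisher", "bootstrap"),
                              level = 0.95, B = 2000, seed = 1L) {
  ci_method <- arg_match(ci_method)
  if (!is.character(stratum) || length(stratum) != 1 ||
      !stratum %in% names(clinical)) {
    abort("`stratum` must name a column of `clinical`.")
  }
  if (anyNA(clinical[[stratum]])) {
    abort(paste0("Stratum column `", stratum, "` has missing values."))
  }
  pooled <- correlation_report(scores, clinical, ci_method, level, B, seed)
  joined <- pooled$data
  levels_ <- sort(unique(as.character(joined[[stratum]])))
  rows <- purrr::map(levels_, function(lv) {
    sub <- joined[as.character(joined[[stratum]]) == lv, , drop = FALSE]
    if (nrow(sub) < 4) {
      warn(paste0("Stratum `", lv, "` has only ", nrow(sub),
                  " subject(s); reported as missing."))
      return(tibble(stratum = lv, r = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n = nrow(sub)))
    }
    r <- pearson_r(sub$cobra_score, sub$clinical_score)
    ci <- if (abs(r) >= 1 - 1e-12) {
      c(low = r, high = r)
    } else if (ci_method == "fisher") {
      fisher_ci(r, nrow(sub), level)
    } else {
      bootstrap_ci(sub[, c("subject_id", "cobra_score")], sub,
                   B = B, seed = seed, level = level)
    }
    tibble(stratum = lv, r = r, ci_low = unname(ci[1]),
           ci_high = unname(ci[2]), n = nrow(sub))
  })
  pooled$breakdown <- bind_rows(rows)
  pooled
}

#' Compare scores built from relevant, complement and all classes
#'
#' Scores every subject three ways — restricting the confidence average to
#' datapoints predicted in the clinically relevant classes, to their
#' complement, and to all classes — and reports the clinical correlation of
#' each. When the medical condition alters only the relevant classes, the
#' relevant-only score carries the severity signal and the complement score
#' does not.
#'
#' @inheritParams correlation_report
#' @param probs Probability table covering the test cohort.
#' @param relevant Clinically relevant class names; must leave a nonempty
#'   complement.
#' @param classes Optional declared vocabulary.
#' @return A named list of class `cobra_partition` with `cobra_correlation`
#'   elements `relevant`, `complement` and `all`. Subjects with zero points
#'   predicted in a partition are excluded from that report with a warning.
#' @export
class_partition_comparison <- function(probs, relevant, clinical,
                                       classes = NULL,
                                       ci_method = c("fisher", "bootstrap"),
                                       level = 0.95, B = 2000, seed = 1L) {
  ci_method <- arg_match(ci_method)
  vocab <- resolve_classes(probs, classes)
  relevant <- check_relevant(relevant, vocab)
  complement <- setdiff(vocab, relevant)
  if (length(complement) == 0) {
    abort("`relevant` covers the whole vocabulary; the complement is empty.")
  }
  one <- function(set) {
    s <- score_cohort(probs, set, classes = vocab, on_empty = "missing")
    correlation_report(s, clinical, ci_method, level, B, seed)
  }
  structure(
    list(relevant = one(relevant), complement = one(complement),
         all = one(vocab)),
    class = "cobra_partition"
  )
}

#' Confidence-distribution summary for a pair of subjects
#'
#' Builds normalised histograms of the per-datapoint confidences of two
#' subjects over the attainable range `[1/K, 1]` and reports their overlap
#' coefficient (the summed bin-wise minimum, in `[0, 1]`) together with each
#' subject's mean confidence. Individual confidences typically overlap
#' heavily between a healthy and an impaired subject even when the means —
#' and hence the COBRA scores — separate cleanly.
#'
#' @inheritParams predict_confidence
#' @param bins Number of equal-width histogram bins over `[1/K, 1]`
#'   (at least 2).
#' @return A list of class `cobra_confidence_summary` with `histograms`
#'   (tibble: `subject_id`, `bin`, `lower`, `upper`, `proportion`),
#'   `overlap` and `means` (tibble: `subject_id`, `mean_confidence`,
#'   `n_points`).
#' @export
confidence_distribution_summary <- function(probs, classes = NULL, bins = 20,
                                            simplex_tolerance = 1e-6) {
  check_scalar_number(bins, "bins", lower = 2)
  bins <- as.integer(bins)
  pred <- predict_confidence(probs, classes, simplex_tolerance)
  vocab <- attr(pred, "classes")
  subjects <- unique(pred$subject_id)
  if (length(subjects) != 2) {
    abort("`probs` must contain exactly two subjects.")
  }
  lo <- 1 / length(vocab)
  breaks <- seq(lo, 1, length.out = bins + 1)
  hist_one <- function(conf) {
    idx <- findInterval(conf, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = bins) / length(conf)
  }
  h <- purrr::map(subjects, function(s) hist_one(pred$confidence[pred$subject_id == s]))
  histograms <- bind_rows(purrr::map2(subjects, h, function(s, hh) {
    tibble(subject_id = s, bin = seq_len(bins),
           lower = breaks[-length(breaks)], upper = breaks[-1],
           proportion = hh)
  }))
  means <- pred %>%
    group_by(subject_id) %>%
    summarise(mean_confidence = mean(confidence), n_points = n(),
              .groups = "drop")
  structure(
    list(histograms = histograms, overlap = sum(pmin(h[[1]], h[[2]])),
         means = means),
    class = "cobra_confidence_summary"
  )
}

#' @export
print.cobra_correlation <- function(x, ...) {
  cat(sprintf("<cobra_correlation> r = %.3f, %d%% CI [%.3f, %.3f], n = %d (%s)\n",
              x$r, round(100 * x$level), x$ci_low, x$ci_high, x$n,
              x$ci_method))
  if (!is.null(x$breakdown)) {
    cat("breakdown:\n")
    print(x$breakdown)
  }
  invisible(x)
}

#' @rdname correlation_report
#' @param x A `cobra_correlation`.
#' @param ... Unused.
#' @export
tidy.cobra_correlation <- function(x, ...) {
  pooled <- tibble(stratum = "(pooled)", r = x$r, ci_low = x$ci_low,
                   ci_high = x$ci_high, n = x$n)
  if (is.null(x$breakdown)) pooled[, -1] else bind_rows(pooled, x$breakdown)
}

#' @rdname correlation_report
#' @export
glance.cobra_correlation <- function(x, ...) {
  tibble(r = x$r, ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
         ci_method = x$ci_method, level = x$level)
}

#' @export
print.cobra_partition <- function(x, ...) {
  cat("<cobra_partition> score-clinical correlation by class partition\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname class_partition_comparison
#' @param x A `cobra_partition`.
#' @param ... Unused.
#' @export
tidy.cobra_partition <- function(x, ...) {
  bind_rows(purrr::imap(x, function(rep, nm) {
    tibble(partition = nm, r = rep$r, ci_low = rep$ci_low,
           ci_high = rep$ci_high, n = rep$n)
  }))
}
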