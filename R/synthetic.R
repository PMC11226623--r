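# Synthetic cohort simulator. Emulates the statistical structure the COBRA
# score assumes: K class-conditional spherical-Gaussian feature distributions,
# a per-subject severity parameter that deforms only the clinically relevant
# class distributions, an optional severity-independent confounder shift, and
# a monotone severity-to-clinical-score mapping. Defaults mirror the
# stroke-rehabilitation setting at desk scale: 5 motion-primitive classes of
# which 3 (reach, reposition, transport) are clinically relevant, 25 healthy
# training subjects, 55 test subjects, 300 datapoints per subject, an
# FMA-like 0-66 clinical scale, and a severity shift of 3 noise standard
# deviations at maximum severity.

default_class_names <- c("reach", "reposition", "transport",
                         "stabilize", "idle")

#' Configuration of the synthetic cohort generator
#'
#' Class-conditional features are spherical Gaussians. By default the K class
#' means sit at `mean_separation` (in units of `noise_sd`) along the first K
#' feature axes. Severity `s` in `[0, 1]` translates each relevant class mean
#' by `s * shift_magnitude` along its shift direction; by default each
#' relevant class drifts toward the *next* relevant class (cyclically), the
#' way impairment blurs motion primitives among themselves without making
#' them resemble the non-motion classes. Non-relevant class distributions are
#' severity-independent by construction.
#'
#' The optional confounder assigns each test subject, with probability
#' `confounder$probability`, a severity-independent translation
#' `confounder$effect` applied to the datapoints of ALL classes — the
#' analogue of an acquisition artefact (dark objects, blur) that degrades the
#' evidence for the relevant classes regardless of impairment. The default
#' effect suppresses the feature components that signal the relevant classes
#' (magnitude `3 * noise_sd` along the negative normalised sum of the
#' relevant class means).
#'
#' @param class_names Ordered class vocabulary (length K >= 2).
#' @param feature_dim Feature dimension L (default 10; must be >= K for the
#'   default means).
#' @param class_priors Class sampling probabilities (default uniform).
#' @param class_means K x L matrix of class means. Default:
#'   `mean_separation * noise_sd` along the first K axes.
#' @param mean_separation Distance of each default class mean from the
#'   origin, in noise standard deviations (default 4, giving a near
#'   Bayes-separable healthy problem as for the paper-scale deep backends).
#' @param noise_sd Within-class standard deviation, isotropic (default 1).
#' @param relevant Clinically relevant class names (default reach,
#'   reposition, transport).
#' @param shift_magnitude Translation of each relevant class mean at
#'   severity 1, in feature units (default `3 * noise_sd`).
#' @param shift_directions Optional `length(relevant)` x L matrix of unit
#'   shift directions (rows ordered as `relevant`); default cyclic
#'   between-relevant-class directions.
#' @param n_train Number of healthy training subjects (default 25).
#' @param n_test Number of test subjects (default 55).
#' @param points_per_subject Datapoints per subject (default 300).
#' @param severity Per-test-subject severities in `[0, 1]`; default evenly
#'   spaced over `[0, 1]` including exact 0, so the test cohort contains
#'   healthy subjects.
#' @param clinical_scale `"fma"` (0-66, 66 = healthy) or `"kl"` (0-4,
#'   0 = healthy).
#' @param activities Activity tags sampled uniformly per datapoint.
#' @param confounder `NULL` (none), `TRUE` (defaults), or a list with
#'   `probability` and `effect` (length-L numeric).
#' @param covariance_inflation Optional factor `kappa`: at severity `s`
#'   relevant-class noise is scaled by `sqrt(1 + s * kappa)` — a second,
#'   dispersion-based impairment mode (default 0, off).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `cobra_cohort_config`.
#' @export
cohort_config <- function(class_names = default_class_names,
                          feature_dim = 10,
                          class_priors = NULL,
                          class_means = NULL,
                          mean_separation = 4,
                          noise_sd = 1,
                          relevant = c("reach", "reposition", "transport"),
                          shift_magnitude = 3,
                          shift_directions = NULL,
                          n_train = 25,
                          n_test = 55,
                          points_per_subject = 300,
                          severity = NULL,
                          clinical_scale = c("fma", "kl"),
                          activities = c("tabletop", "shelf", "glasses"),
                          confounder = NULL,
                          covariance_inflation = 0,
                          seed = 1L) {
  clinical_scale <- arg_match(clinical_scale)
  problems <- character()
  class_names <- as.character(class_names)
  K <- length(class_names)
  if (K < 2 || anyDuplicated(class_names)) {
    problems <- c(problems, "class_names must be >= 2 distinct names")
  }
  check_scalar_number(feature_dim, "feature_dim", lower = 1)
  L <- as.integer(feature_dim)
  check_scalar_number(noise_sd, "noise_sd", lower = .Machine$double.eps)
  check_scalar_number(shift_magnitude, "shift_magnitude", lower = 0)
  check_scalar_number(mean_separation, "mean_separation", lower = 0)
  check_scalar_number(covariance_inflation, "covariance_inflation", lower = 0)
  check_scalar_number(n_train, "n_train", lower = 1)
  check_scalar_number(n_test, "n_test", lower = 1)
  check_scalar_number(points_per_subject, "points_per_subject", lower = 1)

  if (is.null(class_priors)) class_priors <- rep(1 / K, K)
  if (length(class_priors) != K || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-8) {
    problems <- c(problems, "class_priors must be a length-K simplex vector")
  }
  if (is.null(class_means)) {
    if (L < K) {
      problems <- c(problems,
                    "feature_dim must be >= K for the default class means")
      class_means <- matrix(0, K, max(L, 1))
    } else {
      class_means <- matrix(0, K, L)
      for (k in seq_len(K)) class_means[k, k] <- mean_separation * noise_sd
    }
  }
  class_means <- as.matrix(class_means)
  if (!identical(dim(class_means), c(K, L))) {
    problems <- c(problems, "class_means must be a K x L matrix")
  }
  relevant <- as.character(relevant)
  if (length(relevant) == 0 || !all(relevant %in% class_names) ||
      anyDuplicated(relevant)) {
    problems <- c(problems,
                  "relevant must be a nonempty duplicate-free subset of class_names")
  }
  if (is.null(shift_directions) && length(problems) == 0) {
    # each relevant class drifts toward the next relevant class, cyclically
    ri <- match(relevant, class_names)
    nxt <- ri[c(seq_along(ri)[-1], 1)]
    shift_directions <- matrix(0, length(ri), L)
    for (i in seq_along(ri)) {
      d <- class_means[nxt[i], ] - class_means[ri[i], ]
      nrm <- sqrt(sum(d^2))
      shift_directions[i, ] <- if (nrm > 0) d / nrm else 0
    }
  }
  if (!is.null(shift_directions)) {
    shift_directions <- as.matrix(shift_directions)
    if (!identical(dim(shift_directions), c(length(relevant), L))) {
      problems <- c(problems,
                    "shift_directions must be length(relevant) x L")
    } else {
      nrms <- sqrt(rowSums(shift_directions^2))
      if (any(abs(nrms - 1) > 1e-6 & nrms > 0)) {
        problems <- c(problems, "shift_directions rows must be unit vectors")
      }
    }
  }
  if (isTRUE(confounder)) confounder <- list()
  if (!is.null(confounder)) {
    if (!is.list(confounder)) {
      problems <- c(problems, "confounder must be NULL, TRUE or a list")
      confounder <- list()
    }
    confounder$probability <- confounder$probability %||% 0.5
    if (is.null(confounder$effect) && length(problems) == 0) {
      u <- colSums(class_means[match(relevant, class_names), , drop = FALSE])
      nrm <- sqrt(sum(u^2))
      confounder$effect <- if (nrm > 0) -3 * noise_sd * u / nrm else rep(0, L)
    }
    if (length(confounder$effect) != L ||
        !all(is.finite(confounder$effect))) {
      problems <- c(problems, "confounder$effect must be a finite length-L vector")
    }
    if (confounder$probability < 0 || confounder$probability > 1) {
      problems <- c(problems, "confounder$probability must be in [0, 1]")
    }
  }
  if (is.null(severity)) {
    severity <- if (n_test == 1) 0 else seq(0, 1, length.out = n_test)
  }
  if (length(severity) != n_test || any(severity < 0 | severity > 1)) {
    problems <- c(problems,
                  "severity must give one value in [0, 1] per test subject")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid generator configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  structure(
    list(class_names = class_names, feature_dim = L,
         class_priors = as.numeric(class_priors), class_means = class_means,
         noise_sd = noise_sd, relevant = relevant,
         shift_magnitude = shift_magnitude,
         shift_directions = shift_directions,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         points_per_subject = as.integer(points_per_subject),
         severity = as.numeric(severity), clinical_scale = clinical_scale,
         activities = as.character(activities), confounder = confounder,
         covariance_inflation = covariance_inflation,
         seed = as.integer(seed)),
    class = "cobra_cohort_config"
  )
}

#' Map a latent severity to a clinical score
#'
#' The FMA-like scale runs from 66 (healthy) down to 0 (maximum impairment):
#' `round(66 * (1 - s))` with halves rounded away from zero. The KL-like
#' scale runs from 0 (healthy) to 4 (severe): `min(floor(5 * s), 4)`.
#'
#' @param severity Numeric vector in `[0, 1]`.
#' @param scale `"fma"` or `"kl"`.
#' @return Integer clinical scores.
#' @export
severity_to_clinical <- function(severity, scale = c("fma", "kl")) {
  scale <- arg_match(scale)
  if (!is.numeric(severity) || anyNA(severity) ||
      any(severity < 0 | severity > 1)) {
    abort("`severity` must lie in [0, 1].")
  }
  if (scale == "fma") {
    as.integer(floor(66 * (1 - severity) + 0.5))
  } else {
    as.integer(pmin(floor(5 * severity), 4))
  }
}

# Generate all datapoints of one subject at severity s.
simulate_subject <- function(cfg, subject_id, s, confounded) {
  K <- length(cfg$class_names)
  M <- cfg$points_per_subject
  L <- cfg$feature_dim
  k <- sample.int(K, M, replace = TRUE, prob = cfg$class_priors)
  X <- cfg$class_means[k, , drop = FALSE]
  rel_idx <- match(cfg$relevant, cfg$class_names)
  is_rel <- k %in% rel_idx
  if (s > 0 && cfg$shift_magnitude > 0 && any(is_rel)) {
    X[is_rel, ] <- X[is_rel, , drop = FALSE] +
      s * cfg$shift_magnitude *
        cfg$shift_directions[match(k[is_rel], rel_idx), , drop = FALSE]
  }
  sdv <- rep(cfg$noise_sd, M)
  if (cfg$covariance_inflation > 0) {
    sdv[is_rel] <- sdv[is_rel] * sqrt(1 + s * cfg$covariance_inflation)
  }
  X <- X + matrix(rnorm(M * L), M, L) * sdv
  if (confounded) {
    X <- sweep(X, 2, cfg$confounder$effect, "+")
  }
  act <- sample(cfg$activities, M, replace = TRUE)
  out <- tibble(
    subject_id = subject_id,
    point_id = sprintf("%s_p%04d", subject_id, seq_len(M)),
    activity = act,
    label = cfg$class_names[k]
  )
  feats <- as_tibble(as.data.frame(X))
  names(feats) <- paste0("f_", seq_len(L))
  dplyr::bind_cols(out, feats)
}

#' Simulate a healthy training cohort and a severity-graded test cohort
#'
#' Healthy training subjects are generated at severity 0; test subjects at
#' the configured severity grid (a severity-0 test subject follows the
#' identical generative path as a healthy training subject). True class
#' labels are attached to all subjects; test labels exist only for oracle
#' checks and are never used by the scoring pipeline.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cobra_cohort` with elements `train` and `test`
#'   (tibbles: `subject_id`, `point_id`, `activity`, `label`, `f_1 ... f_L`),
#'   `clinical` (tibble: `subject_id`, `clinical_score`, `group`,
#'   `true_severity`, and `confounder_stratum` when the confounder is
#'   enabled), and the `config`. Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cobra_cohort_config")) {
    abort("`config` must come from `cohort_config()`.")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    train <- bind_rows(purrr::map(seq_len(cfg$n_train), function(i) {
      simulate_subject(cfg, sprintf("healthy_%03d", i), 0, FALSE)
    }))
    confounded <- if (is.null(cfg$confounder)) {
      rep(FALSE, cfg$n_test)
    } else {
      stats::runif(cfg$n_test) < cfg$confounder$probability
    }
    test <- bind_rows(purrr::map(seq_len(cfg$n_test), function(i) {
      simulate_subject(cfg, sprintf("test_%03d", i), cfg$severity[i],
                       confounded[i])
    }))
  })
  clinical <- tibble(
    subject_id = sprintf("test_%03d", seq_len(cfg$n_test)),
    clinical_score = severity_to_clinical(cfg$severity, cfg$clinical_scale),
    group = ifelse(cfg$severity == 0, "healthy", "patient"),
    true_severity = cfg$severity
  )
  if (!is.null(cfg$confounder)) {
    clinical$confounder_stratum <- ifelse(confounded, "affected", "unaffected")
  }
  structure(list(train = train, test = test, clinical = clinical,
                 config = cfg),
            class = "cobra_cohort")
}

#' @export
print.cobra_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<cobra_cohort>\n")
  cat(sprintf("  train: %d healthy subjects x %d points\n",
              cfg$n_train, cfg$points_per_subject))
  cat(sprintf("  test:  %d subjects x %d points, severity in [%g, %g], %s scale\n",
              cfg$n_test, cfg$points_per_subject, min(cfg$severity),
              max(cfg$severity), cfg$clinical_scale))
  cat(sprintf("  classes: %s (relevant: %s)\n",
              paste(cfg$class_names, collapse = ", "),
              paste(cfg$relevant, collapse = ", ")))
  if (!is.null(cfg$confounder)) {
    cat(sprintf("  confounder enabled (probability %.2f)\n",
                cfg$confounder$probability))
  }
  invisible(x)
}
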