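# Shared fixtures and independent oracles. The oracles are deliberately
# written as explicit loops so they share no code path with the package.

# The worked 4-row, 3-class fixture: predictions (A, B, C, A), so with
# relevant = {A, B} the score is (0.7 + 0.6 + 0.5) / 3 = 0.6.
worked_probs <- function() {
  tibble::tibble(
    subject_id = "s1",
    point_id = as.character(1:4),
    p_A = c(0.7, 0.1, 0.2, 0.5),
    p_B = c(0.2, 0.6, 0.3, 0.25),
    p_C = c(0.1, 0.3, 0.5, 0.25)
  )
}

# Random probability table: n rows, K classes, one or more subjects.
random_probs <- function(n, K, subjects = "s1", class_names = LETTERS[1:K]) {
  P <- matrix(stats::rexp(n * K), n, K)
  P <- P / rowSums(P)
  out <- tibble::tibble(
    subject_id = sample(subjects, n, replace = TRUE),
    point_id = sprintf("pt%04d", seq_len(n))
  )
  for (k in seq_len(K)) out[[paste0("p_", class_names[k])]] <- P[, k]
  out
}

# Brute-force COBRA oracle: explicit loop over rows, no vector tricks.
brute_cobra <- function(probs, relevant) {
  classes <- sub("^p_", "", names(probs)[startsWith(names(probs), "p_")])
  total <- 0
  count <- 0
  for (i in seq_len(nrow(probs))) {
    p <- as.numeric(probs[i, paste0("p_", classes)])
    p <- p / sum(p)
    best <- 1
    for (k in seq_along(p)) if (p[k] > p[best]) best <- k
    if (classes[best] %in% relevant) {
      total <- total + p[best]
      count <- count + 1
    }
  }
  if (count == 0) NA_real_ else total / count
}

# Brute-force two-pass Pearson oracle.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Small labeled two-class training table with well-separated spherical
# Gaussian classes (mean distance `sep` in units of sd = 1).
two_class_train <- function(n, sep = 8, L = 4, seed = 1,
                            subjects = c("h1", "h2")) {
  withr::with_seed(seed, {
    k <- rep(1:2, length.out = n)
    mu <- rbind(c(rep(0, L)), c(sep, rep(0, L - 1)))
    X <- mu[k, , drop = FALSE] + matrix(stats::rnorm(n * L), n, L)
    out <- tibble::tibble(
      subject_id = sample(subjects, n, replace = TRUE),
      point_id = sprintf("pt%04d", seq_len(n)),
      label = c("a", "b")[k]
    )
    for (j in seq_len(L)) out[[paste0("f_", j)]] <- X[, j]
    out
  })
}

# Fit-once cache for the default synthetic cohort pipeline used by several
# property tests (kept at reduced size relative to the headline cohort).
small_cohort_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_train = 10, n_test = 30,
                           points_per_subject = 120, seed = 404)
      co <- simulate_cohort(cfg)
      model <- fit_backend(co$train, backend_config(),
                           classes = cfg$class_names)
      probs <- predict_proba(model, co$test)
      cache <<- list(cfg = cfg, cohort = co, model = model, probs = probs)
    }
    cache
  }
})
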