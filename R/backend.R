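# Reference backend: an L2-regularised multinomial softmax regression trained
# only on the healthy cohort. It stands behind the generic "classifier f"
# contract — any model emitting per-datapoint class probabilities can feed the
# scoring layer; this one exists so the whole pipeline runs deterministically
# at desk scale. The fit is a convex full-batch quasi-Newton (BFGS) minimisation
# of the penalised cross-entropy from a zero start, so refitting the same data
# with the same configuration reproduces identical probabilities.

#' Configuration of the reference backend
#'
#' @param l2_penalty Nonnegative ridge penalty on the slope weights (the
#'   intercepts are unpenalised), applied to the mean cross-entropy.
#' @param max_iterations Iteration cap for the BFGS optimiser.
#' @param convergence_tolerance Relative convergence tolerance of the
#'   optimiser.
#' @param context_window Number of neighbouring datapoints concatenated on
#'   each side of every datapoint (per subject, in row order) before the
#'   linear map, for sequence-like data; edges are repeat-padded so every
#'   subject keeps all its datapoints. With window `w` the effective feature
#'   length is `(2w + 1) * L`.
#' @param seed Integer recorded with the model for provenance. The fit itself
#'   is deterministic (zero initialisation, full-batch), so the seed does not
#'   influence the result.
#' @param standardize Standardise features to zero mean and unit variance
#'   using statistics of the healthy training data only (patient data are
#'   never seen at training time).
#' @return A list of class `cobra_backend_config`.
#' @export
backend_config <- function(l2_penalty = 1e-3, max_iterations = 1000,
                           convergence_tolerance = 1e-8, context_window = 0,
                           seed = 1L, standardize = TRUE) {
  check_scalar_number(l2_penalty, "l2_penalty", lower = 0)
  check_scalar_number(max_iterations, "max_iterations", lower = 1)
  check_scalar_number(convergence_tolerance, "convergence_tolerance",
                      lower = .Machine$double.eps)
  check_scalar_number(context_window, "context_window", lower = 0)
  structure(
    list(
      l2_penalty = l2_penalty,
      max_iterations = as.integer(max_iterations),
      convergence_tolerance = convergence_tolerance,
      context_window = as.integer(context_window),
      seed = as.integer(seed),
      standardize = isTRUE(standardize)
    ),
    class = "cobra_backend_config"
  )
}

# Extract, in column order, the f_* feature matrix of a training/feature table.
feature_matrix <- function(x) {
  cols <- feature_col_names(x)
  if (length(cols) == 0) abort("No `f_*` feature columns found.")
  X <- as.matrix(x[, cols])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, 1]
    abort(paste0("Non-finite feature value in row ", bad, "."))
  }
  X
}

# Concatenate each row with its w left and right neighbours within each
# subject block (rows in order of appearance); edges are repeat-padded.
window_features <- function(X, subject_id, w) {
  if (w == 0) return(X)
  blocks <- split(seq_len(nrow(X)), factor(subject_id, levels = unique(subject_id)))
  out <- matrix(0, nrow(X), (2 * w + 1) * ncol(X))
  for (rows in blocks) {
    m <- length(rows)
    for (off in -w:w) {
      src <- pmin(pmax(seq_len(m) + off, 1), m)
      cols <- (off + w) * ncol(X) + seq_len(ncol(X))
      out[rows, cols] <- X[rows[src], , drop = FALSE]
    }
  }
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Fit the reference backend on a labeled healthy cohort
#'
#' Pools all datapoints of the healthy training subjects and fits a
#' multinomial softmax regression by minimising the L2-penalised mean
#' cross-entropy with full-batch BFGS from a zero start. The model emits a
#' point on the K-simplex for any finite input.
#'
#' @param train Training table: data frame with `subject_id`, `point_id`,
#'   optional `activity`, a `label` column, and feature columns `f_1 ... f_L`.
#' @param config A [backend_config()].
#' @param classes Ordered class vocabulary. Defaults to the levels of `label`
#'   if it is a factor, otherwise to the unique labels in order of first
#'   appearance. A vocabulary class absent from the training labels triggers a
#'   warning (its probabilities are still emitted).
#' @return An object of class `cobra_backend` with the fitted weights,
#'   standardisation statistics, vocabulary, configuration echo and training
#'   diagnostics.
#' @seealso [predict_proba()], [write_backend()]
#' @export
fit_backend <- function(train, config = backend_config(), classes = NULL) {
  if (!is.data.frame(train) || nrow(train) == 0) {
    abort("`train` must be a nonempty data frame.")
  }
  if (!all(c("subject_id", "label") %in% names(train))) {
    abort("`train` needs `subject_id` and `label` columns.")
  }
  if (!inherits(config, "cobra_backend_config")) {
    abort("`config` must come from `backend_config()`.")
  }
  lab <- train$label
  classes <- classes %||% if (is.factor(lab)) levels(lab) else unique(as.character(lab))
  classes <- as.character(classes)
  if (length(classes) < 2) abort("Need at least two classes.")
  lab <- as.character(lab)
  unknown <- setdiff(unique(lab), classes)
  if (length(unknown) > 0) {
    abort(paste0("Label(s) outside the vocabulary: ",
                 paste(unknown, collapse = ", "), "."))
  }
  absent <- setdiff(classes, unique(lab))
  if (length(absent) > 0) {
    warn(paste0("Vocabulary class(es) absent from the training labels: ",
                paste(absent, collapse = ", "),
                ". Their probabilities are still emitted."))
  }
  if (length(unique(lab)) < 2) {
    abort("Training labels contain fewer than two distinct classes.")
  }

  X <- feature_matrix(train)
  L <- ncol(X)
  if (config$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  } else {
    ctr <- rep(0, L)
    scl <- rep(1, L)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xw <- window_features(Xs, train$subject_id, config$context_window)
  Xa <- cbind(1, Xw)
  D <- ncol(Xa)
  K <- length(classes)
  y <- match(lab, classes)
  Y <- matrix(0, nrow(Xa), K)
  Y[cbind(seq_along(y), y)] <- 1
  lam <- config$l2_penalty
  n_pts <- nrow(Xa)

  obj <- function(par) {
    W <- matrix(par, D, K)
    P <- softmax_rows(Xa %*% W)
    nll <- -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
    nll + lam / 2 * sum(W[-1, ]^2)
  }
  grd <- function(par) {
    W <- matrix(par, D, K)
    P <- softmax_rows(Xa %*% W)
    G <- crossprod(Xa, P - Y) / n_pts
    G[-1, ] <- G[-1, ] + lam * W[-1, ]
    as.vector(G)
  }
  fit <- optim(rep(0, D * K), obj, grd, method = "BFGS",
               control = list(maxit = config$max_iterations,
                              reltol = config$convergence_tolerance))
  W <- matrix(fit$par, D, K, dimnames = list(NULL, classes))
  P_train <- softmax_rows(Xa %*% W)
  structure(
    list(
      weights = W,
      classes = classes,
      config = config,
      center = ctr,
      scale = scl,
      n_features = L,
      diagnostics = list(
        final_loss = fit$value,
        evaluations = unname(fit$counts["function"]),
        converged = fit$convergence == 0,
        n_train_points = n_pts,
        n_train_subjects = n_distinct(train$subject_id),
        train_accuracy = mean(argmax_first(P_train) == y),
        train_log_likelihood = sum(log(pmax(
          P_train[cbind(seq_along(y), y)], 1e-300)))
      )
    ),
    class = "cobra_backend"
  )
}

#' Per-datapoint class probabilities from a fitted backend
#'
#' Applies the trained model to new feature rows and returns a valid
#' probability table (rows on the K-simplex, input order preserved).
#'
#' @param model A `cobra_backend` from [fit_backend()] or [read_backend()].
#' @param points Data frame with `subject_id`, `point_id`, optional tag
#'   columns, and the same `f_*` feature columns used in training.
#' @return A tibble with the id/tag columns of `points` plus one `p_<class>`
#'   column per vocabulary class.
#' @export
predict_proba <- function(model, points) {
  if (!inherits(model, "cobra_backend")) {
    abort("`model` must be a `cobra_backend`.")
  }
  if (!all(c("subject_id", "point_id") %in% names(points))) {
    abort("`points` needs `subject_id` and `point_id` columns.")
  }
  X <- feature_matrix(points)
  if (ncol(X) != model$n_features) {
    abort(paste0("Feature dimension mismatch: model expects ",
                 model$n_features, ", got ", ncol(X), "."))
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xw <- window_features(Xs, points$subject_id, model$config$context_window)
  P <- softmax_rows(cbind(1, Xw) %*% model$weights)
  meta <- as_tibble(points)[, setdiff(names(points), feature_col_names(points))]
  probs <- as_tibble(as.data.frame(P))
  names(probs) <- prob_col_names(model$classes)
  dplyr::bind_cols(meta, probs)
}

#' @export
predict.cobra_backend <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- arg_match(type)
  probs <- predict_proba(object, newdata)
  if (type == "prob") return(probs)
  predict_confidence(probs)
}

#' @export
print.cobra_backend <- function(x, ...) {
  cat("<cobra_backend> multinomial softmax regression\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", x$n_features,
      if (x$config$context_window > 0) {
        paste0("(context window ", x$config$context_window, ", effective ",
               (2 * x$config$context_window + 1) * x$n_features, ")")
      } else "", "\n")
  cat(sprintf("  trained on %d points from %d healthy subjects\n",
              x$diagnostics$n_train_points, x$diagnostics$n_train_subjects))
  cat(sprintf("  final penalised loss %.6f, training accuracy %.3f\n",
              x$diagnostics$final_loss, x$diagnostics$train_accuracy))
  invisible(x)
}

#' @rdname fit_backend
#' @param x A `cobra_backend`.
#' @param ... Unused.
#' @export
tidy.cobra_backend <- function(x, ...) {
  D <- nrow(x$weights)
  term <- c("(intercept)", paste0("x", seq_len(D - 1)))
  tibble(
    term = rep(term, times = ncol(x$weights)),
    class = rep(x$classes, each = D),
    estimate = as.vector(x$weights)
  )
}

#' @rdname fit_backend
#' @export
glance.cobra_backend <- function(x, ...) {
  tibble(
    n_train_points = x$diagnostics$n_train_points,
    n_train_subjects = x$diagnostics$n_train_subjects,
    n_classes = length(x$classes),
    final_loss = x$diagnostics$final_loss,
    train_accuracy = x$diagnostics$train_accuracy,
    train_log_likelihood = x$diagnostics$train_log_likelihood,
    converged = x$diagnostics$converged,
    l2_penalty = x$config$l2_penalty
  )
}
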