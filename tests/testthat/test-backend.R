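# Reference backend: deterministic L2-penalised softmax regression.

test_that("well-separated classes are classified near-perfectly on held-out data", {
  train <- two_class_train(500, sep = 8, seed = 5)
  test <- two_class_train(400, sep = 8, seed = 6, subjects = "t1")
  model <- fit_backend(train, backend_config())
  pred <- predict_confidence(predict_proba(model, test))
  expect_gte(mean(pred$predicted_class == test$label), 0.99)
})

test_that("refitting with identical data and config reproduces identical probabilities", {
  train <- two_class_train(200, sep = 4, seed = 11)
  test <- two_class_train(50, sep = 4, seed = 12, subjects = "t1")
  m1 <- fit_backend(train, backend_config())
  m2 <- fit_backend(train, backend_config())
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict_proba(m1, test), predict_proba(m2, test))
})

test_that("a point midway between two symmetric class means gets probability one half", {
  # exactly mirror-symmetric training set: x and -x with swapped labels
  withr::with_seed(3, {
    n <- 100; L <- 3
    X <- matrix(rnorm(n * L), n, L) + 4
    train <- tibble::tibble(
      subject_id = "h1",
      point_id = sprintf("p%03d", 1:(2 * n)),
      label = rep(c("a", "b"), each = n)
    )
    feats <- rbind(X, -X)
    for (j in 1:L) train[[paste0("f_", j)]] <- feats[, j]
  })
  model <- fit_backend(train, backend_config())
  mid <- tibble::tibble(subject_id = "t", point_id = "m",
                        f_1 = 0, f_2 = 0, f_3 = 0)
  p <- predict_proba(model, mid)
  expect_equal(p$p_a, 0.5, tolerance = 1e-6)
  expect_equal(p$p_b, 0.5, tolerance = 1e-6)
})

test_that("emitted rows always lie on the simplex, even for extreme inputs", {
  train <- two_class_train(150, sep = 4, seed = 21)
  model <- fit_backend(train, backend_config())
  pts <- tibble::tibble(subject_id = "t", point_id = as.character(1:3),
                        f_1 = c(1e6, -1e6, 0), f_2 = c(-1e6, 1e6, 0),
                        f_3 = 0, f_4 = c(1e5, 0, -1e5))
  P <- as.matrix(predict_proba(model, pts)[, c("p_a", "p_b")])
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
})

test_that("duplicated input rows produce identical output rows in preserved order", {
  train <- two_class_train(150, sep = 4, seed = 22)
  test <- two_class_train(10, sep = 4, seed = 23, subjects = "t1")
  dup <- dplyr::bind_rows(test, test[3, ] |> dplyr::mutate(point_id = "copy"))
  P <- predict_proba(fit_backend(train, backend_config()), dup)
  expect_equal(unlist(P[nrow(P), c("p_a", "p_b")]),
               unlist(P[3, c("p_a", "p_b")]))
  expect_identical(P$point_id[1:10], test$point_id)
})

test_that("a context window concatenates repeat-padded neighbours", {
  X <- matrix(1:6, nrow = 3)           # 3 points, 2 features
  W <- cobrascore:::window_features(X, rep("s", 3), 1)
  expect_identical(dim(W), c(3L, 6L))
  # edge rows repeat themselves on the missing side
  expect_equal(W[1, ], c(X[1, ], X[1, ], X[2, ]))
  expect_equal(W[2, ], c(X[1, ], X[2, ], X[3, ]))
  expect_equal(W[3, ], c(X[2, ], X[3, ], X[3, ]))
  # windows never cross subject boundaries
  W2 <- cobrascore:::window_features(X, c("s", "s", "t"), 1)
  expect_equal(W2[3, ], c(X[3, ], X[3, ], X[3, ]))
  expect_equal(W2[2, ], c(X[1, ], X[2, ], X[2, ]))
  # and the fitted weight matrix has (2w+1)L + 1 rows
  train <- two_class_train(120, sep = 4, seed = 31)
  model <- fit_backend(train, backend_config(context_window = 1))
  expect_identical(nrow(model$weights), 4L * 3L + 1L)
})

test_that("dimension mismatches and non-finite features are rejected", {
  train <- two_class_train(100, sep = 4, seed = 41)
  model <- fit_backend(train, backend_config())
  bad_dim <- tibble::tibble(subject_id = "t", point_id = "1",
                            f_1 = 0, f_2 = 0)
  expect_error(predict_proba(model, bad_dim), "expects 4, got 2")
  bad_val <- train
  bad_val$f_1[5] <- NaN
  expect_error(fit_backend(bad_val, backend_config()), "Non-finite feature")
})

test_that("a vocabulary class absent from the labels warns but is still emitted", {
  train <- two_class_train(100, sep = 4, seed = 51)
  expect_warning(
    model <- fit_backend(train, backend_config(), classes = c("a", "b", "ghost")),
    "absent from the training labels"
  )
  p <- predict_proba(model, train[1:3, ])
  expect_true(all(c("p_a", "p_b", "p_ghost") %in% names(p)))
  expect_equal(rowSums(as.matrix(p[, c("p_a", "p_b", "p_ghost")])),
               rep(1, 3), tolerance = 1e-12)
})

test_that("a tenfold larger ridge penalty never raises the training log-likelihood", {
  train <- two_class_train(200, sep = 2, seed = 61)
  for (lam in c(1e-3, 1e-2, 1e-1)) {
    ll1 <- fit_backend(train, backend_config(l2_penalty = lam)
                       )$diagnostics$train_log_likelihood
    ll2 <- fit_backend(train, backend_config(l2_penalty = 10 * lam)
                       )$diagnostics$train_log_likelihood
    expect_lte(ll2, ll1 + 1e-6)
  }
})

test_that("fitted probabilities agree with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  # overlapping classes keep the unpenalised MLE finite
  train <- two_class_train(400, sep = 2, L = 2, seed = 71)
  model <- fit_backend(train, backend_config(l2_penalty = 0,
                                             standardize = FALSE))
  df <- data.frame(label = factor(train$label, levels = c("a", "b")),
                   f_1 = train$f_1, f_2 = train$f_2)
  ref <- nnet::multinom(label ~ f_1 + f_2, df, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  grid <- tibble::tibble(subject_id = "g", point_id = as.character(1:5),
                         f_1 = seq(-1, 3, 1), f_2 = seq(1, -3, -1))
  p_ours <- predict_proba(model, grid)$p_b
  p_ref <- as.numeric(predict(ref, grid, type = "probs"))
  expect_equal(p_ours, p_ref, tolerance = 1e-3)
})

test_that("the trained backend loses confidence on severity-shifted relevant points", {
  cfg <- cohort_config(n_train = 10, n_test = 8,
                       points_per_subject = 150, shift_magnitude = 4,
                       severity = rep(c(0, 1), each = 4), seed = 314)
  co <- simulate_cohort(cfg)
  model <- fit_backend(co$train, backend_config(), classes = cfg$class_names)
  pred <- predict_confidence(predict_proba(model, co$test))
  pred$label <- co$test$label
  pred$severity <- co$clinical$true_severity[
    match(pred$subject_id, co$clinical$subject_id)]
  rel <- pred$label %in% cfg$relevant
  healthy <- mean(pred$confidence[rel & pred$severity == 0])
  shifted <- mean(pred$confidence[rel & pred$severity == 1])
  expect_gte(healthy - shifted, 0.05)
})

test_that("tidy and glance summarise the fit", {
  train <- two_class_train(100, sep = 4, seed = 81)
  model <- fit_backend(train, backend_config())
  td <- tidy(model)
  expect_identical(nrow(td), (4L + 1L) * 2L)
  gl <- glance(model)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_identical(gl$n_train_points, 100L)
})
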