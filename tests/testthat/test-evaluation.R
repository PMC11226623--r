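# Evaluation layer: correlation, intervals, stratification, partitions and
# confidence-distribution summaries.

test_that("pearson_r reproduces hand-computed values and matches a brute-force oracle", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(3:40, 1)
      x <- rnorm(n); y <- rnorm(n)
      expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
    }
  })
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("fisher_ci is symmetric at zero and rejects degenerate input", {
  ci <- fisher_ci(0, 28)
  c_half <- tanh(qnorm(0.975) / 5)
  expect_equal(unname(ci), c(-c_half, c_half), tolerance = 1e-12)
  expect_error(fisher_ci(1, 30), "\\|r\\| < 1")
  expect_error(fisher_ci(0.5, 3), "must be in")
})

test_that("fisher_ci width shrinks monotonically in n and collapses onto r", {
  widths <- vapply(c(5, 10, 30, 100, 1000), function(n) {
    ci <- fisher_ci(0.6, n); ci["high"] - ci["low"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  big <- fisher_ci(0.6, 1e7)
  expect_equal(unname(big), c(0.6, 0.6), tolerance = 1e-3)
  # the interval straddles r at any usable n
  ci <- fisher_ci(0.6, 10)
  expect_lt(ci["low"], 0.6); expect_gt(ci["high"], 0.6)
})

test_that("bootstrap interval is deterministic, degenerates correctly, and tracks Fisher under normality", {
  scores <- tibble::tibble(subject_id = sprintf("s%02d", 1:10),
                           cobra_score = seq(0.5, 0.95, length.out = 10))
  clinical <- tibble::tibble(subject_id = scores$subject_id,
                             clinical_score = 2 * scores$cobra_score + 1)
  ci <- bootstrap_ci(scores, clinical, B = 200, seed = 9)
  expect_equal(unname(ci), c(1, 1))
  expect_identical(bootstrap_ci(scores, clinical, B = 200, seed = 9),
                   bootstrap_ci(scores, clinical, B = 200, seed = 9))
  # bivariate normal fixture, n = 55, true rho = 0.8
  withr::with_seed(55, {
    n <- 55
    x <- rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  })
  sc <- tibble::tibble(subject_id = as.character(1:55), cobra_score = x)
  cl <- tibble::tibble(subject_id = as.character(1:55), clinical_score = y)
  boot <- bootstrap_ci(sc, cl, B = 2000, seed = 10)
  fish <- fisher_ci(pearson_r(x, y), 55)
  expect_lt(max(abs(boot - fish)), 0.05)
})

test_that("correlation_report joins on subject, drops incomplete pairs with a warning", {
  scores <- tibble::tibble(subject_id = sprintf("s%02d", 1:8),
                           cobra_score = seq(0.4, 0.9, length.out = 8))
  clinical <- tibble::tibble(subject_id = sprintf("s%02d", 1:9),
                             clinical_score = c(10 + 3 * seq_len(8), 50))
  expect_warning(rep <- correlation_report(scores, clinical),
                 "excluded")
  expect_equal(rep$r, 1.0)           # affine increasing transform
  expect_identical(rep$n, 8L)
  expect_lte(rep$ci_low, rep$r); expect_gte(rep$ci_high, rep$r)
  expect_error(correlation_report(scores[1:3, ], clinical[1:3, ]),
               "at least 4")
  gl <- glance(rep)
  expect_identical(gl$ci_method, "fisher")
})

test_that("a constant stratum reproduces the pooled report; small strata are flagged", {
  withr::with_seed(23, {
    n <- 12
    scores <- tibble::tibble(subject_id = as.character(1:n),
                             cobra_score = runif(n, 0.5, 1))
    clinical <- tibble::tibble(
      subject_id = as.character(1:n),
      clinical_score = 60 * scores$cobra_score + rnorm(n, sd = 2),
      site = "one"
    )
  })
  rep <- stratified_report(scores, clinical, "site")
  expect_identical(nrow(rep$breakdown), 1L)
  expect_equal(rep$breakdown$r, rep$r)
  expect_equal(rep$breakdown$n, rep$n)
  clinical$site <- c(rep("big", 9), rep("tiny", 3))
  expect_warning(rep2 <- stratified_report(scores, clinical, "site"),
                 "reported as missing")
  expect_true(is.na(rep2$breakdown$r[rep2$breakdown$stratum == "tiny"]))
  # permutation of subject order leaves all entries unchanged
  perm <- sample(nrow(scores))
  rep3 <- suppressWarnings(
    stratified_report(scores[perm, ], clinical[sample(nrow(clinical)), ],
                      "site"))
  expect_equal(tidy(rep3), suppressWarnings(tidy(rep2)))
})

test_that("partition comparison degenerates correctly when relevant covers the vocabulary", {
  pl <- small_cohort_pipeline()
  expect_error(
    class_partition_comparison(pl$probs, pl$cfg$class_names,
                               pl$cohort$clinical),
    "complement is empty"
  )
})

test_that("partition reports share the joined subject set and expose tidy output", {
  pl <- small_cohort_pipeline()
  cmp <- suppressWarnings(
    class_partition_comparison(pl$probs, pl$cfg$relevant,
                               pl$cohort$clinical))
  td <- tidy(cmp)
  expect_identical(td$partition, c("relevant", "complement", "all"))
  expect_true(all(td$n == td$n[1]))
  # relevant-only equals rescoring with the relevant set directly
  direct <- correlation_report(
    score_cohort(pl$probs, pl$cfg$relevant), pl$cohort$clinical)
  expect_equal(cmp$relevant$r, direct$r, tolerance = 1e-12)
})

test_that("confidence histograms are normalized and the overlap coefficient behaves", {
  # identical point sets -> overlap 1
  a <- random_probs(40, 2, subjects = "a")
  b <- a; b$subject_id <- "b"; b$point_id <- paste0(b$point_id, "b")
  s <- confidence_distribution_summary(dplyr::bind_rows(a, b), bins = 10)
  expect_equal(s$overlap, 1.0)
  expect_equal(sum(s$histograms$proportion[s$histograms$subject_id == "a"]), 1)
  # disjoint confidence supports -> overlap 0
  hi <- tibble::tibble(subject_id = "a", point_id = as.character(1:5),
                       p_A = 0.95, p_B = 0.05)
  lo <- tibble::tibble(subject_id = "b", point_id = as.character(6:10),
                       p_A = 0.55, p_B = 0.45)
  s2 <- confidence_distribution_summary(dplyr::bind_rows(hi, lo), bins = 4)
  expect_equal(s2$overlap, 0.0)
  expect_equal(s2$means$mean_confidence, c(0.95, 0.55))
  # half-overlapping histograms (0.5, 0.5, 0) vs (0, 0.5, 0.5) -> 0.5
  # K = 2 so the range is [0.5, 1]; bins at [.5,.666), [.666,.833), [.833,1]
  s1_conf <- c(0.55, 0.6, 0.7, 0.75)       # two in bin 1, two in bin 2
  s2_conf <- c(0.7, 0.75, 0.9, 0.95)       # two in bin 2, two in bin 3
  mk <- function(id, conf, off) tibble::tibble(
    subject_id = id, point_id = as.character(seq_along(conf) + off),
    p_A = conf, p_B = 1 - conf)
  s3 <- confidence_distribution_summary(
    dplyr::bind_rows(mk("a", s1_conf, 0), mk("b", s2_conf, 10)), bins = 3)
  expect_equal(s3$overlap, 0.5)
  expect_error(
    confidence_distribution_summary(a, bins = 10), "exactly two subjects")
})
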