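---
title: "COBRA scoring: model, backend and synthetic-cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COBRA scoring: model, backend and synthetic-cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `cobrascore`, the
numerical choices made in the implementation, and the design of the
synthetic cohort generator used to exercise the pipeline. Code chunks are
shown but not evaluated; the README contains an executed walkthrough.

## 1. The score

### Model and assumptions

A backend classifier estimates class posteriors `p(y = k | x)` for `K`
classes, trained **only on data from healthy subjects**. The working
assumption is that impairment moves a subject's datapoints away from the
healthy class-conditional distributions, which a well-calibrated classifier
expresses as *flattened* posteriors — lower maximum probability — rather
than as confident misclassification. Under that assumption, average
confidence is a monotone proxy for closeness-to-healthy.

For subject datapoints `x_1, …, x_M`:

* `ŷ_i = argmax_k p(y = k | x_i)` and `conf_i = p(y = ŷ_i | x_i)`;
* with a set `CR` of clinically relevant classes, the score is the mean of
  `conf_i` over `I = { i : ŷ_i ∈ CR }`.

Restricting to `CR` matters because not every class is informative about
the condition: for upper-limb impairment, confidence on *idle* frames says
little, and pooling it in dilutes the signal. `cobra_score()` therefore
takes `relevant` as a required argument, and
`class_partition_comparison()` quantifies the contrast between scoring on
the relevant classes, their complement, and all classes.

Each `conf_i` lies in `[1/K, 1]` (a softmax maximum cannot fall below
uniform), so the score does too; healthy subjects sit near 1. Averaging
`M` approximately independent datapoints shrinks the sampling variance of
the score like `1/M`, which the test suite checks empirically across
`M ∈ {10, 100, 1000}`.

### Numerical conventions

* Probability rows must sum to 1 within `simplex_tolerance` (default
  `1e-6`); rows inside the tolerance are renormalised, rows outside it are
  an error naming the offending row. Values outside `[0, 1]` are always an
  error.
* Argmax ties break to the **earliest class in the declared vocabulary**
  (`max.col(ties.method = "first")`), so scoring is deterministic and
  independent of row order.
* A subject with no datapoint predicted in `CR` has no defined score;
  `on_empty = "error"` (default) fails loudly, `on_empty = "missing"`
  returns `NA` (used by the complement-partition analysis, where empty
  partitions are expected and reported).

## 2. The reference backend

Deployed systems use task-specific deep backbones (action segmentation
networks for wearable-sensor sequences, video models, segmentation
U-Nets for MRI). Those are out of scope here; the package ships a
transparent reference backend so the full pipeline is runnable and
testable end-to-end: L2-penalised multinomial softmax regression.

```{r}
backend_config(
  l2_penalty = 1e-3,          # ridge penalty on weights (not intercepts)
  max_iterations = 1000,
  convergence_tolerance = 1e-8,
  context_window = 0,         # w frames either side -> (2w+1)L features
  standardize = TRUE
)
```

Design decisions:

* **Determinism.** The fit is full-batch BFGS (`stats::optim`) from a zero
  initialisation, so the same training table always yields bit-identical
  weights and probabilities. The test suite asserts this, and asserts that
  a model serialised to JSON and reloaded reproduces probabilities
  exactly (numeric arrays are stored as `%.17g` strings for bit-exact
  round-trips).
* **Penalisation.** Weights are ridge-penalised, intercepts are not; the
  penalty makes the (over-parameterised) softmax objective strictly convex
  and the optimum unique. A 10× larger penalty can only decrease the
  unpenalised training log-likelihood, which is tested.
* **Standardisation** uses means and standard deviations of the *healthy
  training set only* — test subjects must be transformed by healthy
  statistics or the impairment signal would be partially normalised away.
* **Context windows** (`context_window = w`) concatenate the `w`
  preceding and following frames within a subject's block, with
  repeat-padding at block edges; windows never cross subject boundaries.
  This is a minimal stand-in for the temporal receptive field of sequence
  backbones.
* With the penalty at 0 and standardisation off, the fitted probabilities
  agree with `nnet::multinom` on small fixtures to `1e-3`, which serves as
  the independent cross-check of the implementation.

## 3. Evaluation

Validation is correlational: the score is compared with a clinical scale
across subjects via Pearson's r (`stats::cor`). Two interval methods are
provided:

* `fisher_ci(r, n, level)` — the Fisher z-transform interval
  `tanh(atanh(r) ± z_{α/2} / sqrt(n − 3))`, the default in
  `correlation_report()`. It is undefined at `|r| = 1` and errors there;
  the report functions clamp the interval to the point `[r, r]` in that
  degenerate case.
* `bootstrap_ci()` — a percentile interval over subject-level resamples
  (default `B = 2000`), deterministic given its seed; degenerate resamples
  (zero variance in either variable) are redrawn.

`stratified_report()` computes the pooled correlation plus a per-stratum
breakdown for a labelled confounder (strata with fewer than 4 subjects
get `NA` with a warning, since `fisher_ci` needs `n > 3`).

## 4. The synthetic cohort generator

Real cohorts (wearable-sensor or video recordings of structured
rehabilitation activities; knee MRI with radiographic grades) cannot ship
with the package, so the generator produces feature-level cohorts whose
*mechanisms* mirror the phenomena the score relies on. Its defaults are
the package's canonical study conditions and are used as-is by the test
suite and `scripts/acceptance.R`.

```{r}
cohort_config(
  n_train = 25, n_test = 55,       # healthy training cohort / mixed test cohort
  points_per_subject = 300,
  feature_dim = 10, n_classes = 5,
  class_names = c("reach", "reposition", "transport", "stabilize", "idle"),
  relevant   = c("reach", "reposition", "transport"),
  class_separation = 4,            # healthy class means at 4 sigma
  shift_magnitude = 3,             # delta: feature shift at severity 1
  clinical_scale = "fma",          # or "kl"
  confounder = FALSE
)
```

### What it emulates

* **Healthy structure.** Each class `k` is an isotropic Gaussian in
  feature space, mean `4σ` along the `k`-th axis: well-separated, so a
  healthy-trained softmax is accurate and confident (the geometry of the
  "healthy manifold").
* **Severity.** A subject with severity `s ∈ [0, 1]` has each *relevant*
  class mean shifted by `s · δ` toward the **next relevant class in a
  cycle** (reach → reposition → transport → reach). The cyclic direction
  is deliberate: a linear softmax only loses confidence for displacement
  inside its discriminative subspace, and blurring relevant primitives
  *into each other* models impairment degrading the distinctions among
  arm movements while leaving the complement classes (stabilize, idle)
  clean — which is exactly what gives the relevant-class partition its
  advantage over the complement partition. Shifting toward the complement
  centroid instead would leak misclassified relevant points into the
  complement partition and blur that contrast.
* **Clinical scales.** Severity maps to an FMA-like scale by
  `floor(66 (1 − s) + 0.5)` (half-away-from-zero, so endpoint behaviour is
  platform-stable; base `round()` is half-to-even) or to a KL-like grade
  by `min(floor(5 s), 4)`, giving positive and negative correlation
  directions respectively.
* **Confounder.** With `confounder = TRUE`, each test subject is
  independently "affected" with probability 0.5; all of an affected
  subject's points receive an additional severity-independent shift of
  `3σ` along `−unit(Σ_{k ∈ CR} μ_k)` — a uniform suppression of the
  feature evidence for relevant classes, the analogue of an
  acquisition-level nuisance (e.g. poor sensor placement or a visually
  degraded recording) that lowers confidence without reflecting
  impairment. Because it acts through the complement-class competitors
  and combines additively with the severity mechanism, stratifying by the
  recorded `confounder_stratum` recovers the per-stratum correlation —
  the behaviour `stratified_report()` is designed to expose.
* **Problem sizes.** The default 25 healthy training subjects, 55 test
  subjects and the alternative `n_test = 435` KL cohort are the package's
  canonical small-movement-cohort and large-imaging-cohort settings; 300
  points per subject keeps per-subject score noise small relative to the
  severity effect.

### What it does not emulate

* No raw signals: the generator emits classifier-ready feature vectors,
  not IMU time series, video, or images; the deep feature extractors are
  explicitly out of scope.
* No temporal autocorrelation within a subject (points are i.i.d. given
  the class), so `context_window > 0` gains nothing on synthetic data.
* No calibration error: the backend's softmax probabilities are used
  as-is, and the generator does not model a systematically over- or
  under-confident backend.
* No label noise in the clinical scale beyond the deterministic
  severity-to-scale mapping.

Determinism: `simulate_cohort()` is a pure function of its config
(`withr::with_seed`), and cohorts written with `write_cohort()` round-trip
byte-identically — CSV readers use base `read.csv` (correctly-rounded
`strtod`) beneath tibble-returning wrappers precisely to preserve the
write → read → write byte-identity invariant.

## 5. Limitations

* Confidence is a proxy, not a measurement: any distribution shift —
  device change, population shift, degraded acquisition — lowers
  confidence just as impairment does. The confounder machinery
  (`stratified_report()`) mitigates only *labelled* nuisances.
* The score inherits the backend's calibration; a badly calibrated
  backend can compress or distort the score's dynamic range.
* Validation is correlational across a cohort. A single subject's score
  has no absolute clinical meaning without a reference cohort.
* The reference backend is linear in its features; conclusions drawn from
  synthetic cohorts are statements about the pipeline's mechanics, not
  evidence about any particular clinical population.
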