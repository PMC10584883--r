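test_that("LV merges into WK and stages map to ordinals deepest-first", {
  expect_equal(merge_and_encode(c("LV", "WK", "N3")), c(5L, 5L, 1L))
  expect_equal(merge_and_encode(rep("N2", 4)), rep(2L, 4))
  expect_length(merge_and_encode(character(0)), 0)
  expect_equal(merge_and_encode(c("N3", "N2", "N1", "REM", "WK")), 1:5)
  expect_error(merge_and_encode(c("N2", "N4")), "N4")
})

test_that("confusion matrix tallies epochs and conserves their count", {
  cm <- confusion_matrix5(1:5, 1:5)
  expect_equal(diag(cm), setNames(rep(1L, 5), c("N3", "N2", "N1", "REM", "WK")))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm2 <- confusion_matrix5(c(1, 1, 2), c(1, 2, 2))
  expect_equal(cm2[1, 1], 1L)
  expect_equal(cm2[1, 2], 1L)
  expect_equal(cm2[2, 2], 1L)
  expect_equal(sum(cm2), 3)

  set.seed(1)
  t5 <- sample(1:5, 300, replace = TRUE)
  p5 <- sample(1:5, 300, replace = TRUE)
  expect_equal(sum(confusion_matrix5(t5, p5)), 300)
  expect_error(confusion_matrix5(1:4, 1:5), "mismatch")
})

test_that("printed metric formulas agree with a brute-force epoch tally", {
  # perfect prediction
  expect_equal(unname(overall_metrics(confusion_matrix5(1:5, 1:5))),
               c(1, 1, 1))
  pc <- per_class_metrics(confusion_matrix5(rep(1:5, 3), rep(1:5, 3)))
  expect_true(all(abs(as.matrix(pc[, 2:4]) - 1) < 1e-12))

  # oracle equivalence on 1000 fuzzed matrices
  set.seed(2)
  for (i in 1:1000) {
    cm <- matrix(rpois(25, 4), 5, 5)
    # guarantee every class appears in truth and prediction
    diag(cm) <- diag(cm) + 1
    dimnames(cm) <- list(true = c("N3", "N2", "N1", "REM", "WK"),
                         pred = c("N3", "N2", "N1", "REM", "WK"))
    class(cm) <- c("confusion_matrix5", class(cm))
    seqs <- expand_cm(cm)
    want <- oracle_metrics_from_sequences(seqs$t5, seqs$p5)
    got <- overall_metrics(cm)
    expect_equal(unname(got), unname(want$overall), tolerance = 1e-12)
    gpc <- per_class_metrics(cm)
    for (cc in 1:5)
      expect_equal(unname(unlist(gpc[cc, 2:4])),
                   unname(want$per_class[[as.character(cc)]]),
                   tolerance = 1e-12)
    # bounds
    expect_gte(got["accuracy"], 0); expect_lte(got["accuracy"], 1)
    expect_gte(got["kappa"], -1); expect_lte(got["kappa"], 1)
    expect_gte(got["f1"], 0); expect_lte(got["f1"], 1)
  }
})

test_that("uniform-random balanced prediction has chance-level kappa", {
  set.seed(3)
  n <- 1e6
  t5 <- sample(1:5, n, replace = TRUE)
  p5 <- sample(1:5, n, replace = TRUE)
  m <- overall_metrics(confusion_matrix5(t5, p5))
  expect_lt(abs(m["kappa"]), 0.005)
  expect_lt(abs(m["accuracy"] - 0.5), 0.005)   # S -> 0.2, P -> 0.8
})

test_that("metrics are invariant to epoch order and to when LV is merged", {
  set.seed(4)
  lab <- sample(STAGES6, 400, replace = TRUE)
  prd <- sample(STAGES6, 400, replace = TRUE)
  m1 <- overall_metrics(confusion_matrix5(lab, prd))
  perm <- sample(400)
  expect_equal(overall_metrics(confusion_matrix5(lab[perm], prd[perm])), m1)
  # merge before vs inside confusion construction
  lab2 <- ifelse(lab == "LV", "WK", lab)
  prd2 <- ifelse(prd == "LV", "WK", prd)
  expect_equal(overall_metrics(confusion_matrix5(lab2, prd2)), m1)
})

test_that("degenerate classes yield NaN with a warning, not silent zeros", {
  # class N3 (ordinal 1) absent from truth and prediction
  t5 <- rep(2:5, 10); p5 <- rep(2:5, 10)
  cm <- confusion_matrix5(t5, p5)
  expect_warning(pc <- per_class_metrics(cm), "undefined")
  expect_true(is.nan(pc$accuracy[pc$class == "N3"]))
  expect_false(anyNA(pc$accuracy[pc$class != "N3"]))
})

test_that("conventional Cohen's kappa stays a distinct diagnostic", {
  cm <- confusion_matrix5(rep(1:5, 8), rep(1:5, 8))
  expect_equal(kappa_cohen(cm), 1)
  # skewed marginals: chance-corrected kappa < pooled-Youden kappa
  t5 <- c(rep(2, 90), rep(5, 10))
  p5 <- c(rep(2, 95), rep(5, 5))
  cmx <- confusion_matrix5(t5, p5)
  expect_false(isTRUE(all.equal(kappa_cohen(cmx),
                                unname(overall_metrics(cmx)["kappa"]))))
})

test_that("cohort summaries aggregate per-subject metrics and covariates", {
  h1 <- hypnogram(rep(c("N2", "WK"), 20))
  pairs <- list(A = list(true = h1, pred = h1),
                B = list(true = h1, pred = h1))
  cs <- cohort_summary(pairs)
  expect_equal(unname(cs$mean), c(1, 1, 1))
  expect_equal(unname(cs$sd), c(0, 0, 0))

  single <- cohort_summary(pairs[1])
  expect_true(all(is.na(single$sd)))

  # covariate correlation equals the closed-form Pearson r
  set.seed(5)
  mk <- function(err) {
    lab <- sample(STAGES5, 200, replace = TRUE)
    prd <- ifelse(runif(200) < err, sample(STAGES5, 200, replace = TRUE), lab)
    list(true = hypnogram(lab), pred = hypnogram(prd))
  }
  errs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pr <- lapply(errs, mk)
  names(pr) <- paste0("S", 1:5)
  cov <- data.frame(severity = errs)
  cs2 <- cohort_summary(pr, covariates = cov)
  acc <- cs2$per_subject$accuracy
  want_r <- sum((acc - mean(acc)) * (errs - mean(errs))) /
    sqrt(sum((acc - mean(acc))^2) * sum((errs - mean(errs))^2))
  got_r <- cs2$correlations$r[cs2$correlations$metric == "accuracy"]
  expect_equal(got_r, want_r, tolerance = 1e-12)

  expect_error(cohort_summary(pr, covariates = data.frame(x = 1:2)),
               "match the number of subjects")
})
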