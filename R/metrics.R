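#' Merge LV into WK and encode stages as ordinal values
#'
#' Before any agreement metric, the "out of bed" class is combined with
#' wake, and the five remaining stages are assigned ordinal values from
#' deepest to lightest: `N3 = 1, N2 = 2, N1 = 3, REM = 4, WK = 5`.
#'
#' @param labels a [hypnogram()] or character vector over [STAGES6]
#' @return integer vector in `1..5`
#' @export
merge_and_encode <- function(labels) {
  labels <- toupper(as.character(labels))
  bad <- setdiff(unique(labels), STAGES6)
  if (length(bad) > 0) stop("unknown stage label: ", bad[1])
  labels[labels == "LV"] <- "WK"
  unname(c(N3 = 1L, N2 = 2L, N1 = 3L, REM = 4L, WK = 5L)[labels])
}

ORDINAL_CLASSES <- c("N3", "N2", "N1", "REM", "WK")

#' 5x5 epoch confusion matrix
#'
#' Rows are the true ordinal class, columns the predicted class
#' (`N3, N2, N1, REM, WK` = 1..5 after the LV merge). Inputs may be
#' hypnograms (merged and encoded internally) or already-encoded integer
#' sequences.
#'
#' @param true_seq,pred_seq equal-length label or ordinal sequences
#' @return integer matrix with class `"confusion_matrix5"`
#' @export
confusion_matrix5 <- function(true_seq, pred_seq) {
  enc <- function(x) if (is.numeric(x)) as.integer(x) else merge_and_encode(x)
  t5 <- enc(true_seq); p5 <- enc(pred_seq)
  if (length(t5) != length(p5))
    stop(sprintf("length mismatch: %d true vs %d predicted epochs",
                 length(t5), length(p5)))
  if (length(t5) == 0) stop("empty sequences")
  stopifnot(all(t5 %in% 1:5), all(p5 %in% 1:5))
  cm <- table(factor(t5, levels = 1:5), factor(p5, levels = 1:5))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(true = ORDINAL_CLASSES, pred = ORDINAL_CLASSES))
  class(cm) <- c("confusion_matrix5", class(cm))
  cm
}

# one-vs-rest tallies per class from a 5x5 confusion matrix
ovr_tallies <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  data.frame(class = ORDINAL_CLASSES, tp = tp, fn = fn, fp = fp, tn = tn,
             row.names = NULL)
}

# the three printed agreement formulas from pooled or per-class tallies:
# S = TP/(TP+FN), P = TN/(FP+TN); accuracy = (S+P)/2; kappa = S+P-1
# (pooled Youden's J); F1 = 2S / (2 + S - P). Implemented verbatim.
metric_triplet <- function(tp, fn, fp, tn) {
  S <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("sensitivity undefined: no positive epochs"); NaN
  }
  P <- if (fp + tn > 0) tn / (fp + tn) else {
    warning("specificity undefined: no negative epochs"); NaN
  }
  c(accuracy = (S + P) / 2, kappa = S + P - 1, f1 = 2 * S / (2 + S - P))
}

#' Overall epoch-agreement metrics
#'
#' Balanced accuracy, the pooled-Youden kappa, and the F1-type score,
#' computed from the class-pooled one-vs-rest tallies exactly as printed:
#' with pooled sensitivity `S = sum TP_c / (sum TP_c + sum FN_c)` and pooled
#' specificity `P = sum TN_c / (sum FP_c + sum TN_c)`,
#' `accuracy = (S + P)/2`, `kappa = S + P - 1`, `F1 = 2S / (2 + S - P)`.
#' Note this kappa is Youden's J on pooled tallies, not the conventional
#' chance-corrected Cohen's kappa; the latter is available separately as
#' [kappa_cohen()] and is never substituted.
#'
#' @param cm a [confusion_matrix5()]
#' @return named numeric vector `(accuracy, kappa, f1)`
#' @export
overall_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  tl <- ovr_tallies(cm)
  metric_triplet(sum(tl$tp), sum(tl$fn), sum(tl$fp), sum(tl$tn))
}

#' Per-class agreement metrics
#'
#' The same three formulas applied to each class's own one-vs-rest tallies.
#' A class absent from the truth has undefined sensitivity and yields NaN
#' metrics with a warning.
#'
#' @param cm a [confusion_matrix5()]
#' @return data.frame with one row per class (`N3, N2, N1, REM, WK`)
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  tl <- ovr_tallies(cm)
  vals <- t(mapply(metric_triplet, tl$tp, tl$fn, tl$fp, tl$tn))
  data.frame(class = tl$class, vals, row.names = NULL)
}

#' Conventional chance-corrected Cohen's kappa
#'
#' Shipped as a diagnostic alongside the printed pooled-Youden form of
#' [overall_metrics()]; the two are distinct statistics.
#'
#' @param cm a [confusion_matrix5()]
#' @return scalar kappa in `[-1, 1]`
#' @export
kappa_cohen <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(NaN)
  (po - pe) / (1 - pe)
}

#' Cohort-level agreement summary
#'
#' Per-subject overall metrics plus cohort mean and sample SD, and optional
#' Pearson correlations of each metric against subject covariates (e.g.
#' apnea severity, age, sleep efficiency).
#'
#' @param pairs list of per-subject `list(true, pred)` hypnogram pairs (the
#'   output of [loocv()] works directly)
#' @param covariates optional data.frame of numeric covariates, one row per
#'   subject
#' @return list with `per_subject` (data.frame), `mean`, `sd`, and
#'   `correlations` (data.frame of r and p per metric x covariate, or NULL)
#' @export
cohort_summary <- function(pairs, covariates = NULL) {
  stopifnot(length(pairs) >= 1)
  per <- t(vapply(pairs, function(p) {
    overall_metrics(confusion_matrix5(p$true, p$pred))
  }, numeric(3)))
  per_df <- data.frame(subject = names(pairs) %||% seq_along(pairs), per,
                       row.names = NULL)
  mu <- colMeans(per)
  sdv <- if (nrow(per) > 1) apply(per, 2, stats::sd) else
    stats::setNames(rep(NA_real_, 3), colnames(per))
  cors <- NULL
  if (!is.null(covariates)) {
    if (nrow(covariates) != nrow(per))
      stop("covariate rows must match the number of subjects")
    cors <- do.call(rbind, lapply(colnames(per), function(m) {
      do.call(rbind, lapply(names(covariates), function(cv) {
        ct <- stats::cor.test(per[, m], covariates[[cv]])
        data.frame(metric = m, covariate = cv,
                   r = unname(ct$estimate), p = ct$p.value)
      }))
    }))
  }
  list(per_subject = per_df, mean = mu, sd = sdv, correlations = cors)
}
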