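#' Sleep parameters of one hypnogram
#'
#' With LV merged into WK and 30 s epochs (0.5 min each):
#' time in bed `TIB` is the full record duration; total sleep time `TST`
#' counts all non-wake epochs; sleep latency `SL` runs from the first epoch
#' ("bedtime") to the first epoch scored as any sleep stage; wake after
#' sleep onset is the identity `WASO = TIB - SL - TST`; `REM%` and `NREM%`
#' are percentages of sleep epochs; sleep efficiency `SE = 100 TST / TIB`.
#' A night without any sleep epoch yields `SL = TIB`, `TST = 0`, and NaN
#' REM%/NREM% with a warning.
#'
#' @param hyp a [hypnogram()]
#' @param strip_padding drop 4 LV epochs from each end first (undoes
#'   [pad_lv()])
#' @return one-row data.frame
#'   (`tib, tst, sl, waso, rem_pct, nrem_pct, se`; minutes and percent)
#' @export
sleep_parameters <- function(hyp, strip_padding = FALSE) {
  lab <- as.character(hyp)
  if (strip_padding) {
    if (length(lab) <= 8) stop("hypnogram empty after stripping LV padding")
    lab <- lab[5:(length(lab) - 4)]
  }
  stopifnot(length(lab) >= 1)
  lab[lab == "LV"] <- "WK"
  n <- length(lab)
  tib <- n * 0.5
  sleep <- lab != "WK"
  tst <- 0.5 * sum(sleep)
  first <- which(sleep)[1]
  sl <- if (is.na(first)) tib else 0.5 * (first - 1)
  waso <- tib - sl - tst
  n_sleep <- sum(sleep)
  if (n_sleep == 0) {
    warning("no sleep epochs: REM% and NREM% undefined")
    rem_pct <- NaN; nrem_pct <- NaN
  } else {
    rem_pct <- 100 * sum(lab == "REM") / n_sleep
    nrem_pct <- 100 * sum(lab %in% c("N1", "N2", "N3")) / n_sleep
  }
  data.frame(tib = tib, tst = tst, sl = sl, waso = waso,
             rem_pct = rem_pct, nrem_pct = nrem_pct, se = 100 * tst / tib)
}

#' Deming (errors-in-variables) regression
#'
#' Closed-form estimator treating both variables as noisy, with error
#' variance ratio `delta = var(err_y) / var(err_x)`: with sample moments
#' `sxx, syy, sxy`,
#' `slope = (syy - delta sxx + sqrt((syy - delta sxx)^2 + 4 delta sxy^2)) /
#' (2 sxy)`. `variance_ratio = 1` gives orthogonal regression; as the ratio
#' grows the fit tends to ordinary least squares of y on x.
#'
#' @param x reference values (`n >= 3`)
#' @param y comparison values
#' @param variance_ratio error-variance ratio `delta` (default 1)
#' @return `list(slope, intercept)`
#' @export
deming_regression <- function(x, y, variance_ratio = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3, variance_ratio > 0)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  if (sxx == 0 && syy == 0) stop("no variance in x or y")
  if (sxy == 0) {
    if (abs(syy - variance_ratio * sxx) < 1e-300)
      stop("Deming slope undefined: zero covariance with equal scaled variances")
    # zero covariance: slope is 0 or infinite depending on the variance excess
    if (syy < variance_ratio * sxx) return(list(slope = 0, intercept = my))
    stop("Deming slope undefined: zero covariance")
  }
  d <- variance_ratio
  slope <- (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = my - slope * mx)
}

#' Bland-Altman agreement analysis
#'
#' Differences `y - x` against their means: bias is the mean difference,
#' the 95% limits of agreement are `bias +/- 1.96 SD(diff)` (sample SD),
#' and the Spearman rank correlation between difference and average tests
#' for proportional bias. Identical arrays give bias 0, zero-width limits
#' and an undefined (NaN, with warning) rho.
#'
#' @param x reference values (`n >= 3`)
#' @param y comparison values
#' @return list with `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `spearman_rho`, `spearman_p`
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- y - x
  a <- (x + y) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  rho <- NaN; pval <- NaN
  if (stats::sd(d) == 0 || stats::sd(a) == 0) {
    warning("proportional-bias test undefined: constant differences or averages")
  } else {
    ct <- suppressWarnings(stats::cor.test(d, a, method = "spearman"))
    rho <- unname(ct$estimate); pval <- ct$p.value
  }
  list(bias = bias, sd_diff = sdd,
       loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
       spearman_rho = rho, spearman_p = pval)
}

#' Compare predicted and reference sleep parameters across subjects
#'
#' Computes both parameter sets per subject and, for each of TST, SL, WASO,
#' REM%, NREM% and SE, runs Deming regression, Bland-Altman analysis, the
#' Pearson correlation, and a paired t statistic (descriptive, two-sided,
#' no multiplicity correction).
#'
#' @param pairs list of per-subject `list(true, pred)` hypnogram pairs
#' @param strip_padding passed to [sleep_parameters()] (use TRUE when the
#'   hypnograms are LV-padded)
#' @return data.frame with one row per parameter: reference and predicted
#'   mean +/- SD, paired t and p, Pearson r, Deming slope/intercept, bias
#'   and limits of agreement, and the proportional-bias Spearman rho/p
#' @export
compare_sleep_parameters <- function(pairs, strip_padding = FALSE) {
  if (length(pairs) < 3) stop("need at least 3 subjects to compare parameters")
  ref <- do.call(rbind, lapply(pairs, function(p)
    sleep_parameters(p$true, strip_padding)))
  prd <- do.call(rbind, lapply(pairs, function(p)
    sleep_parameters(p$pred, strip_padding)))
  pars <- c("tst", "sl", "waso", "rem_pct", "nrem_pct", "se")
  rows <- lapply(pars, function(pn) {
    x <- ref[[pn]]; y <- prd[[pn]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    tt <- if (stats::sd(y - x) > 0) stats::t.test(y, x, paired = TRUE) else
      list(statistic = c(t = 0), p.value = 1)
    dm <- tryCatch(deming_regression(x, y), error = function(e)
      list(slope = NA_real_, intercept = NA_real_))
    ba <- bland_altman(x, y)
    r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
    data.frame(parameter = pn, n = length(x),
               ref_mean = mean(x), ref_sd = stats::sd(x),
               pred_mean = mean(y), pred_sd = stats::sd(y),
               t = unname(tt$statistic), p = tt$p.value, pearson_r = r,
               deming_slope = dm$slope, deming_intercept = dm$intercept,
               bias = ba$bias, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper,
               spearman_rho = ba$spearman_rho, spearman_p = ba$spearman_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
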