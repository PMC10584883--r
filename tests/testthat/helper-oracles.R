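# Independent brute-force oracles. These re-derive expected values by the
# most literal route available (per-epoch tallies, direct sums, textbook
# formulas) and deliberately share no code with the implementation paths
# they check.

# per-epoch one-vs-rest tally of the three agreement formulas, from raw
# ordinal sequences
oracle_metrics_from_sequences <- function(t5, p5, classes = 1:5) {
  tp <- fn <- fp <- tn <- 0
  per <- list()
  for (cc in classes) {
    tpc <- sum(t5 == cc & p5 == cc)
    fnc <- sum(t5 == cc & p5 != cc)
    fpc <- sum(t5 != cc & p5 == cc)
    tnc <- sum(t5 != cc & p5 != cc)
    S <- tpc / (tpc + fnc); P <- tnc / (fpc + tnc)
    per[[as.character(cc)]] <- c(accuracy = (S + P) / 2, kappa = S + P - 1,
                                 f1 = 2 * S / (2 + S - P))
    tp <- tp + tpc; fn <- fn + fnc; fp <- fp + fpc; tn <- tn + tnc
  }
  S <- tp / (tp + fn); P <- tn / (fp + tn)
  list(overall = c(accuracy = (S + P) / 2, kappa = S + P - 1,
                   f1 = 2 * S / (2 + S - P)),
       per_class = per)
}

# expand a 5x5 count matrix into explicit (true, pred) epoch sequences
expand_cm <- function(cm) {
  t5 <- integer(0); p5 <- integer(0)
  for (i in 1:5) for (j in 1:5) {
    n <- cm[i, j]
    t5 <- c(t5, rep(i, n)); p5 <- c(p5, rep(j, n))
  }
  list(t5 = t5, p5 = p5)
}

# direct double-sum cross-entropy
oracle_cel <- function(probs, class_idx) {
  total <- 0
  for (i in seq_along(class_idx)) {
    for (c in seq_len(ncol(probs))) {
      y <- as.numeric(class_idx[i] == c)
      total <- total - y * log(max(probs[i, c], 1e-12))
    }
  }
  total / length(class_idx)
}

# textbook Deming estimator, coded independently (population moments,
# explicit loops)
oracle_deming <- function(x, y, delta = 1) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- syy <- sxy <- 0
  for (i in seq_len(n)) {
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  sxx <- sxx / (n - 1); syy <- syy / (n - 1); sxy <- sxy / (n - 1)
  b <- (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
    (2 * sxy)
  list(slope = b, intercept = my - b * mx)
}

oracle_bland_altman <- function(x, y) {
  d <- y - x
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  rho <- stats::cor(rank(d), rank((x + y) / 2))
  list(bias = bias, loa_lower = bias - 1.96 * sdd,
       loa_upper = bias + 1.96 * sdd, rho = rho)
}

# random valid hypnogram of length n (may include LV)
random_hypnogram <- function(n, include_lv = TRUE) {
  pool <- if (include_lv) STAGES6 else STAGES5
  hypnogram(sample(pool, n, replace = TRUE))
}

# tiny manufactured feature cohort where the stage is linearly decodable
# from the features; bypasses the signal simulator for fast classifier tests
toy_feature_cohort <- function(n_subjects, n_epochs, seed = 1,
                               noise_sd = 0.05) {
  centers <- rbind(N1 = c(62, 15, 0.45, 0.01),
                   N2 = c(58, 14, 0.80, 0.005),
                   N3 = c(55, 13, 0.95, 0),
                   REM = c(68, 18, 0.20, 0.01),
                   WK = c(75, 16, 0.30, 0.1),
                   LV = c(0, 0, 0, 0))
  feats <- list(); labs <- list()
  set.seed(seed)
  for (s in seq_len(n_subjects)) {
    lab <- sample(STAGES5, n_epochs, replace = TRUE)
    lab <- c(rep("LV", 4), lab, rep("LV", 4))
    x <- centers[lab, , drop = FALSE] *
      (1 + matrix(rnorm(length(lab) * 4, 0, noise_sd), ncol = 4))
    x[lab == "LV", ] <- 0
    id <- sprintf("T%02d", s)
    feats[[id]] <- x
    labs[[id]] <- hypnogram(lab)
  }
  list(features = feats, labels = labs)
}
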