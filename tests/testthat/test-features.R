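test_that("RRI outlier screen removes range and jump violations only", {
  bt <- cumsum(c(0, rep(1, 20)))
  rri <- rep(1000, 20)
  cl <- clean_rri(bt, rri)
  expect_equal(cl$rri_ms, rri)

  # a missed-beat artifact (3000 ms) among 1000 ms neighbours is dropped
  rri2 <- rri; rri2[10] <- 3000
  bt2 <- c(0, cumsum(rri2) / 1000)
  cl2 <- clean_rri(bt2, rri2)
  expect_equal(sum(cl2$rri_ms == 3000), 0)
  expect_equal(length(cl2$rri_ms), 19)

  # below the 300 ms physiological floor
  rri3 <- rri; rri3[5] <- 250
  bt3 <- c(0, cumsum(rri3) / 1000)
  expect_false(250 %in% clean_rri(bt3, rri3)$rri_ms)

  # a 25% jump passes the range rule but fails the 30%-of-median rule? no:
  # 25% < 30%, so it is kept
  rri4 <- rri; rri4[8] <- 1250
  bt4 <- c(0, cumsum(rri4) / 1000)
  expect_true(1250 %in% clean_rri(bt4, rri4)$rri_ms)
  # a 40% jump is dropped
  rri5 <- rri; rri5[8] <- 1400
  bt5 <- c(0, cumsum(rri5) / 1000)
  expect_false(1400 %in% clean_rri(bt5, rri5)$rri_ms)

  expect_error(clean_rri(c(0, 1), c(2500)), "insufficient beats")
  expect_error(clean_rri(c(0, 1, 0.5), rep(1000, 2)), "strictly increasing")
})

test_that("spline resampling reproduces constants and knot values", {
  t <- seq(1, 30)
  r1 <- resample_rri(t, rep(1000, 30))
  expect_true(all(abs(r1$hr - 60) < 1e-9))
  expect_equal(diff(r1$t)[1], 0.1)
  r2 <- resample_rri(t, rep(1200, 30))
  expect_true(all(abs(r2$hr - 50) < 1e-9))
  # interpolation property: spline passes through the knots exactly
  vals <- rep(c(900, 1100), 15)
  r3 <- resample_rri(t, vals)
  at_knots <- r3$rri[match(t, round(r3$t, 6))]
  expect_equal(at_knots, vals, tolerance = 1e-9)
  expect_error(resample_rri(c(1, 2, 3), c(1, 1, 1) * 1000), "4 points")
})

test_that("respiration band-pass has the expected pass/stop behaviour", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  inband <- sin(2 * pi * 0.25 * t)
  out <- filter_respiration(inband, fs)
  expect_gte(max(abs(out[2000:4000])), 0.9)
  stop_tone <- sin(2 * pi * 2 * t)
  out2 <- filter_respiration(stop_tone, fs)
  expect_lte(max(abs(out2[2000:4000])), 0.1)
  expect_equal(filter_respiration(numeric(6001), fs), numeric(6001))
  expect_error(filter_respiration(rep(0, 5), fs), "too short")
})

test_that("wavelet PSD finds the dominant respiratory frequency", {
  fs <- 10
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  f1 <- estimate_resp_frequency(sin(2 * pi * 0.25 * t), fs)
  expect_gte(f1, 0.24); expect_lte(f1, 0.26)

  two <- sin(2 * pi * 0.2 * t) + 0.3 * sin(2 * pi * 0.4 * t)
  f2 <- estimate_resp_frequency(two, fs)
  expect_lt(abs(f2 - 0.2), 0.02)

  expect_true(is.na(estimate_resp_frequency(numeric(200), fs)))

  # range contract on pure noise
  set.seed(42)
  for (i in 1:100) {
    f <- estimate_resp_frequency(rnorm(200), fs)
    expect_gte(f, 0.05); expect_lte(f, 0.6)
  }
})

test_that("RSA extraction keeps the respiratory band and drops the rest", {
  fs <- 10; f_R <- 0.25
  t <- seq(0, 600, by = 1 / fs)
  mod <- 50 * sin(2 * pi * f_R * t)
  rsa <- extract_rsa(1000 + mod, f_R, fs)
  expect_gte(max(abs(rsa[2000:4000])), 0.9 * 50)
  far <- 50 * sin(2 * pi * 2.5 * f_R * t)
  rsa2 <- extract_rsa(1000 + far, f_R, fs)
  expect_lte(max(abs(rsa2[2000:4000])), 0.2 * 50)
  # DC removed away from the filter's edge transients
  rsa3 <- extract_rsa(rep(1000, length(t)), f_R, fs)
  expect_lt(max(abs(rsa3[2000:4000])), 1e-6)
  expect_error(extract_rsa(mod, 0), "degenerate")
  expect_error(extract_rsa(mod, 4), "degenerate")
})

test_that("analytic-signal phase behaves like the phase of a pure tone", {
  fs <- 10
  t <- seq(0, 100 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)
  ph <- instantaneous_phase(x)
  interior <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  slope <- mean(diff(unwrap_local <- cumsum(c(ph[interior[1]],
    wrap_phase(diff(ph[interior])))))) * fs
  expect_lt(abs(slope - 2 * pi * 0.25) / (2 * pi * 0.25), 0.01)

  # quadrature: cos leads sin by pi/2
  pc <- instantaneous_phase(cos(2 * pi * 0.25 * t))
  dphi <- wrap_phase(pc[interior] - ph[interior])
  expect_true(all(abs(dphi - pi / 2) < 0.05))

  # amplitude invariance (compare as wrapped differences: +pi and -pi are
  # the same angle)
  expect_lt(max(abs(wrap_phase(instantaneous_phase(3.7 * x) - ph))), 1e-9)
})

test_that("phase coherence matches its analytic limits", {
  expect_equal(phase_coherence(rep(0.7, 200), 100)[200], 1)
  psi <- rep(c(0, pi), 50)
  expect_lt(phase_coherence(psi, 100)[100], 1e-20)
  expect_error(phase_coherence(rep(0, 50), 100), "longer than")

  # E[lambda] = 1/N for iid uniform phase differences
  set.seed(3)
  N <- 50
  psi <- runif(2e5, -pi, pi)
  lam <- phase_coherence(psi, N)
  idx <- seq(N, length(psi), by = N)   # non-overlapping windows
  expect_lt(abs(mean(lam[idx]) - 1 / N) / (1 / N), 0.2)

  # rotation invariance: adding a constant to psi leaves lambda unchanged
  psi2 <- runif(500, -pi, pi)
  expect_equal(phase_coherence(psi2 + 1.3, 100), phase_coherence(psi2, 100),
               tolerance = 1e-12)

  # bounds on fuzzed inputs
  set.seed(4)
  for (i in 1:200) {
    p <- switch(1 + i %% 4,
                runif(150, -pi, pi),
                rep(runif(1, -pi, pi), 150),
                cumsum(rnorm(150, 0, 0.3)),
                wrap_phase(rnorm(150, 0, 5)))
    lam <- phase_coherence(p, sample(2:100, 1))
    expect_true(all(lam >= 0 & lam <= 1))
  }
})

test_that("EMG movement windows trigger on bursts, not on small excursions", {
  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  base <- sin(2 * pi * 9.7 * t) + 0.5 * sin(2 * pi * 14.3 * t)
  sd0 <- mad(base)
  emg <- base
  burst <- t >= 33 & t < 34
  emg[burst] <- emg[burst] + 10 * sd0 * sin(2 * pi * 12 * t[burst])
  mov <- detect_body_movements(emg, fs, n_windows = 24)
  # the 1 s burst at 33-34 s lies in windows [25,35) and [30,40)
  expect_equal(mov[6], 1L)
  expect_equal(mov[7], 1L)
  expect_lte(sum(mov), 3)

  # an excursion reaching only 2 baseline SDs stays below threshold
  small <- base
  small[burst] <- 2 * sd0 * sin(2 * pi * 12 * t[burst])
  expect_equal(sum(detect_body_movements(small, fs, n_windows = 24)), 0)

  expect_error(detect_body_movements(emg, 50), "60 Hz")
})

test_that("window rule agrees with an independently coded per-window tally", {
  fs <- 200
  set.seed(8)
  emg <- rnorm(120 * fs)
  got <- detect_body_movements(emg, fs, n_windows = 24)
  # independent route: same published rule, coded directly
  b <- signal::butter(2, c(1, 30) * 2 / fs, type = "pass")
  filt <- as.numeric(signal::filtfilt(b, emg))
  z <- abs(filt) / mad(filt)
  want <- vapply(0:23, function(k) {
    i0 <- floor(k * 5 * fs) + 1
    i1 <- min(length(z), ceiling((k * 5 + 10) * fs))
    as.integer(any(z[i0:i1] > 3))
  }, integer(1))
  expect_identical(got, want)
})

test_that("feature epochs align with the hypnogram for any duration", {
  cfg <- cohort_config(n_subjects = 1, record_minutes = 5, seed = 2)
  hyp <- hypnogram(rep("N2", 10))
  sig <- simulate_signals(hyp, cfg, seed = 2)
  fe <- compute_feature_epochs(sig, hyp)
  expect_equal(nrow(fe), 10)
  expect_true(all(fe$lam >= 0 & fe$lam <= 1))
  expect_true(all(fe$bmf * 30 == round(fe$bmf * 30)))

  for (n_ep in c(4, 7, 13)) {
    h <- simulate_hypnogram(cohort_config(n_subjects = 1,
                                          record_minutes = n_ep / 2, seed = n_ep))
    s <- simulate_signals(h, cfg, seed = n_ep)
    expect_equal(nrow(compute_feature_epochs(s, h)), n_ep)
  }
})

test_that("constant-rate beats give constant epoch heart rate", {
  # hand-built bundle: metronome beats at 60 bpm, clean 0.25 Hz breathing
  dur <- 300; fs_r <- 10; fs_e <- 200
  bt <- seq(0, dur, by = 1)
  tr <- seq(0, dur - 1 / fs_r, by = 1 / fs_r)
  te <- seq(0, dur - 1 / fs_e, by = 1 / fs_e)
  bundle <- list(beat_times = bt, rri = diff(bt) * 1000,
                 respiration = sin(2 * pi * 0.25 * tr),
                 emg = sin(2 * pi * 9.7 * te),
                 resp_sampling_hz = fs_r, emg_sampling_hz = fs_e,
                 lv_mask_resp = NULL, lv_mask_emg = NULL)
  hyp <- hypnogram(rep("N2", 10))
  fe <- compute_feature_epochs(bundle, hyp)
  expect_equal(fe$hr, rep(60, 10), tolerance = 1e-6)
  expect_equal(fe$rr, rep(15, 10), tolerance = 0.6)
  expect_equal(fe$bmf, rep(0, 10))
})

test_that("LV padding adds exactly four zero epochs per end", {
  cfg <- cohort_config(n_subjects = 1, record_minutes = 5, seed = 3)
  hyp <- hypnogram(rep("N2", 10))
  fe <- compute_feature_epochs(simulate_signals(hyp, cfg, seed = 3), hyp)
  pl <- pad_lv(fe, hyp)
  expect_equal(nrow(pl$features), 18)
  expect_length(pl$hypnogram, 18)
  expect_true(all(as.matrix(pl$features[c(1:4, 15:18), c("hr", "rr", "lam", "bmf")]) == 0))
  expect_equal(as.character(pl$hypnogram)[c(1:4, 15:18)], rep("LV", 8))
  expect_equal(as.character(pl$hypnogram)[5:14], rep("N2", 10))

  # applying twice keeps growing; no idempotence claimed
  pl2 <- pad_lv(pl$features, pl$hypnogram)
  expect_equal(nrow(pl2$features), 26)

  # degenerate empty input
  pl0 <- pad_lv(fe[0, ], hypnogram(character(0)))
  expect_equal(nrow(pl0$features), 8)
  expect_equal(as.character(pl0$hypnogram), rep("LV", 8))
})
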