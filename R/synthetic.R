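#' Stage-conditional signal profile
#'
#' Bundles the generator parameters that characterize one sleep stage:
#' mean heart rate and the SD of its slow wander (beats/min), respiratory
#' frequency and the SD of its slow drift (Hz), the peak RRI modulation by
#' respiratory sinus arrhythmia (ms), the SD of the RSA-vs-respiration
#' phase-difference noise (radians; this is the dial that sets the
#' ground-truth phase coherence), and the body-movement burst rate
#' (events/min) and amplitude (multiples of the baseline EMG SD).
#'
#' @param stage one of `WK, REM, N1, N2, N3`
#' @param mean_hr beats/min, `> 0`
#' @param hr_wander_sd beats/min; stationary SD of the AR(1) heart-rate wander
#' @param resp_freq Hz; must lie inside the 0.05--0.6 Hz respiration band
#' @param resp_freq_jitter Hz; stationary SD of the slow respiratory drift
#' @param rsa_amplitude ms; peak RRI modulation at `resp_freq`
#' @param phase_jitter_sd radians, `>= 0`
#' @param movement_rate events/min, `>= 0` (Poisson rate of EMG bursts)
#' @param movement_amp burst amplitude as a multiple of the baseline EMG SD
#' @return a list with class `"stage_profile"`
#' @export
stage_profile <- function(stage, mean_hr, hr_wander_sd, resp_freq,
                          resp_freq_jitter, rsa_amplitude, phase_jitter_sd,
                          movement_rate, movement_amp) {
  stage <- match.arg(stage, STAGES5)
  stopifnot(mean_hr > 0, hr_wander_sd >= 0,
            resp_freq >= 0.05, resp_freq <= 0.6,
            resp_freq_jitter >= 0, rsa_amplitude >= 0,
            phase_jitter_sd >= 0, movement_rate >= 0, movement_amp >= 0)
  structure(list(stage = stage, mean_hr = mean_hr, hr_wander_sd = hr_wander_sd,
                 resp_freq = resp_freq, resp_freq_jitter = resp_freq_jitter,
                 rsa_amplitude = rsa_amplitude, phase_jitter_sd = phase_jitter_sd,
                 movement_rate = movement_rate, movement_amp = movement_amp),
            class = "stage_profile")
}

#' Default stage profiles
#'
#' Encode the qualitative stage-conditional structure of overnight
#' cardiorespiratory recordings: as sleep deepens from N1 to N3, heart rate
#' and respiration slow down and stabilize and the cardiorespiratory phase
#' coherence rises; REM shows the largest heart-rate wander and the weakest,
#' most fluctuating phase locking; body movements are most frequent in wake.
#' The numbers are generator configuration, not physiological claims.
#'
#' `separated_stage_profiles()` is a benchmark variant with deliberately
#' exaggerated between-stage contrasts, used to test that the sequence
#' classifier can learn at desk scale.
#'
#' @return named list of [stage_profile()]s, one per stage in [STAGES5]
#' @export
default_stage_profiles <- function() {
  list(
    WK  = stage_profile("WK",  mean_hr = 70, hr_wander_sd = 3.0,
                        resp_freq = 0.27, resp_freq_jitter = 0.030,
                        rsa_amplitude = 20, phase_jitter_sd = 1.0,
                        movement_rate = 1.5, movement_amp = 8),
    REM = stage_profile("REM", mean_hr = 68, hr_wander_sd = 4.0,
                        resp_freq = 0.30, resp_freq_jitter = 0.040,
                        rsa_amplitude = 25, phase_jitter_sd = 1.5,
                        movement_rate = 0.2, movement_amp = 6),
    N1  = stage_profile("N1",  mean_hr = 62, hr_wander_sd = 2.0,
                        resp_freq = 0.25, resp_freq_jitter = 0.020,
                        rsa_amplitude = 35, phase_jitter_sd = 0.7,
                        movement_rate = 0.5, movement_amp = 8),
    N2  = stage_profile("N2",  mean_hr = 58, hr_wander_sd = 1.2,
                        resp_freq = 0.23, resp_freq_jitter = 0.010,
                        rsa_amplitude = 45, phase_jitter_sd = 0.30,
                        movement_rate = 0.1, movement_amp = 8),
    N3  = stage_profile("N3",  mean_hr = 55, hr_wander_sd = 0.8,
                        resp_freq = 0.22, resp_freq_jitter = 0.005,
                        rsa_amplitude = 50, phase_jitter_sd = 0.15,
                        movement_rate = 0.05, movement_amp = 8)
  )
}

#' @rdname default_stage_profiles
#' @export
separated_stage_profiles <- function() {
  list(
    WK  = stage_profile("WK",  mean_hr = 78, hr_wander_sd = 2.0,
                        resp_freq = 0.32, resp_freq_jitter = 0.020,
                        rsa_amplitude = 15, phase_jitter_sd = 1.1,
                        movement_rate = 3.0, movement_amp = 10),
    REM = stage_profile("REM", mean_hr = 70, hr_wander_sd = 3.5,
                        resp_freq = 0.36, resp_freq_jitter = 0.030,
                        rsa_amplitude = 20, phase_jitter_sd = 1.8,
                        movement_rate = 0.2, movement_amp = 8),
    N1  = stage_profile("N1",  mean_hr = 64, hr_wander_sd = 1.5,
                        resp_freq = 0.27, resp_freq_jitter = 0.010,
                        rsa_amplitude = 35, phase_jitter_sd = 0.8,
                        movement_rate = 0.6, movement_amp = 8),
    N2  = stage_profile("N2",  mean_hr = 58, hr_wander_sd = 0.8,
                        resp_freq = 0.23, resp_freq_jitter = 0.005,
                        rsa_amplitude = 45, phase_jitter_sd = 0.30,
                        movement_rate = 0.05, movement_amp = 8),
    N3  = stage_profile("N3",  mean_hr = 50, hr_wander_sd = 0.5,
                        resp_freq = 0.19, resp_freq_jitter = 0.003,
                        rsa_amplitude = 55, phase_jitter_sd = 0.10,
                        movement_rate = 0.02, movement_amp = 8)
  )
}

#' Default 6-state stage-transition matrix
#'
#' Row-stochastic Markov transition matrix over `WK, REM, N1, N2, N3, LV`
#' at 30 s resolution. The default favours stage persistence (diagonal
#' around 0.9) with transitions that loosely follow sleep architecture
#' (WK -> N1 -> N2 -> N3, REM entered from N2) and a rare LV state.
#'
#' `balanced_transition_matrix()` is a benchmark variant whose stationary
#' distribution is close to uniform over the five sleep stages, used by the
#' desk-scale learning experiments so that chance-level agreement sits near
#' zero.
#'
#' @return a 6x6 row-stochastic matrix with dimnames [STAGES6]
#' @export
default_transition_matrix <- function() {
  m <- matrix(0, 6, 6, dimnames = list(STAGES6, STAGES6))
  #          WK    REM    N1     N2     N3     LV
  m["WK", ] <- c(0.880, 0.005, 0.100, 0.005, 0.000, 0.010)
  m["REM", ] <- c(0.040, 0.900, 0.030, 0.030, 0.000, 0.000)
  m["N1", ] <- c(0.060, 0.020, 0.800, 0.120, 0.000, 0.000)
  m["N2", ] <- c(0.020, 0.030, 0.040, 0.880, 0.030, 0.000)
  m["N3", ] <- c(0.010, 0.005, 0.005, 0.080, 0.900, 0.000)
  m["LV", ] <- c(0.200, 0.000, 0.000, 0.000, 0.000, 0.800)
  m
}

#' @rdname default_transition_matrix
#' @export
balanced_transition_matrix <- function() {
  # symmetric off-diagonal mixing over the 5 sleep stages -> uniform
  # stationary distribution; the moderate persistence (0.75, mean bout
  # ~2 min) keeps one night's realized stage marginals close to uniform,
  # so chance-level epoch agreement sits near zero on a single night;
  # LV entered/left symmetrically from WK only
  m <- matrix(0, 6, 6, dimnames = list(STAGES6, STAGES6))
  for (s in STAGES5) {
    m[s, STAGES5] <- 0.25 / 4
    m[s, s] <- 0.75
  }
  m["WK", "LV"] <- 0.01
  m["WK", "WK"] <- m["WK", "WK"] - 0.01
  m["LV", ] <- c(0.10, 0, 0, 0, 0, 0.90)
  m
}

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects, `>= 1`
#' @param record_minutes record duration per subject in minutes, `>= 2`
#'   and a multiple of 0.5 (30 s epochs)
#' @param transition_matrix 6x6 row-stochastic matrix over [STAGES6]
#' @param profiles named list of [stage_profile()]s covering [STAGES5]
#' @param emg_sampling_hz EMG sampling rate (default 200 Hz)
#' @param resp_sampling_hz respiration sampling rate (default 10 Hz)
#' @param initial_stage stage of the first epoch (default `"WK"`)
#' @param seed master seed; all per-subject seeds derive from it
#' @return a list with class `"cohort_config"`
#' @export
cohort_config <- function(n_subjects = 12, record_minutes = 480,
                          transition_matrix = default_transition_matrix(),
                          profiles = default_stage_profiles(),
                          emg_sampling_hz = 200, resp_sampling_hz = 10,
                          initial_stage = "WK", seed = 1L) {
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  if (record_minutes < 2) stop("configuration error: record_minutes must be >= 2")
  if (abs(record_minutes / 0.5 - round(record_minutes / 0.5)) > 1e-9)
    stop("configuration error: record_minutes must be a multiple of 0.5")
  stopifnot(is.matrix(transition_matrix),
            all(dim(transition_matrix) == c(6, 6)))
  rs <- rowSums(transition_matrix)
  off <- which(abs(rs - 1) > 1e-12)
  if (length(off) > 0) {
    stop(sprintf("configuration error: transition matrix row %d ('%s') sums to %.15g, not 1",
                 off[1], STAGES6[off[1]], rs[off[1]]))
  }
  if (any(transition_matrix < 0))
    stop("configuration error: transition matrix has negative entries")
  missing_p <- setdiff(STAGES5, names(profiles))
  if (length(missing_p) > 0)
    stop("configuration error: missing StageProfile for ", paste(missing_p, collapse = ", "))
  initial_stage <- match.arg(initial_stage, STAGES6)
  structure(list(n_subjects = as.integer(n_subjects),
                 record_minutes = record_minutes,
                 epoch_seconds = 30,
                 transition_matrix = transition_matrix,
                 profiles = profiles,
                 emg_sampling_hz = emg_sampling_hz,
                 resp_sampling_hz = resp_sampling_hz,
                 initial_stage = initial_stage,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a hypnogram as a first-order Markov chain over 30 s epochs
#'
#' @param config a [cohort_config()]
#' @param seed integer seed (defaults to `config$seed`)
#' @return a [hypnogram()] of length `record_minutes * 2`
#' @export
simulate_hypnogram <- function(config, seed = config$seed) {
  n_epochs <- as.integer(round(config$record_minutes * 2))
  P <- config$transition_matrix
  labels <- character(n_epochs)
  with_seed(seed, {
    state <- match(config$initial_stage, STAGES6)
    for (k in seq_len(n_epochs)) {
      labels[k] <- STAGES6[state]
      state <- sample.int(6L, 1L, prob = P[state, ])
    }
  })
  hypnogram(labels)
}

# Ornstein-Uhlenbeck process on a uniform grid: stationary SD `sd`,
# correlation time `tau` seconds; exact discretization.
ou_process <- function(n, dt, sd, tau) {
  if (sd == 0 || n == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  eps <- rnorm(n - 1, 0, innov_sd)
  # AR(1) recursion via filter() for speed
  if (n > 1) x <- stats::filter(c(x[1], eps), a, method = "recursive")
  as.numeric(x)
}

#' Simulate raw channels for one night given a hypnogram
#'
#' Generates, per stage, (i) a narrowband respiration oscillation whose
#' instantaneous frequency drifts around the stage's `resp_freq`
#' (Ornstein-Uhlenbeck drift, clipped to the 0.05--0.6 Hz band);
#' (ii) a beat list obtained by integrating an instantaneous RRI composed of
#' `60000 / (mean_hr + wander)` plus an RSA modulation
#' `rsa_amplitude * sin(respiration phase + phase noise)`, where the phase
#' noise is an OU process with 5 s correlation time and stationary SD
#' `phase_jitter_sd` (this sets the ground-truth phase coherence); and
#' (iii) an EMG trace of bounded narrowband baseline tone plus Poisson-placed
#' movement bursts of amplitude `movement_amp` baseline-SDs. All channels are
#' zeroed, and beats removed, inside LV ("out of bed") epochs.
#'
#' @param hyp a [hypnogram()]
#' @param config a [cohort_config()] supplying profiles and sampling rates
#' @param seed integer seed
#' @return a list with class `"signal_bundle"`: `beat_times` (s), `rri` (ms,
#'   `diff(beat_times) * 1000`), `respiration`, `emg`, their sampling rates,
#'   per-sample LV masks, and a `ground_truth` list with the realized
#'   per-epoch mean HR, mean respiratory frequency, and true burst count.
#' @export
simulate_signals <- function(hyp, config, seed = config$seed) {
  n_epochs <- length(hyp)
  stopifnot(n_epochs >= 1)
  for (s in setdiff(unique(as.character(hyp)), "LV")) {
    if (is.null(config$profiles[[s]]))
      stop("missing StageProfile for stage ", s)
    f <- config$profiles[[s]]$resp_freq
    if (f < 0.05 || f > 0.6)
      stop("resp_freq outside [0.05, 0.6] for stage ", s)
  }
  dur <- n_epochs * 30
  fs_r <- config$resp_sampling_hz
  fs_e <- config$emg_sampling_hz
  n_r <- as.integer(round(dur * fs_r))
  n_e <- as.integer(round(dur * fs_e))
  lab <- as.character(hyp)
  is_lv_epoch <- lab == "LV"
  # per-resp-sample stage index; LV samples carry the last non-LV profile
  # for waveform continuity but are zeroed afterwards
  epoch_of_r <- pmin(floor(seq_len(n_r) - 1) %/% (30L * fs_r) + 1L, n_epochs)
  prof_stage <- lab
  if (all(is_lv_epoch)) prof_stage[] <- "WK" else {
    for (k in seq_len(n_epochs)) if (is_lv_epoch[k])
      prof_stage[k] <- if (k > 1) prof_stage[k - 1] else lab[which(!is_lv_epoch)[1]]
  }
  pget <- function(field) unname(vapply(config$profiles, `[[`,
                                        numeric(1), field)[prof_stage])

  f0_e <- pget("resp_freq")          # per-epoch values
  fj_e <- pget("resp_freq_jitter")
  hr_e <- pget("mean_hr")
  hw_e <- pget("hr_wander_sd")
  rsa_e <- pget("rsa_amplitude")
  pj_e <- pget("phase_jitter_sd")
  mr_e <- pget("movement_rate")
  ma_e <- pget("movement_amp")

  # autonomic tone does not step instantaneously at a stage boundary:
  # continuous profile parameters ramp linearly between epoch centers
  # (30 s ramps), which also keeps beat-to-beat RRI changes far below the
  # downstream 30% artifact screen
  centers <- (seq_len(n_epochs) - 0.5) * 30
  smooth_prof <- function(v, times) {
    if (n_epochs == 1) return(rep(v[1], length(times)))
    stats::approx(centers, v, xout = times, rule = 2)$y
  }

  out <- with_seed(seed, {
    dt_r <- 1 / fs_r
    t_r <- (seq_len(n_r) - 1) * dt_r
    # respiration: instantaneous frequency = stage freq + scaled unit OU drift
    ou_f <- ou_process(n_r, dt_r, 1, 30)
    f_inst <- clip(smooth_prof(f0_e, t_r) + smooth_prof(fj_e, t_r) * ou_f,
                   0.05, 0.6)
    resp_phase <- cumsum(2 * pi * f_inst * dt_r)
    respiration <- sin(resp_phase)

    # RSA-vs-respiration phase noise: unit OU (tau = 5 s) scaled per stage
    ou_th <- ou_process(n_r, dt_r, 1, 5)

    # smoothed per-sample profile tracks for the beat integrator
    hr_s <- smooth_prof(hr_e, t_r)
    hw_s <- smooth_prof(hw_e, t_r)
    rsa_s <- smooth_prof(rsa_e, t_r)
    pj_s <- smooth_prof(pj_e, t_r)

    # beats: integrate instantaneous RRI; HR wander is AR(1) at beat
    # resolution with coefficient 0.999, unit stationary SD, scaled per stage
    max_beats <- as.integer(ceiling(dur / 0.3)) + 10L   # rri floor is 300 ms
    beat_times <- numeric(max_beats)
    a <- 0.999
    w <- rnorm(1)
    innov_sd <- sqrt(1 - a^2)
    innov <- rnorm(max_beats, 0, innov_sd)
    t <- 0
    nb <- 0L
    while (t < dur) {
      nb <- nb + 1L
      beat_times[nb] <- t
      ri <- as.integer(min(floor(t * fs_r) + 1, n_r))
      hr_inst <- max(hr_s[ri] + hw_s[ri] * w, 20)
      rri_ms <- 60000 / hr_inst +
        rsa_s[ri] * sin(resp_phase[ri] + pj_s[ri] * ou_th[ri])
      rri_ms <- max(rri_ms, 300)
      t <- t + rri_ms / 1000
      w <- a * w + innov[nb]
    }
    beat_times <- beat_times[seq_len(nb)]

    # EMG: bounded narrowband baseline tone (never exceeds 3 robust SDs, so
    # the single-sample threshold rule has a near-zero false-alarm rate)
    # plus Poisson-placed 0.5 s noise bursts
    t_e <- (seq_len(n_e) - 1) / fs_e
    phi <- runif(2, 0, 2 * pi)
    emg <- sin(2 * pi * 9.7 * t_e + phi[1]) + 0.5 * sin(2 * pi * 14.3 * t_e + phi[2])
    base_sd <- stats::mad(emg)   # robust baseline SD of the tone
    burst_count_epoch <- integer(n_epochs)
    burst_times <- numeric(0)
    for (k in seq_len(n_epochs)) {
      if (is_lv_epoch[k]) next
      nk <- rpois(1, mr_e[k] * 0.5)   # rate per min * 0.5 min
      burst_count_epoch[k] <- nk
      if (nk > 0) {
        t0 <- sort(runif(nk, (k - 1) * 30, k * 30 - 0.5))
        burst_times <- c(burst_times, t0)
        for (b in t0) {
          idx <- which(t_e >= b & t_e < b + 0.5)
          emg[idx] <- emg[idx] + rnorm(length(idx), 0, ma_e[k] * base_sd)
        }
      }
    }

    # LV dropout: zero all channels, remove beats
    lv_mask_resp <- is_lv_epoch[pmin(floor(t_r / 30) + 1, n_epochs)]
    lv_mask_emg <- is_lv_epoch[pmin(floor(t_e / 30) + 1, n_epochs)]
    respiration[lv_mask_resp] <- 0
    emg[lv_mask_emg] <- 0
    beat_ep <- pmin(floor(beat_times / 30) + 1, n_epochs)
    beat_times <- beat_times[!is_lv_epoch[beat_ep]]

    list(beat_times = beat_times, respiration = respiration, emg = emg,
         lv_mask_resp = lv_mask_resp, lv_mask_emg = lv_mask_emg,
         f_inst = f_inst, epoch_of_r = epoch_of_r,
         burst_count_epoch = burst_count_epoch, burst_times = burst_times)
  })

  bt <- out$beat_times
  rri <- diff(bt) * 1000
  # realized per-epoch ground truth
  gt_resp_freq <- vapply(seq_len(n_epochs), function(k)
    mean(unname(out$f_inst[out$epoch_of_r == k])), numeric(1))
  ep_of_beat <- pmin(floor(bt / 30) + 1, n_epochs)
  inst_hr <- 60000 / rri
  gt_hr <- vapply(seq_len(n_epochs), function(k) {
    i <- which(ep_of_beat[-length(ep_of_beat)] == k)
    if (length(i) == 0) NA_real_ else mean(inst_hr[i])
  }, numeric(1))

  structure(list(beat_times = bt, rri = rri,
                 respiration = out$respiration, emg = out$emg,
                 resp_sampling_hz = fs_r, emg_sampling_hz = fs_e,
                 lv_mask_resp = out$lv_mask_resp, lv_mask_emg = out$lv_mask_emg,
                 ground_truth = list(mean_hr = gt_hr,
                                     resp_freq = gt_resp_freq,
                                     burst_count = out$burst_count_epoch,
                                     burst_times = out$burst_times)),
            class = "signal_bundle")
}

#' Simulate a cohort of labelled overnight recordings
#'
#' Per-subject seeds derive reproducibly from `config$seed` and the subject
#' id, so subjects are exchangeable and the whole cohort is reproducible.
#' Each subject carries a synthetic apnea-severity covariate (`ahi`), used
#' only as a label in downstream correlation summaries, never in simulation.
#'
#' @param config a [cohort_config()]
#' @return list of subjects, each
#'   `list(id, hypnogram, signals, ahi)`
#' @export
simulate_cohort <- function(config) {
  if (config$n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  subjects <- vector("list", config$n_subjects)
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  for (i in seq_len(config$n_subjects)) {
    s_hyp <- derive_seed(config$seed, paste0(ids[i], ":hyp"))
    s_sig <- derive_seed(config$seed, paste0(ids[i], ":sig"))
    s_cov <- derive_seed(config$seed, paste0(ids[i], ":cov"))
    hyp <- simulate_hypnogram(config, seed = s_hyp)
    sig <- simulate_signals(hyp, config, seed = s_sig)
    ahi <- with_seed(s_cov, round(stats::rlnorm(1, log(15), 0.8), 1))
    subjects[[i]] <- list(id = ids[i], hypnogram = hyp, signals = sig, ahi = ahi)
  }
  names(subjects) <- ids
  subjects
}
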