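#' Simulation configuration for synthetic cohorts
#'
#' Defines the statistical structure of generated recordings: the stimulus
#' protocol and probe layout of the study, gamma-shaped hemodynamic response
#' functions per condition, physiological oscillations (Mayer waves near
#' 0.1 Hz, respiration near 0.25 Hz, cardiac pulsation near 1.1 Hz), slow
#' random-walk drift, white measurement noise, and a superficial (scalp)
#' component injected into the short-separation channels at unit weight and
#' into the long channels at per-channel coupling weights. Behavioral
#' parameters default to the study's group descriptives (pressure-pain
#' thresholds 45 +/- 18 N for patients, 57 +/- 7.3 N for controls; ages
#' 32 +/- 6.1 vs 33.6 +/- 10.7 years) and heart-rate levels to the observed
#' group means.
#'
#' `amplitudes` are calibrated so that, for a noise-free subject, the
#' pipeline's block average (median of the middle 2.5 s stimulus window after
#' per-epoch detrending and pre-window normalization) equals the configured
#' value exactly; they are therefore the ground truth the pipeline should
#' recover.
#'
#' @param seed Base seed; every subject's stream is derived from it.
#' @param n_hc,n_clbp Group sizes.
#' @param protocol,layout Study protocol and probe layout.
#' @param amplitudes Named per-condition oxyhemoglobin block amplitudes in uM.
#' @param hhb_ratio Deoxyhemoglobin task amplitude as a fraction of the
#'   oxyhemoglobin amplitude (negative = antiphase).
#' @param hhb_nuisance_ratio Scaling of all nuisance components for HHb.
#' @param responder_channel_fraction Fraction of long channels carrying a
#'   task response (the rest are null channels).
#' @param hrf_shape,hrf_scale Gamma-kernel parameters (peak at
#'   `(shape - 1) * scale` seconds).
#' @param systemic List of `mayer`, `resp`, `cardiac`, each with `freq` (Hz)
#'   and `amp` (uM); frequencies must be below Nyquist.
#' @param scalp Superficial-component settings: `sd` (slow AR(1) scalp
#'   fluctuation, uM), `osc_amp`/`osc_freq` (scalp-borne Mayer-wave
#'   oscillation, uM / Hz), `task_amp` (stimulus-evoked scalp blood-flow
#'   response, uM), `task_shape`/`task_scale` (gamma kernel of that response;
#'   deliberately slower and broader than the cortical kernel), `coupling`
#'   (range of per-long-channel coupling weights), `ar` (AR(1) coefficient).
#' @param drift_scale Random-walk drift scale in uM per sqrt(s).
#' @param noise_sd White measurement noise SD in uM.
#' @param clbp_heterogeneity If `TRUE`, patients draw a bimodal per-subject
#'   amplitude multiplier (0.3x or 1.7x) emulating responder subgroups;
#'   default off.
#' @param hr List of heart-rate generator settings (per-group baseline mean
#'   and SD in bpm, evoked bump amplitude and peak latency, noise SD).
#' @param behavioral List of group behavioral distributions.
#' @param i0 Forward-model baseline intensity (arbitrary units).
#' @param truth_detail `"epoch"` (default): ground-truth block values are
#'   computed by passing the noise-free injected signal through the epoch
#'   pipeline (exact, accounts for trial overlap); `"amplitude"`: the truth
#'   table simply records the configured amplitudes (cheaper; sufficient for
#'   studies that only use the responder mask).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_hc = 20, n_clbp = 12,
                       protocol = stimulus_protocol(),
                       layout = build_default_layout(),
                       amplitudes = c(PAPain = 0.5, PAnP = 0.4, Brush = 0.15),
                       hhb_ratio = -1 / 3,
                       hhb_nuisance_ratio = 0.4,
                       responder_channel_fraction = 1,
                       hrf_shape = 6, hrf_scale = 1.2,
                       systemic = list(mayer = list(freq = 0.1, amp = 0.1),
                                       resp = list(freq = 0.25, amp = 0.1),
                                       cardiac = list(freq = 1.1, amp = 0.3)),
                       scalp = list(sd = 0.3, osc_amp = 0.3, osc_freq = 0.1,
                                    task_amp = 0.15, task_shape = 2,
                                    task_scale = 1.5,
                                    coupling = c(0.3, 0.7), ar = 0.995),
                       drift_scale = 0.05,
                       noise_sd = 0.2,
                       clbp_heterogeneity = FALSE,
                       hr = list(clbp_mean = 63.3, clbp_sd = 10.9,
                                 hc_mean = 62.0, hc_sd = 7.6,
                                 bump_bpm = 0.8, bump_peak_s = 8,
                                 noise_sd = 1),
                       behavioral = list(
                         clbp_ppt = c(mean = 45, sd = 18),
                         hc_ppt = c(mean = 57, sd = 7.3),
                         clbp_age = c(mean = 32, sd = 6.1, lo = 24, hi = 44),
                         hc_age = c(mean = 33.6, sd = 10.7, lo = 22, hi = 61),
                         nonpainful_force = 30),
                       i0 = 1e6,
                       truth_detail = c("epoch", "amplitude")) {
  truth_detail <- match.arg(truth_detail)
  nyq <- layout$sampling_rate / 2
  freqs <- vapply(systemic, function(s) s$freq, numeric(1))
  if (any(freqs >= nyq)) {
    stop(sprintf("systemic frequency at or above Nyquist (%.3f Hz)", nyq))
  }
  if (!setequal(names(amplitudes), protocol$conditions)) {
    stop("amplitudes must be named by the protocol conditions")
  }
  cfg <- as.list(environment())
  cfg$nyq <- NULL
  cfg$freqs <- NULL
  structure(cfg, class = "sim_config")
}

# Gamma-shaped hemodynamic impulse response on the sampling grid, peak
# normalized to 1 (latency (shape-1)*scale seconds).
hrf_kernel <- function(fs, shape, scale, length_s = 30) {
  t <- seq(0, length_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = shape, scale = scale)
  h / max(h)
}

# Convolve a 0/1 stimulus train with a kernel, same length as the train.
conv_train <- function(train, kernel) {
  out <- stats::convolve(train, rev(kernel), type = "open")
  out[seq_along(train)]
}

# Per-condition calibration scale: the clean block value (epoch detrend +
# pre-median normalization + middle-window median) of a unit-peak response
# under a reference pseudo-random sequence. Memoized on the protocol/HRF
# parameters, so amplitude parameters are expressed in recovered-block units
# identically for every subject.
.calib_cache <- new.env(parent = emptyenv())

unit_response_scale <- function(protocol, fs, hrf_shape, hrf_scale) {
  key <- paste(protocol$baseline_s, protocol$trials_per_condition,
               protocol$stimulus_s, protocol$isi_s, fs, hrf_shape, hrf_scale,
               paste(protocol$conditions, collapse = "|"), sep = "_")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  ref <- generate_stimulus_sequence(protocol, seed = 999983)
  nt <- round(protocol_duration_s(ref) * fs)
  kern <- hrf_kernel(fs, hrf_shape, hrf_scale)
  stim_len <- round(ref$stimulus_s * fs)
  resp <- list()
  for (cond in ref$conditions) {
    train <- numeric(nt)
    idx <- floor(ref$sequence$onset_s[ref$sequence$condition == cond] * fs) + 1L
    for (i in idx) train[i:min(nt, i + stim_len - 1L)] <- 1
    resp[[cond]] <- conv_train(train, kern)
  }
  hb <- structure(list(
    o2hb = do.call(rbind, resp), hhb = do.call(rbind, resp) * 0,
    time = (seq_len(nt) - 1) / fs, fs = fs,
    layout = minimal_layout_for(length(resp), fs),
    protocol = ref, subject = list(age = 30),
    filtered = FALSE, detrended = FALSE, ssr_applied = FALSE),
    class = "hb_series")
  es <- detrend_normalize_epochs(segment_trials(hb, ref))
  ba <- block_average(es)
  scale <- vapply(seq_along(resp), function(i) {
    b <- ba$value[ba$channel == i & ba$condition == names(resp)[i] &
                    ba$chromophore == "o2hb"]
    if (abs(b) < 1e-6) stop("degenerate response calibration")
    b
  }, numeric(1))
  names(scale) <- names(resp)
  .calib_cache[[key]] <- scale
  scale
}

# Calibrated per-condition response time courses for a subject's sequence.
unit_responses <- function(protocol, layout, hrf_shape, hrf_scale) {
  fs <- layout$sampling_rate
  nt <- round(protocol_duration_s(protocol) * fs)
  kern <- hrf_kernel(fs, hrf_shape, hrf_scale)
  stim_len <- round(protocol$stimulus_s * fs)
  scale <- unit_response_scale(protocol, fs, hrf_shape, hrf_scale)
  resp <- list()
  for (cond in protocol$conditions) {
    train <- numeric(nt)
    on <- protocol$sequence$onset_s[protocol$sequence$condition == cond]
    idx <- floor(on * fs) + 1L
    for (i in idx) train[i:min(nt, i + stim_len - 1L)] <- 1
    resp[[cond]] <- conv_train(train, kern) / scale[[cond]]
  }
  resp
}

# Tiny stand-in layout so the calibration epoching can reuse segment_trials
# with one row per condition.
minimal_layout_for <- function(n_rows, fs) {
  list(channels = tibble::tibble(channel = seq_len(n_rows)),
       sampling_rate = fs)
}

# Quasi-periodic physiological oscillation: a sinusoid whose phase performs a
# random walk (diffusion in rad^2 per second). Physiological rhythms (Mayer
# waves, respiration, cardiac) drift in frequency/phase, so they are not
# phase-locked to the 20 s trial grid the way a pure sinusoid would be.
narrowband_osc <- function(nt, fs, freq, amp, phase_diffusion = 0.05) {
  t_s <- (seq_len(nt) - 1) / fs
  phi <- cumsum(stats::rnorm(nt, 0, sqrt(phase_diffusion / fs)))
  amp * sin(2 * pi * freq * t_s + stats::runif(1, 0, 2 * pi) + phi)
}

truncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate one subject: recording, heart rate, behavior, ground truth
#'
#' Builds the subject's concentration-space signal as
#' `sum_c amplitude_c * response_c + systemic oscillations + coupled scalp
#' component + drift + noise`, forwards it through the modified Beer-Lambert
#' model to two-wavelength intensities (`I = I0 * 10^(-OD)`), and generates a
#' matching 1 Hz heart-rate series and a behavioral record. Short-separation
#' channels carry the scalp component (unit weight) and nuisances but no task
#' response. All randomness derives from the config seed and the subject
#' index, so repeated calls are bit-identical.
#'
#' @param config A [sim_config()].
#' @param subject_index Index within the group (1-based).
#' @param group `"HC"` or `"CLBP"`.
#' @return List with `recording` ([raw_intensity_recording()]), `hr` (tibble
#'   time_s, hr_bpm), `record` (behavioral tibble row) and `truth` (list:
#'   `true_block` tibble of noise-free block values, `responder_channels`,
#'   `scalp` series, `scalp_coupling`, `amplitude_multiplier`, onsets).
#' @export
simulate_subject <- function(config, subject_index, group = c("HC", "CLBP")) {
  group <- match.arg(group)
  seed <- (config$seed * 100003 + subject_index * 1009 +
             ifelse(group == "CLBP", 500009, 0)) %% 2147483629
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  layout <- config$layout
  fs <- layout$sampling_rate
  protocol <- generate_stimulus_sequence(config$protocol, seed = seed + 7)
  nt <- round(protocol_duration_s(protocol) * fs)
  n_ch <- nrow(layout$channels)
  shorts <- layout$channels$channel[layout$channels$is_short]
  longs <- layout$channels$channel[!layout$channels$is_short]

  # --- behavioral record ---------------------------------------------------
  beh <- config$behavioral
  if (group == "CLBP") {
    age <- truncnorm1(1, beh$clbp_age[["mean"]], beh$clbp_age[["sd"]],
                      beh$clbp_age[["lo"]], beh$clbp_age[["hi"]])
    ppt <- truncnorm1(1, beh$clbp_ppt[["mean"]], beh$clbp_ppt[["sd"]], lo = 10)
    record <- tibble::tibble(
      subject = sprintf("CLBP%02d", subject_index), group = group,
      age = age, ppt = ppt,
      nonpainful_force = min(beh$nonpainful_force, 0.6 * ppt),
      pain_detect_current = round(truncnorm1(1, 1.9, 1.1, 0, 5)),
      pain_detect_ave4w = round_half_up(truncnorm1(1, 4.0, 0.7, 0, 10), 1),
      pain_detect_total = round(truncnorm1(1, 5.8, 3.8, 0, 38)),
      rmd = round(truncnorm1(1, 3.7, 2.8, 0, 24)))
  } else {
    age <- truncnorm1(1, beh$hc_age[["mean"]], beh$hc_age[["sd"]],
                      beh$hc_age[["lo"]], beh$hc_age[["hi"]])
    ppt <- truncnorm1(1, beh$hc_ppt[["mean"]], beh$hc_ppt[["sd"]], lo = 10)
    record <- tibble::tibble(
      subject = sprintf("HC%02d", subject_index), group = group,
      age = age, ppt = ppt,
      nonpainful_force = min(beh$nonpainful_force, 0.6 * ppt),
      pain_detect_current = NA_real_, pain_detect_ave4w = NA_real_,
      pain_detect_total = NA_real_, rmd = NA_real_)
  }
  subject_meta <- list(id = record$subject, group = group, age = record$age)

  # --- task responses ------------------------------------------------------
  null_task <- all(config$amplitudes == 0)
  resp <- if (null_task) NULL else
    unit_responses(protocol, layout, config$hrf_shape, config$hrf_scale)
  # The responder channel set is a cohort-level property (drawn from the
  # config seed only), so "null" channels are the same for every subject.
  n_resp_ch <- max(1L, round(config$responder_channel_fraction * length(longs)))
  responder_channels <- if (config$responder_channel_fraction >= 1) {
    longs
  } else if (config$responder_channel_fraction <= 0) {
    integer(0)
  } else {
    keep <- local_seed(config$seed + 424243)
    rc <- sort(sample(longs, n_resp_ch))
    restore_seed(keep)
    rc
  }
  amp_mult <- 1
  if (group == "CLBP" && isTRUE(config$clbp_heterogeneity)) {
    amp_mult <- sample(c(0.3, 1.7), 1)
  }
  task <- matrix(0, n_ch, nt)
  if (!null_task) {
    for (cond in protocol$conditions) {
      amp <- config$amplitudes[[cond]] * amp_mult
      if (length(responder_channels) && amp != 0) {
        task[responder_channels, ] <- task[responder_channels, ] +
          amp * matrix(resp[[cond]], length(responder_channels), nt, byrow = TRUE)
      }
    }
  }

  # --- nuisance components -------------------------------------------------
  t_s <- (seq_len(nt) - 1) / fs
  systemic <- numeric(nt)
  for (s in config$systemic) {
    systemic <- systemic + narrowband_osc(nt, fs, s$freq, s$amp)
  }
  ch_gain <- stats::runif(n_ch, 0.8, 1.2)

  scalp_slow <- as.numeric(stats::filter(stats::rnorm(nt), config$scalp$ar,
                                         method = "recursive"))
  if (stats::sd(scalp_slow) > 0) {
    scalp_slow <- scalp_slow / stats::sd(scalp_slow) * config$scalp$sd
  }
  # Scalp-borne Mayer oscillation (random phase) plus a stimulus-evoked scalp
  # blood-flow response with its own slower, broader kernel: short channels
  # therefore show a task-locked response whose shape differs from the
  # cortical one, as superficial hemodynamics do.
  scalp_osc <- narrowband_osc(nt, fs, config$scalp$osc_freq,
                              config$scalp$osc_amp)
  all_train <- numeric(nt)
  stim_len <- round(protocol$stimulus_s * fs)
  for (i in floor(protocol$sequence$onset_s * fs) + 1L) {
    all_train[i:min(nt, i + stim_len - 1L)] <- 1
  }
  sk <- stats::dgamma(seq(0, 30, by = 1 / fs), shape = config$scalp$task_shape,
                      scale = config$scalp$task_scale)
  sk <- sk / max(sk)
  scalp_task <- conv_train(all_train, sk)
  scalp <- scalp_slow + scalp_osc +
    config$scalp$task_amp * scalp_task / max(abs(scalp_task) + 1e-12)
  coupling <- numeric(n_ch)
  coupling[longs] <- stats::runif(length(longs), config$scalp$coupling[1],
                                  config$scalp$coupling[2])
  coupling[shorts] <- 1

  drift <- t(vapply(seq_len(n_ch), function(i)
    cumsum(stats::rnorm(nt, 0, config$drift_scale / sqrt(fs))),
    numeric(nt)))

  noise_o <- matrix(stats::rnorm(n_ch * nt, 0, config$noise_sd), n_ch, nt)
  noise_h <- matrix(stats::rnorm(n_ch * nt, 0, config$noise_sd), n_ch, nt)

  # Cerebral systemic oscillations are independent of the superficial layer
  # and absent from the short channels (which sample scalp tissue only); the
  # scalp component itself carries the superficial share of systemic
  # physiology (its Mayer-band oscillation) into the long channels via the
  # coupling weights.
  sys_mat <- ch_gain %o% systemic
  sys_mat[shorts, ] <- 0
  nuis <- sys_mat + coupling %o% scalp + drift
  o2hb <- task + nuis + noise_o
  hhb <- config$hhb_ratio * task + config$hhb_nuisance_ratio * nuis + noise_h

  recording <- forward_model(o2hb, hhb, layout, protocol, subject_meta,
                             i0 = config$i0)

  # --- ground-truth block values: the noise-free injected signal passed
  # through the epoch pipeline (segmentation, per-epoch detrend, pre-window
  # normalization, middle-window median). This accounts for response overlap
  # between neighboring trials, so it is exactly what an ideal noise-free
  # analysis would report.
  if (all(task == 0) || identical(config$truth_detail, "amplitude")) {
    grid <- expand.grid(channel = seq_len(n_ch), condition = protocol$conditions,
                        chromophore = c("o2hb", "hhb"),
                        stringsAsFactors = FALSE)
    amp_of <- function(cond, chrom, ch) {
      a <- config$amplitudes[[cond]] * amp_mult *
        as.numeric(ch %in% responder_channels)
      if (chrom == "hhb") a <- a * config$hhb_ratio
      a
    }
    v <- mapply(amp_of, grid$condition, grid$chromophore, grid$channel)
    true_block <- tibble::tibble(channel = grid$channel,
                                 condition = grid$condition,
                                 chromophore = grid$chromophore,
                                 value = as.numeric(v))
  } else {
    clean <- structure(list(
      o2hb = task, hhb = config$hhb_ratio * task,
      time = t_s, fs = fs, layout = layout, protocol = protocol,
      subject = subject_meta,
      filtered = FALSE, detrended = FALSE, ssr_applied = FALSE),
      class = "hb_series")
    es0 <- detrend_normalize_epochs(segment_trials(clean, protocol))
    tb <- block_average(es0)
    true_block <- tb[, c("channel", "condition", "chromophore", "value")]
  }

  # --- heart rate ----------------------------------------------------------
  hr_cfg <- config$hr
  base <- if (group == "CLBP") {
    truncnorm1(1, hr_cfg$clbp_mean, hr_cfg$clbp_sd, lo = 40)
  } else {
    truncnorm1(1, hr_cfg$hc_mean, hr_cfg$hc_sd, lo = 40)
  }
  t_hr <- seq(0, floor(protocol_duration_s(protocol)) - 1)
  bump_kern <- stats::dgamma(seq(0, 25), shape = 4,
                             scale = hr_cfg$bump_peak_s / 3)
  bump_kern <- bump_kern / max(bump_kern)
  train_hr <- numeric(length(t_hr))
  on_sec <- floor(protocol$sequence$onset_s) + 1L
  train_hr[on_sec[on_sec <= length(train_hr)]] <- 1
  hr_bpm <- base + hr_cfg$bump_bpm * conv_train(train_hr, bump_kern) +
    stats::rnorm(length(t_hr), 0, hr_cfg$noise_sd)
  hr_bpm <- pmax(hr_bpm, 30)
  hr <- tibble::tibble(time_s = t_hr, hr_bpm = hr_bpm)

  list(recording = recording, hr = hr, record = record,
       truth = list(true_block = true_block,
                    responder_channels = responder_channels,
                    scalp = scalp, scalp_coupling = coupling,
                    amplitude_multiplier = amp_mult,
                    onsets = protocol$sequence))
}

#' Simulate a full two-group cohort
#'
#' Applies [simulate_subject()] to `n_hc` healthy controls and `n_clbp`
#' patients. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `nirs_cohort`: list with `subjects` (list of
#'   per-subject bundles), `config`.
#' @export
simulate_cohort <- function(config) {
  if (config$n_hc < 1 || config$n_clbp < 1) stop("both groups must be non-empty")
  subjects <- c(
    lapply(seq_len(config$n_hc), function(i) simulate_subject(config, i, "HC")),
    lapply(seq_len(config$n_clbp), function(i) simulate_subject(config, i, "CLBP")))
  structure(list(subjects = subjects, config = config), class = "nirs_cohort")
}

#' Preprocess every subject of a cohort and collect tidy tables
#'
#' Runs the full preprocessing chain on each simulated recording and gathers
#' per-subject block averages, per-trial values, heart-rate summaries and
#' behavioral records into tidy tables keyed by `subject` and `group`.
#'
#' @param cohort A `nirs_cohort`.
#' @param with_trials Also collect per-trial values (needed for screening and
#'   patient-versus-norm analyses).
#' @param with_hr Also collect heart-rate summaries.
#' @param chromophores Chromophores to summarize.
#' @param ... Passed to [preprocess_recording()].
#' @return List with `blocks`, `trials`, `hr_summaries`, `records` tibbles
#'   and `layout`.
#' @export
preprocess_cohort <- function(cohort, with_trials = TRUE, with_hr = TRUE,
                              chromophores = c("o2hb", "hhb"), ...) {
  blocks <- list(); trials <- list(); hrs <- list(); recs <- list()
  for (s in cohort$subjects) {
    es <- preprocess_recording(s$recording, ...)
    id <- s$record$subject
    grp <- s$record$group
    b <- block_average(es, chromophores = chromophores)
    b$subject <- id; b$group <- grp
    blocks[[id]] <- b
    if (with_trials) {
      tr <- per_trial_values(es, chromophores = chromophores)
      tr$subject <- id; tr$group <- grp
      trials[[id]] <- tr
    }
    if (with_hr) {
      h <- hr_trial_summaries(s$hr, s$recording$protocol)
      h$subject <- id; h$group <- grp
      hrs[[id]] <- h
    }
    recs[[id]] <- s$record
  }
  list(blocks = dplyr::bind_rows(blocks),
       trials = if (with_trials) dplyr::bind_rows(trials) else NULL,
       hr_summaries = if (with_hr) dplyr::bind_rows(hrs) else NULL,
       records = dplyr::bind_rows(recs),
       layout = cohort$config$layout)
}
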