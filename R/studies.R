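#' Verification studies
#'
#' These functions run the package's standard simulation studies: Monte-Carlo
#' checks that the full pipeline controls the false-discovery rate on null
#' data, recovers injected response amplitudes, removes the superficial
#' (scalp) component, and that the responder-only analysis mode is at least
#' as specific as the all-channel mode. They are used by the test suite and
#' by the reproduction script; all are deterministic in their `seed`.
#'
#' The studies run on shortened recordings (shorter baseline, fewer trials
#' per condition) so that hundreds of simulated cohorts complete on a single
#' CPU; the protocol structure (18 channels, 7.81 Hz, 5 s stimuli, 15 s ISI,
#' 12 + 20 subjects) is unchanged. The methods vignette discusses these
#' problem sizes.
#'
#' @name verification-studies
NULL

#' Null-cohort false-discovery-rate study
#'
#' Simulates `n_cohorts` cohorts with zero response amplitude everywhere
#' (12 patients + 20 controls each), runs the full pipeline (optics,
#' filtering, SSR, epoching, block averages) and the complete within-group
#' and between-group statistical battery, and measures the fraction of
#' channel-wise tests rejected at q < 0.05.
#'
#' @param n_cohorts Number of simulated null cohorts.
#' @param seed Base seed.
#' @param trials_per_condition,baseline_s Reduced protocol dimensions.
#' @return List: `fraction` (rejected share), `n_tests`, `threshold`
#'   (0.05 + 3 binomial SE), `pass`.
#' @export
study_null_fdr <- function(n_cohorts = 200, seed = 1,
                           trials_per_condition = 3, baseline_s = 12) {
  proto <- stimulus_protocol(baseline_s = baseline_s,
                             trials_per_condition = trials_per_condition)
  n_sig <- 0L
  n_tests <- 0L
  for (k in seq_len(n_cohorts)) {
    cfg <- sim_config(seed = seed * 1000 + k, protocol = proto,
                      amplitudes = c(PAPain = 0, PAnP = 0, Brush = 0))
    coh <- simulate_cohort(cfg)
    pp <- preprocess_cohort(coh, with_trials = FALSE, with_hr = FALSE)
    st <- dplyr::bind_rows(lapply(c("HC", "CLBP"), function(g)
      run_analysis(pp$blocks[pp$blocks$group == g, ], NULL, pp$layout,
                   group = g, modes = "All")))
    bg <- between_group_compare(pp$blocks[pp$blocks$group == "HC", ],
                                pp$blocks[pp$blocks$group == "CLBP", ],
                                pp$layout)
    all_q <- c(st$significant[!is.na(st$q)], bg$significant[!is.na(bg$q)])
    n_sig <- n_sig + sum(all_q)
    n_tests <- n_tests + length(all_q)
  }
  fraction <- n_sig / n_tests
  threshold <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_tests)
  list(fraction = fraction, n_tests = n_tests, threshold = threshold,
       pass = fraction <= threshold)
}

#' Amplitude-recovery study
#'
#' Simulates subjects with a known injected oxyhemoglobin response, runs the
#' full default pipeline and compares the recovered block averages with the
#' generator's ground truth (the noise-free signal passed through the same
#' epoch pipeline). Reported per condition: the median, over responder
#' channels and subjects, of recovered / true.
#'
#' @param seed Base seed.
#' @param n_subjects Subjects per noise regime.
#' @param snr `"high"` (nuisance amplitudes scaled down ~10x) or
#'   `"default"` (the study-level noise configuration).
#' @return Tibble: condition, snr, median_ratio, median_abs_error (relative).
#' @export
study_amplitude_recovery <- function(seed = 1, n_subjects = 3,
                                     snr = c("high", "default")) {
  snr <- match.arg(snr)
  cfg <- if (snr == "high") {
    sim_config(seed = seed,
               systemic = list(mayer = list(freq = 0.1, amp = 0.01),
                               resp = list(freq = 0.25, amp = 0.01),
                               cardiac = list(freq = 1.1, amp = 0.03)),
               scalp = list(sd = 0.1, osc_amp = 0.1, osc_freq = 0.1,
                            task_amp = 0.05, task_shape = 2, task_scale = 1.5,
                            coupling = c(0.3, 0.7), ar = 0.995),
               drift_scale = 0.005, noise_sd = 0.02)
  } else {
    sim_config(seed = seed)
  }
  rows <- list()
  for (i in seq_len(n_subjects)) {
    s <- simulate_subject(cfg, i, "HC")
    es <- preprocess_recording(s$recording)
    ba <- block_average(es)
    m <- dplyr::inner_join(ba, s$truth$true_block,
                           by = c("channel", "condition", "chromophore"),
                           suffix = c("", "_true"))
    m <- m[m$chromophore == "o2hb" & m$channel %in% s$truth$responder_channels, ]
    rows[[i]] <- tibble::tibble(condition = m$condition,
                                ratio = m$value / m$value_true)
  }
  all_rows <- dplyr::bind_rows(rows)
  per_cond <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$condition),
    median_ratio = stats::median(.data$ratio),
    median_abs_error = stats::median(abs(.data$ratio - 1)),
    .groups = "drop")
  pooled <- tibble::tibble(condition = "pooled",
                           median_ratio = stats::median(all_rows$ratio),
                           median_abs_error = abs(stats::median(all_rows$ratio) - 1))
  dplyr::mutate(dplyr::bind_rows(pooled, per_cond), snr = snr)
}

#' Scalp-removal (SSR efficacy) study, per-epoch regression regime
#'
#' Simulates subjects at the default noise configuration, runs the pipeline
#' with per-epoch short-separation regression and measures how much of the
#' injected scalp component survives in the corrected long channels. The
#' residual scalp in a corrected epoch is `(w - beta) * s`, with `w` the true
#' coupling weight, `beta` the fitted coefficient and `s` the epoch-processed
#' true scalp series; the statistic is the variance of the residual summed
#' over epochs and long channels, relative to the injected variance
#' `w^2 * var(s)`.
#'
#' @param seed Base seed.
#' @param n_subjects Number of subjects.
#' @return List: `residual_fraction`, `pass` (<= 0.05).
#' @export
study_ssr_efficacy <- function(seed = 1, n_subjects = 2) {
  # Designed removal experiment: a pronounced scalp component is injected
  # (strong superficial contamination) and the response amplitudes are zero,
  # so the statistic isolates how much of the injected component the
  # regression removes. With a weak injection the per-epoch coefficient is
  # dominated by its own sampling noise, and with a task response present it
  # additionally absorbs evoked signal (the collinearity discussed in the
  # methods vignette) — both different phenomena from scalp removal.
  cfg <- sim_config(seed = seed,
                    protocol = stimulus_protocol(baseline_s = 60,
                                                 trials_per_condition = 10),
                    amplitudes = c(PAPain = 0, PAnP = 0, Brush = 0),
                    scalp = list(sd = 1.2, osc_amp = 1.5, osc_freq = 0.1,
                                 task_amp = 0.5, task_shape = 2,
                                 task_scale = 1.5, coupling = c(0.3, 0.7),
                                 ar = 0.995))
  num <- 0; den <- 0
  for (i in seq_len(n_subjects)) {
    s <- simulate_subject(cfg, i, "CLBP")
    es <- preprocess_recording(s$recording, ssr_scope = "per_epoch")
    betas <- attr(es, "ssr_beta")
    # epoch-process the true scalp series exactly like the data
    lay <- s$recording$layout
    scalp_hb <- structure(list(
      o2hb = matrix(s$truth$scalp, nrow(lay$channels), length(s$truth$scalp),
                    byrow = TRUE),
      hhb = matrix(0, nrow(lay$channels), length(s$truth$scalp)),
      time = (seq_along(s$truth$scalp) - 1) / lay$sampling_rate,
      fs = lay$sampling_rate, layout = lay,
      protocol = s$recording$protocol, subject = s$recording$subject,
      filtered = FALSE, detrended = FALSE, ssr_applied = FALSE),
      class = "hb_series")
    scalp_es <- detrend_normalize_epochs(segment_trials(scalp_hb))
    w <- s$truth$scalp_coupling
    for (cond in es$conditions) {
      s_ep <- scalp_es$data$o2hb[[cond]][1, , ]  # identical across channels
      v_ep <- apply(s_ep, 2, stats::var)         # per-trial scalp variance
      b <- betas[betas$chromophore == "o2hb" & betas$condition == cond, ]
      for (j in seq_along(v_ep)) {
        bj <- b[b$trial == j, ]
        num <- num + sum((w[bj$channel] - bj$beta)^2 * v_ep[j])
        den <- den + sum(w[bj$channel]^2 * v_ep[j])
      }
    }
  }
  res <- num / den
  list(residual_fraction = res, pass = res <= 0.05)
}

#' Responder-mode specificity study
#'
#' Simulates mixed cohorts in which only half of the long channels carry a
#' response and compares the false-positive channel rate (null channels
#' declared significant against baseline, oxyhemoglobin) between the
#' all-channel and the responder-screened analysis modes.
#'
#' @param n_cohorts Number of cohorts.
#' @param seed Base seed.
#' @param trials_per_condition,baseline_s Reduced protocol dimensions
#'   (screening needs enough trials for a single-subject test to be able to
#'   reach p < 0.05; 6 trials give a minimal two-sided exact p of 0.031).
#' @return List: `fp_all`, `fp_responders`, `tp_all`, `tp_responders`,
#'   `pass` (`fp_responders <= fp_all`).
#' @export
study_responders_specificity <- function(n_cohorts = 100, seed = 1,
                                         trials_per_condition = 6,
                                         baseline_s = 12) {
  proto <- stimulus_protocol(baseline_s = baseline_s,
                             trials_per_condition = trials_per_condition)
  fp <- c(All = 0L, Responders = 0L)
  tp <- c(All = 0L, Responders = 0L)
  n_null <- 0L
  n_resp <- 0L
  for (k in seq_len(n_cohorts)) {
    cfg <- sim_config(seed = seed * 1000 + k, protocol = proto,
                      responder_channel_fraction = 0.5,
                      truth_detail = "amplitude")
    coh <- simulate_cohort(cfg)
    pp <- preprocess_cohort(coh, with_hr = FALSE, chromophores = "o2hb")
    resp_ch <- coh$subjects[[1]]$truth$responder_channels
    longs <- long_channels(pp$layout)
    null_ch <- setdiff(longs, resp_ch)
    for (g in c("HC", "CLBP")) {
      blocks <- pp$blocks[pp$blocks$group == g & pp$blocks$chromophore == "o2hb", ]
      trials <- pp$trials[pp$trials$group == g & pp$trials$chromophore == "o2hb", ]
      st <- suppressWarnings(
        run_analysis(blocks, trials, pp$layout, group = g,
                     modes = c("All", "Responders"), tests = "vs_baseline"))
      vb <- st[st$test == "vs_baseline_signed_rank", ]
      for (mode in c("All", "Responders")) {
        sig <- vb[vb$mode == mode & !is.na(vb$significant) & vb$significant, ]
        fp[[mode]] <- fp[[mode]] + sum(sig$channel %in% null_ch)
        tp[[mode]] <- tp[[mode]] + sum(sig$channel %in% resp_ch)
      }
      n_null <- n_null + length(null_ch) * 3  # 3 conditions
      n_resp <- n_resp + length(resp_ch) * 3
    }
  }
  list(fp_all = fp[["All"]] / n_null,
       fp_responders = fp[["Responders"]] / n_null,
       tp_all = tp[["All"]] / n_resp,
       tp_responders = tp[["Responders"]] / n_resp,
       pass = fp[["Responders"]] <= fp[["All"]])
}
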