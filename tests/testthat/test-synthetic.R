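test_that("simulation is deterministic and structurally consistent", {
  cfg <- quiet_config(seed = 5, protocol = tiny_protocol(trials = 3))
  s1 <- simulate_subject(cfg, 1, "HC")
  s2 <- simulate_subject(cfg, 1, "HC")
  expect_identical(s1$recording$intensity, s2$recording$intensity)
  expect_identical(s1$hr, s2$hr)
  expect_identical(s1$record, s2$record)
  # different subjects differ
  s3 <- simulate_subject(cfg, 2, "HC")
  expect_false(identical(s1$recording$intensity, s3$recording$intensity))
  # dimensions: 18 channels x 2 wavelengths x fs * duration
  nt <- round(protocol_duration_s(s1$recording$protocol) * 7.81)
  expect_equal(dim(s1$recording$intensity), c(18, 2, nt))
  expect_true(all(s1$recording$intensity > 0))
  # HR series: 1 Hz, positive
  expect_equal(nrow(s1$hr), floor(protocol_duration_s(s1$recording$protocol)))
  expect_true(all(s1$hr$hr_bpm > 0))
  # behavioral invariant: ppt > nonpainful force > 0
  expect_gt(s1$record$ppt, s1$record$nonpainful_force)
  expect_gt(s1$record$nonpainful_force, 0)
})

test_that("cohorts have the study group sizes and valid records", {
  cfg <- quiet_config(seed = 6, n_hc = 4, n_clbp = 3,
                      protocol = tiny_protocol(trials = 2))
  coh <- simulate_cohort(cfg)
  expect_length(coh$subjects, 7)
  groups <- vapply(coh$subjects, function(s) s$record$group, character(1))
  expect_equal(sum(groups == "HC"), 4)
  expect_equal(sum(groups == "CLBP"), 3)
  expect_error(simulate_cohort(quiet_config(n_hc = 0)), "non-empty")
  # patient questionnaires present, control questionnaires absent
  recs <- dplyr::bind_rows(lapply(coh$subjects, `[[`, "record"))
  expect_true(all(is.na(recs$rmd[recs$group == "HC"])))
  expect_true(all(!is.na(recs$rmd[recs$group == "CLBP"])))
})

test_that("generated long channels carry the configured spectral peaks", {
  cfg <- sim_config(seed = 7, protocol = stimulus_protocol(
    baseline_s = 60, trials_per_condition = 6),
    amplitudes = c(PAPain = 0, PAnP = 0, Brush = 0),
    noise_sd = 0.02, drift_scale = 0.001,
    scalp = list(sd = 0.02, osc_amp = 0.02, osc_freq = 0.1, task_amp = 0,
                 task_shape = 2, task_scale = 1.5, coupling = c(0.3, 0.7),
                 ar = 0.995))
  s <- simulate_subject(cfg, 1, "HC")
  hb <- mbll_convert(intensity_to_od(s$recording, reference = "i0"))
  x <- hb$o2hb[5, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 7.81), plot = FALSE,
                          taper = 0, detrend = TRUE)
  peak_near <- function(f0, half = 0.05) {
    band <- sp$freq > f0 - half & sp$freq < f0 + half
    out <- sp$freq > 1.5 & sp$freq < 3   # quiet reference band
    mean(sp$spec[band]) / mean(sp$spec[out])
  }
  expect_gt(peak_near(0.1), 10)    # Mayer band
  expect_gt(peak_near(0.25), 10)   # respiration
  expect_gt(peak_near(1.1), 10)    # cardiac
})

test_that("short channels carry scalp but no task response", {
  cfg <- quiet_config(seed = 8, protocol = tiny_protocol(trials = 4),
                      noise_sd = 0.001)
  s <- simulate_subject(cfg, 1, "HC")
  hb <- mbll_convert(intensity_to_od(s$recording, reference = "i0"))
  # short channels correlate ~1 with the injected scalp series
  for (sc in c(2, 10)) {
    expect_gt(stats::cor(hb$o2hb[sc, ], s$truth$scalp), 0.95)
  }
  # long-channel scalp correlation reflects the coupling, not unity
  expect_lt(stats::cor(hb$o2hb[1, ], s$truth$scalp), 0.9)
  # truth table marks every long channel as responding at the configured amp
  tb <- s$truth$true_block
  expect_setequal(s$truth$responder_channels,
                  build_default_layout()$channels$channel[
                    !build_default_layout()$channels$is_short])
  expect_equal(nrow(tb), 18 * 3 * 2)
})

test_that("a null configuration yields block averages centered on zero", {
  cfg <- quiet_config(seed = 9, protocol = tiny_protocol(trials = 4),
                      amplitudes = c(PAPain = 0, PAnP = 0, Brush = 0),
                      noise_sd = 0.2)
  s <- simulate_subject(cfg, 1, "CLBP")
  es <- preprocess_recording(s$recording)
  ba <- block_average(es)
  expect_true(all(s$truth$true_block$value == 0))
  expect_lt(abs(mean(ba$value)), 0.1)
  # and single-subject screening stays near the nominal rate
  tr <- per_trial_values(es)
  tr$subject <- "S1"
  scr <- screen_single_subject(tr)
  expect_lt(mean(scr$responder), 0.25)
})

test_that("forward model round-trips and scales linearly", {
  lay <- build_default_layout()
  proto <- generate_stimulus_sequence(tiny_protocol(trials = 2), seed = 9)
  subj <- list(id = "T", group = "HC", age = 28)
  nt <- 300
  set.seed(36)
  o2 <- matrix(stats::rnorm(18 * nt, 0, 0.4), 18)
  hh <- matrix(stats::rnorm(18 * nt, 0, 0.2), 18)
  rec <- forward_model(o2, hh, lay, proto, subj)
  back <- mbll_convert(intensity_to_od(rec, reference = "i0"))
  expect_equal(back$o2hb, o2, tolerance = 1e-9)
  expect_equal(back$hhb, hh, tolerance = 1e-9)
  # zero concentrations give constant intensities
  recz <- forward_model(o2 * 0, hh * 0, lay, proto, subj)
  expect_equal(max(apply(recz$intensity, c(1, 2), function(v) diff(range(v)))), 0)
  # scaling concentrations scales OD linearly
  rec2 <- forward_model(2 * o2, 2 * hh, lay, proto, subj)
  od1 <- intensity_to_od(rec, reference = "i0")$od
  od2 <- intensity_to_od(rec2, reference = "i0")$od
  expect_equal(od2, 2 * od1, tolerance = 1e-9)
})

test_that("amplitude calibration makes the noise-free pipeline exact", {
  # a noise-free subject analyzed without SSR recovers the configured
  # amplitude up to SG filter effects only
  cfg <- sim_config(seed = 10,
                    protocol = stimulus_protocol(baseline_s = 60,
                                                 trials_per_condition = 5),
                    systemic = list(mayer = list(freq = 0.1, amp = 0),
                                    resp = list(freq = 0.25, amp = 0),
                                    cardiac = list(freq = 1.1, amp = 0)),
                    scalp = list(sd = 0, osc_amp = 0, osc_freq = 0.1,
                                 task_amp = 0, task_shape = 2, task_scale = 1.5,
                                 coupling = c(0.3, 0.7), ar = 0.995),
                    drift_scale = 0, noise_sd = 0)
  s <- simulate_subject(cfg, 1, "HC")
  hb <- mbll_convert(intensity_to_od(s$recording, reference = "i0"))
  es <- detrend_normalize_epochs(segment_trials(hb))
  ba <- block_average(es)
  m <- dplyr::inner_join(ba, s$truth$true_block,
                         by = c("channel", "condition", "chromophore"))
  expect_equal(m$value.x, m$value.y, tolerance = 1e-8)
})
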