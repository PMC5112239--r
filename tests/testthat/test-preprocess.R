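fs <- 7.81

test_that("SG smoothing reproduces polynomials and attenuates cardiac band", {
  t <- (0:2000) / fs
  # constant and cubic pass unchanged (both window lengths)
  for (ws in c(4, 80)) {
    if (ws * fs < length(t)) {
      poly <- 0.3 - 0.1 * t + 0.02 * t^2 - 1e-4 * t^3
      hb <- make_hb(rbind(poly, rep(2, length(t))))
      sm <- sg_smooth(hb, ws, 3)
      expect_equal(sm$o2hb[1, ], poly, tolerance = 1e-9)
      expect_equal(sm$o2hb[2, ], rep(2, length(t)), tolerance = 1e-12)
    }
  }
  # frequency response: 1 Hz attenuated relative to 0.02 Hz, and the
  # mid-series gain matches the kernel's DFT response
  F <- painfnirs:::sg_projection(3, 31)
  kernel <- F[16, ]
  g1 <- oracle_fir_response(kernel, 1, fs)
  g002 <- oracle_fir_response(kernel, 0.02, fs)
  expect_lt(g1, g002)
  s1 <- sin(2 * pi * 1 * t)
  sm1 <- sg_smooth(make_hb(rbind(s1)), 4, 3)$o2hb[1, ]
  mid <- 500:1500
  gain_measured <- max(abs(sm1[mid])) / max(abs(s1[mid]))
  expect_equal(gain_measured, g1, tolerance = 0.02)
  expect_error(sg_smooth(make_hb(rbind(s1)), 0.2, 3), "window")
})

test_that("SG detrend removes slow drift, matches the convolution oracle", {
  t <- (0:3200) / fs
  drift <- 0.5 + 0.01 * t + 0.3 * sin(2 * pi * t / 300)
  hb <- make_hb(rbind(drift))
  out <- sg_detrend(hb, 80, 3)$o2hb[1, ]
  expect_lt(max(abs(out)), 0.005)  # pure drift -> ~0
  # linear drift exactly zero
  lin <- make_hb(rbind(1 + 0.2 * t))
  expect_lt(max(abs(sg_detrend(lin, 80, 3)$o2hb[1, ])), 1e-9)
  # residual = x - conv(x, central kernel) in the interior (direct oracle)
  set.seed(8)
  x <- stats::rnorm(length(t))
  res <- sg_detrend(make_hb(rbind(x)), 80, 3)$o2hb[1, ]
  F <- painfnirs:::sg_projection(3, 625)
  kern <- F[313, ]
  i <- 1000
  sm_i <- sum(kern * x[(i - 312):(i + 312)])
  expect_equal(res[i], x[i] - sm_i, tolerance = 1e-9)
  # white noise: trend removal cannot increase variance
  expect_lte(stats::var(res), stats::var(x))
  # embedded 25 s boxcar after drift removal: center amplitude preserved
  # within the filter's actual passband loss (~22%)
  box <- as.numeric(t >= 200 & t < 225)
  hb2 <- make_hb(rbind(drift + box))
  out2 <- sg_detrend(hb2, 80, 3)$o2hb[1, ]
  amp <- mean(out2[t >= 205 & t <= 220]) - mean(out2[t >= 190 & t < 200])
  expect_gt(amp, 0.75)
  expect_lt(amp, 1.05)
})

test_that("segmentation yields equal-length epochs at the documented grid", {
  proto <- generate_stimulus_sequence(stimulus_protocol(), seed = 4)
  nt <- round(protocol_duration_s(proto) * fs)
  lay <- build_default_layout()
  set.seed(9)
  hb <- make_hb(matrix(stats::rnorm(18 * nt), 18), layout = lay,
                protocol = proto)
  es <- segment_trials(hb)
  # 15 epochs per condition, 45 total
  expect_equal(sort(names(es$data$o2hb)), sort(proto$conditions))
  for (cond in proto$conditions) {
    expect_equal(dim(es$data$o2hb[[cond]]), c(18, es$n_samples, 15))
  }
  # epoch sample count equals the arithmetic oracle round(12.8 * fs)
  expect_equal(es$n_samples, round((3.9 + 5 + 3.9) * fs))
  expect_equal(es$n_samples, 100)
  expect_equal(es$pre_index, round(3.9 * fs))
  # pre-window ends one sample before the onset sample
  expect_lt(es$rel_time[es$pre_index], 0)
  expect_equal(es$rel_time[es$pre_index + 1], 0)
  # segmentation is deterministic/bit-reproducible
  expect_identical(es$data, segment_trials(hb)$data)
  # epochs outside the recording are reported by trial index
  short_hb <- make_hb(matrix(1.0, 18, 500), layout = lay, protocol = proto)
  expect_error(segment_trials(short_hb), "trial")
  # epoch content matches direct slicing for a known trial
  on_idx <- floor(proto$sequence$onset_s[1] * fs) + 1
  cond1 <- proto$sequence$condition[1]
  expect_equal(es$data$o2hb[[cond1]][, , 1],
               hb$o2hb[, (on_idx - 30):(on_idx + 69)])
})

test_that("per-epoch detrend + normalization behaves like least squares", {
  proto <- generate_stimulus_sequence(tiny_protocol(), seed = 5)
  lay <- build_default_layout()
  nt <- round(protocol_duration_s(proto) * fs)
  # a pure ramp maps to ~zero after linear detrend
  ramp <- matrix(rep(seq_len(nt) * 0.01, each = 18), 18)
  es <- detrend_normalize_epochs(segment_trials(
    make_hb(ramp, layout = lay, protocol = proto)))
  expect_lt(max(abs(es$data$o2hb[[1]])), 1e-10)
  # pre-window median is exactly zero for arbitrary data
  set.seed(10)
  noisy <- matrix(stats::rnorm(18 * nt), 18)
  es2 <- detrend_normalize_epochs(segment_trials(
    make_hb(noisy, layout = lay, protocol = proto)))
  pre <- seq_len(es2$pre_index)
  for (cond in es2$conditions) {
    meds <- apply(es2$data$o2hb[[cond]][, pre, , drop = FALSE], c(1, 3),
                  stats::median)
    expect_lt(max(abs(meds)), 1e-12)
  }
  # the removed line matches the normal-equations solution per epoch
  raw_es <- segment_trials(make_hb(noisy, layout = lay, protocol = proto))
  cond <- raw_es$conditions[1]
  before <- raw_es$data$o2hb[[cond]][4, , 2]
  after <- es2$data$o2hb[[cond]][4, , 2]
  x <- seq_along(before)
  fit <- stats::lm.fit(cbind(1, x), before)
  manual <- before - fit$fitted.values
  manual <- manual - stats::median(manual[pre])
  expect_equal(after, manual, tolerance = 1e-10)
})

test_that("short-separation regression is an orthogonal projection", {
  set.seed(12)
  short <- stats::rnorm(300)
  # proportional long channel is annihilated, beta recovered
  r <- short_separation_regression(2.5 * short, short)
  expect_equal(r$beta, 2.5, tolerance = 1e-12)
  expect_lt(max(abs(r$corrected)), 1e-12)
  # orthogonal long channel passes through with beta 0
  long_orth <- stats::rnorm(300)
  long_orth <- long_orth - sum(long_orth * short) / sum(short^2) * short
  r2 <- short_separation_regression(long_orth, short)
  expect_equal(r2$beta, 0, tolerance = 1e-12)
  expect_equal(r2$corrected, long_orth, tolerance = 1e-12)
  # random pairs match the one-regressor normal equations and never gain SS
  for (i in 1:20) {
    l <- stats::rnorm(100); s <- stats::rnorm(100)
    r3 <- short_separation_regression(l, s)
    expect_equal(r3$beta, sum(l * s) / sum(s * s), tolerance = 1e-12)
    expect_lt(abs(sum(r3$corrected * s)), 1e-8)   # orthogonality
    expect_lte(sum(r3$corrected^2), sum(l^2) + 1e-12)
  }
  expect_error(short_separation_regression(stats::rnorm(10), rep(1, 10)),
               "variance")
})

test_that("apply_ssr routes corrections through the SSR map", {
  proto <- generate_stimulus_sequence(tiny_protocol(), seed = 6)
  lay <- build_default_layout()
  nt <- round(protocol_duration_s(proto) * fs)
  set.seed(13)
  base <- matrix(stats::rnorm(18 * nt, 0, 0.1), 18)
  hb1 <- make_hb(base, 0.5 * base, layout = lay, protocol = proto)
  # perturbing short channel 2 changes only channels 1, 3-6
  base2 <- base
  base2[2, ] <- base[2, ] + sin(seq_len(nt) / 10)
  hb2 <- make_hb(base2, 0.5 * base2, layout = lay, protocol = proto)
  es1 <- apply_ssr(detrend_normalize_epochs(segment_trials(hb1)))
  es2 <- apply_ssr(detrend_normalize_epochs(segment_trials(hb2)))
  changed <- vapply(1:18, function(ch) {
    any(abs(es1$data$o2hb[[1]][ch, , ] - es2$data$o2hb[[1]][ch, , ]) > 1e-12)
  }, logical(1))
  expect_true(all(changed[c(1, 2, 3, 4, 5, 6)]))  # 2 itself + its targets
  expect_false(any(changed[7:18]))
  # zero-variance short channel raises
  base3 <- base
  base3[10, ] <- 5
  hb3 <- make_hb(base3, 0.5 * base3, layout = lay, protocol = proto)
  expect_error(apply_ssr(hb3), "variance")
  # an injected common scalp component is essentially removed (continuous)
  scalp <- as.numeric(scale(cumsum(stats::rnorm(nt))))
  withscalp <- base
  withscalp[2, ] <- withscalp[2, ] + scalp
  withscalp[10, ] <- withscalp[10, ] + scalp
  longs <- lay$channels$channel[!lay$channels$is_short]
  for (ch in longs) withscalp[ch, ] <- withscalp[ch, ] + 0.5 * scalp
  hb4 <- make_hb(withscalp, 0.5 * withscalp, layout = lay, protocol = proto)
  corr <- apply_ssr(hb4)
  # residual correlation with the scalp series is tiny
  for (ch in c(1, 9, 18)) {
    expect_lt(abs(stats::cor(corr$o2hb[ch, ], scalp)), 0.1)
  }
})
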