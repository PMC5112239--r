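# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms and direct
# convolution only.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the observed (possibly tied) ranks.
oracle_signed_rank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(r)
  sums <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  tol <- 1e-9
  min(1, 2 * min(mean(sums <= w + tol), mean(sums >= w - tol)))
}

# Exact two-sided rank-sum p by enumerating all allocations of pooled ranks.
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  tol <- 1e-9
  min(1, 2 * min(mean(sums <= w + tol), mean(sums >= w - tol)))
}

# Friedman chi-squared by direct rank arithmetic (tie-free classic formula).
oracle_friedman_chisq <- function(m) {
  n <- nrow(m); k <- ncol(m)
  rk <- t(apply(m, 1, rank))
  Rj <- colSums(rk)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

# Hand-stepped Benjamini-Hochberg adjusted q-values.
oracle_bh_q <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Magnitude response of a symmetric FIR kernel at frequency f (Hz).
oracle_fir_response <- function(kernel, f, fs) {
  n <- length(kernel)
  j <- seq_len(n) - (n + 1) / 2
  abs(sum(kernel * exp(-2i * pi * f * j / fs)))
}

# Run-length/count checker for stimulus sequences (independent scan).
oracle_sequence_ok <- function(labels, trials_per_condition, max_run) {
  counts <- table(labels)
  if (any(counts != trials_per_condition)) return(FALSE)
  run <- 1
  for (i in seq_along(labels)[-1]) {
    run <- if (labels[i] == labels[i - 1]) run + 1 else 1
    if (run > max_run) return(FALSE)
  }
  TRUE
}

# Small fast protocols/configs shared by tests.
tiny_protocol <- function(trials = 3, baseline_s = 12) {
  stimulus_protocol(baseline_s = baseline_s, trials_per_condition = trials)
}

quiet_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    systemic = list(mayer = list(freq = 0.1, amp = 0.01),
                    resp = list(freq = 0.25, amp = 0.01),
                    cardiac = list(freq = 1.1, amp = 0.03)),
    scalp = list(sd = 0.1, osc_amp = 0.1, osc_freq = 0.1,
                 task_amp = 0.05, task_shape = 2, task_scale = 1.5,
                 coupling = c(0.3, 0.7), ar = 0.995),
    drift_scale = 0.005, noise_sd = 0.02)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Minimal hb_series wrapper around a channel x time matrix.
make_hb <- function(o2hb, hhb = o2hb * 0, fs = 7.81, layout = NULL,
                    protocol = NULL, subject = list(id = "T", age = 30)) {
  structure(list(o2hb = o2hb, hhb = hhb,
                 time = (seq_len(ncol(o2hb)) - 1) / fs, fs = fs,
                 layout = layout, protocol = protocol, subject = subject,
                 filtered = FALSE, detrended = FALSE, ssr_applied = FALSE),
            class = "hb_series")
}
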