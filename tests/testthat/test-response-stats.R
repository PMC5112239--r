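toy_epochs <- function(values_by_cond, n_ch = 3, fs = 7.81) {
  # Build a normalized epoch_set whose middle-window samples are fully known.
  ns <- 100; npre <- 30
  conds <- names(values_by_cond)
  data <- list(o2hb = list(), hhb = list())
  for (cond in conds) {
    v <- values_by_cond[[cond]]  # one value per trial
    arr <- array(0, c(n_ch, ns, length(v)))
    for (j in seq_along(v)) arr[, , j] <- v[j]
    data$o2hb[[cond]] <- arr
    data$hhb[[cond]] <- -arr / 3
  }
  structure(list(data = data, conditions = conds, fs = fs, pre_index = npre,
                 n_samples = ns, rel_time = (seq_len(ns) - npre - 1) / fs,
                 stimulus_s = 5, layout = build_default_layout(),
                 subject = list(id = "T"), normalized = TRUE,
                 ssr_applied = TRUE),
            class = "epoch_set")
}

test_that("block averages equal sort-based medians of the middle window", {
  # constant epochs: both modes give the constant
  es <- toy_epochs(list(PAPain = rep(0.7, 4), PAnP = rep(-0.2, 4),
                        Brush = rep(0, 4)))
  for (mode in c("pooled_median", "median_of_trial_medians")) {
    ba <- block_average(es, mode)
    expect_equal(ba$value[ba$condition == "PAPain" & ba$chromophore == "o2hb"],
                 rep(0.7, 3))
    expect_equal(ba$value[ba$condition == "PAnP" & ba$chromophore == "hhb"],
                 rep(0.2 / 3, 3))  # -v/3 with v = -0.2
  }
  # two-trial toy: pooled median vs sort oracle
  es2 <- toy_epochs(list(PAPain = c(0.2, 0.8), PAnP = c(0, 0), Brush = c(0, 0)))
  win <- which(es2$rel_time >= 1.25 & es2$rel_time <= 3.75)
  pooled <- median(c(rep(0.2, length(win)), rep(0.8, length(win))))
  ba2 <- block_average(es2, "pooled_median")
  expect_equal(ba2$value[ba2$condition == "PAPain" & ba2$chromophore == "o2hb"][1],
               pooled)
  # single-trial sets: both modes coincide
  es3 <- toy_epochs(list(PAPain = 0.4, PAnP = 0.1, Brush = 0))
  expect_equal(block_average(es3, "pooled_median")$value,
               block_average(es3, "median_of_trial_medians")$value)
  # per-trial values: count and content
  tv <- per_trial_values(es2)
  papain <- tv[tv$condition == "PAPain" & tv$chromophore == "o2hb" &
                 tv$channel == 1, ]
  expect_equal(sort(papain$value), c(0.2, 0.8))
  expect_equal(nrow(papain), 2)
})

test_that("grand averages use the subject median and the SEMed closed form", {
  blocks <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:7), each = 2),
    channel = rep(1:2, 7), condition = "PAPain", chromophore = "o2hb",
    value = c(rbind(c(5, 3, 8, 1, 9, 2, 7), c(1, 1, 1, 1, 1, 1, 1))))
  ga <- grand_average(blocks, group = "HC")
  # odd-n median equals the middle order statistic
  expect_equal(ga$median[ga$channel == 1], sort(c(5, 3, 8, 1, 9, 2, 7))[4])
  expect_equal(ga$semed[ga$channel == 1],
               1.2533 * sd(c(5, 3, 8, 1, 9, 2, 7)) / sqrt(7))
  # identical subject values: median v, SEMed 0
  expect_equal(ga$median[ga$channel == 2], 1)
  expect_equal(ga$semed[ga$channel == 2], 0)
  # invariant under subject reordering
  ga2 <- grand_average(blocks[sample(nrow(blocks)), ], group = "HC")
  expect_equal(dplyr::arrange(ga2, channel)$median,
               dplyr::arrange(ga, channel)$median)
  expect_error(grand_average(blocks[blocks$subject == "S01", ]), "2 subjects")
})

test_that("SEMed approximates the bootstrap SE of the median on Gaussian data", {
  set.seed(21)
  v <- stats::rnorm(40, 2, 1.5)
  blocks <- tibble::tibble(subject = sprintf("S%02d", 1:40), channel = 1,
                           condition = "PAPain", chromophore = "o2hb",
                           value = v)
  asym <- grand_average(blocks)$semed
  boot <- sd(vapply(1:10000, function(i) median(sample(v, replace = TRUE)),
                    numeric(1)))
  expect_lt(abs(asym - boot) / boot, 0.15)
})

test_that("signed-rank p-values match full enumeration, including ties", {
  # symmetric n = 6 case against the 2^6 enumeration
  x <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(wilcoxon_signed_rank(x)$p, oracle_signed_rank_p(x))
  # all positive n = 15: minimal two-sided exact p = 2 / 2^15
  xp <- seq_len(15)
  expect_equal(wilcoxon_signed_rank(xp)$p, 2 / 2^15)
  # degenerate all-zero differences
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(res$p, 1)
  # random instances, continuous and tied
  set.seed(22)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    x <- if (i %% 2) stats::rnorm(n) else sample(-4:4, n, replace = TRUE)
    x <- x[x != 0]
    if (length(x) >= 2) {
      expect_equal(wilcoxon_signed_rank(x)$p, oracle_signed_rank_p(x),
                   info = paste("instance", i))
    }
  }
  # agreement with stats::wilcox.test in the tie-free exact regime
  set.seed(23)
  for (i in 1:20) {
    x <- stats::rnorm(sample(6:12, 1))
    expect_equal(wilcoxon_signed_rank(x)$p, stats::wilcox.test(x)$p.value)
  }
})

test_that("rank-sum p-values match allocation enumeration and wilcox.test", {
  # completely separated samples n = m = 5: exact p = 2 / choose(10, 5)
  a <- 1:5; b <- 11:15
  expect_equal(wilcoxon_rank_sum(a, b)$p, 2 / choose(10, 5))
  # identical constants: ties everywhere, p = 1
  expect_equal(wilcoxon_rank_sum(rep(1, 4), rep(1, 6))$p, 1)
  set.seed(24)
  for (i in 1:40) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    a <- if (i %% 2) stats::rnorm(n1) else sample(1:5, n1, replace = TRUE)
    b <- if (i %% 2) stats::rnorm(n2) else sample(1:5, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p, oracle_rank_sum_p(a, b),
                 info = paste("instance", i))
  }
  for (i in 1:15) {
    a <- stats::rnorm(6); b <- stats::rnorm(8)
    expect_equal(wilcoxon_rank_sum(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Friedman statistic matches closed-form rank arithmetic", {
  # identical columns: chi-squared 0, p 1
  m0 <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  r0 <- friedman_test(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # 12 subjects, strictly ordered effect: maximal chi-squared = 24
  m1 <- t(replicate(12, c(1, 2, 3)))
  m1 <- m1 + stats::rnorm(36, 0, 1e-3) * 0  # keep exact ordering
  r1 <- friedman_test(m1)
  expect_equal(r1$statistic, 24)
  expect_equal(r1$statistic, oracle_friedman_chisq(m1))
  # random tables match the oracle and stats::friedman.test (tie-free)
  set.seed(25)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(8 * 3), 8, 3)
    r <- friedman_test(m)
    expect_equal(r$statistic, oracle_friedman_chisq(m))
    expect_equal(r$statistic,
                 unname(stats::friedman.test(m)$statistic))
    expect_equal(r$p, stats::friedman.test(m)$p.value)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2)), "incomplete")
})

test_that("Friedman p is consistent with a within-block permutation oracle", {
  set.seed(26)
  m <- matrix(stats::rnorm(12 * 3), 12, 3)
  m[, 3] <- m[, 3] + 0.8
  obs <- friedman_test(m)$statistic
  perm <- vapply(1:6000, function(i) {
    mp <- t(apply(m, 1, sample))
    friedman_test(mp)$statistic
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-9)
  p_chisq <- friedman_test(m)$p
  # the chi-squared reference is asymptotic; at n = 12 blocks it tracks the
  # exact permutation distribution to within ~0.1 in the mid p-range
  expect_lt(abs(p_perm - p_chisq), 0.1)
  # and both references agree on a clear effect
  m2 <- m; m2[, 3] <- m2[, 3] + 2
  obs2 <- friedman_test(m2)$statistic
  perm2 <- vapply(1:6000, function(i)
    friedman_test(t(apply(m2, 1, sample)))$statistic, numeric(1))
  expect_lt(friedman_test(m2)$p, 0.05)
  expect_lt(mean(perm2 >= obs2 - 1e-9), 0.05)
})

test_that("BH adjustment matches the hand-stepped oracle", {
  # single p: q = p
  expect_equal(bh_fdr(0.03)$q, 0.03)
  # worked step-up example
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p)$q, oracle_bh_q(p))
  # equal p-values: all q equal that p
  expect_equal(bh_fdr(rep(0.2, 5))$q, rep(0.2, 5))
  # randomized vectors, adjustment is monotone and matches oracle
  set.seed(27)
  for (i in 1:30) {
    p <- stats::runif(sample(2:40, 1))
    q <- bh_fdr(p)$q
    expect_equal(q, oracle_bh_q(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
    expect_true(all(q >= p))
  }
  # BH rejections are a superset of Bonferroni rejections
  for (i in 1:20) {
    p <- stats::runif(16)^2
    bh_rej <- which(bh_fdr(p)$reject)
    bonf_rej <- which(p < 0.05 / length(p))
    expect_true(all(bonf_rej %in% bh_rej))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("Spearman correlation equals rank-then-Pearson with ties", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlation(x, x * 2 + 1)$statistic, 1)
  expect_equal(spearman_correlation(x, -x)$statistic, -1)
  set.seed(28)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    a <- sample(1:6, n, replace = TRUE)
    b <- a + sample(0:3, n, replace = TRUE)
    r <- spearman_correlation(a, b)
    expect_equal(r$statistic, stats::cor(rank(a), rank(b)))
    expect_equal(r$statistic,
                 unname(stats::cor.test(a, b, method = "spearman",
                                        exact = FALSE)$estimate))
  }
  cst <- spearman_correlation(rep(1, 8), stats::rnorm(8))
  expect_true(is.na(cst$statistic))
})

test_that("responder screening gates contributions to group statistics", {
  set.seed(29)
  lay <- build_default_layout()
  n_sub <- 8; n_trial <- 10
  mk_trials <- function(responding) {
    rows <- list()
    for (s in seq_len(n_sub)) for (ch in c(1, 3, 7)) {
      eff <- if (responding && ch %in% c(1, 3)) 0.8 else 0
      for (cond in c("PAPain", "PAnP", "Brush")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sprintf("S%02d", s), channel = ch, condition = cond,
          chromophore = "o2hb", trial = seq_len(n_trial),
          value = stats::rnorm(n_trial, eff, 0.3))
      }
    }
    dplyr::bind_rows(rows)
  }
  trials <- mk_trials(TRUE)
  screen <- screen_single_subject(trials)
  # responder channels pass, null channel mostly does not
  pass_rate <- tapply(screen$responder, screen$channel, mean)
  expect_gt(pass_rate[["1"]], 0.8)
  expect_lt(pass_rate[["7"]], 0.3)
  # Responders mode never includes a screened-out (subject, channel) cell
  blocks <- dplyr::summarise(
    dplyr::group_by(trials, subject, channel, condition, chromophore),
    value = median(value), .groups = "drop")
  filt <- painfnirs:::responder_filter(blocks, screen)
  bad <- dplyr::anti_join(
    filt, dplyr::filter(screen, responder),
    by = c("subject", "channel", "condition", "chromophore"))
  expect_equal(nrow(bad), 0)
  # empty screen -> warning and empty result
  null_screen <- screen
  null_screen$responder <- FALSE
  expect_warning(
    res <- condition_contrasts(blocks, lay, mode = "Responders",
                               screen = null_screen),
    "survived")
  expect_equal(nrow(res), 0)
})

test_that("patient deviation maps flag direction against the HC norm", {
  lay <- build_default_layout()
  longs <- lay$channels$channel[!lay$channels$is_short]
  conds <- c("PAPain", "PAnP", "Brush")
  grid <- expand.grid(channel = longs, condition = conds,
                      chromophore = c("o2hb", "hhb"),
                      stringsAsFactors = FALSE)
  hc_grand <- tibble::tibble(grid, median = 0.2, semed = 0.05,
                             n_subjects = 20, group = "HC")
  # patient identical to the norm: no deviations
  set.seed(30)
  mk_pt <- function(shift_s1) {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      ch <- grid$channel[i]
      shift <- if (shift_s1 && ch >= 7 && grid$chromophore[i] == "o2hb")
        0.4 else 0
      tibble::tibble(subject = "P01", channel = ch,
                     condition = grid$condition[i],
                     chromophore = grid$chromophore[i], trial = 1:15,
                     value = 0.2 + shift + stats::rnorm(15, 0, 0.02))
    })
    dplyr::bind_rows(rows)
  }
  dev0 <- patient_vs_norm(mk_pt(FALSE), hc_grand, lay)
  expect_equal(dim(dev0)[1], 16 * 3 * 2)  # full channel x condition x chrom map
  expect_true(all(dev0$deviation == "none"))
  dev1 <- patient_vs_norm(mk_pt(TRUE), hc_grand, lay)
  s1 <- dev1[dev1$channel >= 11 & dev1$chromophore == "o2hb", ]
  expect_true(all(s1$deviation == "stronger"))
  # unshifted SMA channels are mostly unflagged (BH admits a small
  # false-discovery share when the family holds many true effects)
  sma <- dev1[dev1$channel <= 6 & dev1$chromophore == "o2hb", ]
  expect_gt(mean(sma$deviation == "none"), 0.75)
  expect_false(any(sma$deviation == "weaker"))
})
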