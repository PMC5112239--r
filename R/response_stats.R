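#' @importFrom stats median sd pnorm pchisq p.adjust
NULL

# ---- Block averages -------------------------------------------------------

# Sample offsets (relative to the onset sample) of the middle 2.5 s of a
# stimulus window: rel_time in [window_lo, window_hi].
middle_window_index <- function(epoch_set, window_lo = 1.25, window_hi = 3.75) {
  idx <- which(epoch_set$rel_time >= window_lo & epoch_set$rel_time <= window_hi)
  if (!length(idx)) stop("middle stimulus window contains no samples")
  idx
}

#' Block averages: one scalar per channel, condition and chromophore
#'
#' Collapses a subject's normalized trials to a single value per channel,
#' condition and chromophore, using only samples from the middle 2.5 s of the
#' 5 s stimulus (`[onset + 1.25 s, onset + 3.75 s]`). The default
#' (`"pooled_median"`) takes one median over all middle-window samples of all
#' trials; `"median_of_trial_medians"` first collapses each trial.
#'
#' @param epoch_set A normalized `epoch_set`.
#' @param mode Pooling mode.
#' @param chromophores Chromophores to summarize.
#' @return Tibble: channel, condition, chromophore, value (uM), n_trials, mode.
#' @export
block_average <- function(epoch_set,
                          mode = c("pooled_median", "median_of_trial_medians"),
                          chromophores = c("o2hb", "hhb")) {
  mode <- match.arg(mode)
  if (!epoch_set$normalized) warning("epoch set is not normalized")
  win <- middle_window_index(epoch_set)
  out <- list()
  for (chrom in chromophores) {
    for (cond in epoch_set$conditions) {
      arr <- epoch_set$data[[chrom]][[cond]][, win, , drop = FALSE]
      n_ch <- dim(arr)[1]
      nt <- dim(arr)[3]
      value <- if (mode == "pooled_median") {
        apply(arr, 1, stats::median)
      } else {
        apply(apply(arr, c(1, 3), stats::median), 1, stats::median)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        channel = seq_len(n_ch), condition = cond, chromophore = chrom,
        value = value, n_trials = nt, mode = mode)
    }
  }
  dplyr::bind_rows(out)
}

#' Per-trial middle-window medians
#'
#' Like [block_average()] but without the final collapse: one value per trial
#' (the median of that trial's middle 2.5 s window), the within-subject sample
#' used for single-subject significance screening and patient-versus-norm
#' comparisons.
#'
#' @param epoch_set A normalized `epoch_set`.
#' @param chromophores Chromophores to summarize.
#' @return Tibble: channel, condition, chromophore, trial, value.
#' @export
per_trial_values <- function(epoch_set, chromophores = c("o2hb", "hhb")) {
  win <- middle_window_index(epoch_set)
  out <- list()
  for (chrom in chromophores) {
    for (cond in epoch_set$conditions) {
      arr <- epoch_set$data[[chrom]][[cond]][, win, , drop = FALSE]
      med <- apply(arr, c(1, 3), stats::median)  # channel x trial
      out[[length(out) + 1L]] <- tibble::tibble(
        channel = rep(seq_len(nrow(med)), ncol(med)),
        condition = cond, chromophore = chrom,
        trial = rep(seq_len(ncol(med)), each = nrow(med)),
        value = as.vector(med))
    }
  }
  dplyr::bind_rows(out)
}

#' Grand averages with standard error of the median
#'
#' Group-level summary: the median across subjects of the per-subject block
#' averages, with the standard error of the median (SEMed) from the asymptotic
#' normal-theory formula `1.2533 * SD / sqrt(n)`; a bootstrap alternative is
#' available for validation.
#'
#' @param block_tbl Tibble of per-subject block averages with columns
#'   `subject`, `channel`, `condition`, `chromophore`, `value`.
#' @param group Optional group label stored in the output.
#' @param semed_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `semed_method = "bootstrap"`.
#' @return Tibble: channel, condition, chromophore, median, semed, n_subjects,
#'   group.
#' @export
grand_average <- function(block_tbl, group = NA_character_,
                          semed_method = c("asymptotic", "bootstrap"),
                          n_boot = 2000) {
  semed_method <- match.arg(semed_method)
  dplyr::summarise(
    dplyr::group_by(block_tbl, .data$channel, .data$condition, .data$chromophore),
    median = stats::median(.data$value),
    semed = {
      v <- .data$value
      if (length(v) < 2) stop("SEMed requires at least 2 subjects")
      if (semed_method == "asymptotic") {
        1.2533 * stats::sd(v) / sqrt(length(v))
      } else {
        stats::sd(vapply(seq_len(n_boot), function(i)
          stats::median(sample(v, replace = TRUE)), numeric(1)))
      }
    },
    n_subjects = dplyr::n(),
    .groups = "drop"
  ) |>
    dplyr::mutate(group = group)
}

# ---- Nonparametric tests --------------------------------------------------

# Exact two-sided tail probability for the signed-rank statistic by full
# enumeration of sign assignments over the observed (possibly tied) ranks.
signed_rank_exact_p <- function(ranks, w_obs) {
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  tol <- 1e-9
  p_le <- mean(sums <= w_obs + tol)
  p_ge <- mean(sums >= w_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test (exact for small n)
#'
#' One-sample (or paired-difference) signed-rank test against `mu`. Zero
#' differences are discarded (classic treatment; `zero_method = "pratt"`
#' keeps them in the ranking). For `n <= exact_max` remaining differences the
#' two-sided p-value is exact over all `2^n` sign assignments of the observed
#' ranks (so ties are handled exactly); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x Numeric vector (differences if `y` given).
#' @param y Optional paired second sample.
#' @param mu Null location.
#' @param exact_max Largest n for which the exact distribution is enumerated.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @return List with `test`, `statistic` (W, sum of positive ranks), `z`
#'   (normal path only), `p`, `n` (differences used), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, exact_max = 15,
                                 zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x - mu else x - y
  d <- d[is.finite(d)]
  if (zero_method == "wilcox") {
    nz <- d != 0
    if (!any(nz)) {
      warning("all differences are zero; p = 1")
      return(list(test = "wilcoxon_signed_rank", statistic = 0, z = NA_real_,
                  p = 1, n = 0L, method = "degenerate"))
    }
    d <- d[nz]
    r <- rank(abs(d))
  } else {
    # Pratt: zeros participate in the ranking, then drop out of the statistic
    r_all <- rank(abs(d))
    keep <- d != 0
    if (!any(keep)) {
      warning("all differences are zero; p = 1")
      return(list(test = "wilcoxon_signed_rank", statistic = 0, z = NA_real_,
                  p = 1, n = 0L, method = "degenerate"))
    }
    d <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # Tie-free ranks: the closed-form signed-rank distribution equals the
    # enumeration over sign assignments; with ties, enumerate the observed
    # (mid-)ranks directly.
    p <- if (!anyDuplicated(r)) {
      min(1, 2 * min(stats::psignrank(w, n),
                     stats::psignrank(w - 1, n, lower.tail = FALSE)))
    } else {
      signed_rank_exact_p(r, w)
    }
    return(list(test = "wilcoxon_signed_rank", statistic = w, z = NA_real_,
                p = p, n = n, method = "exact"))
  }
  mu_w <- sum(r) / 2
  sigma2 <- sum(r^2) / 4  # tie-robust: variance from the observed ranks
  z_num <- w - mu_w
  z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(test = "wilcoxon_signed_rank", statistic = w, z = z, p = p, n = n,
       method = "normal")
}

# Exact two-sided tail probability for the rank-sum statistic by enumeration
# of all allocations of the smaller sample's ranks.
rank_sum_exact_p <- function(ranks, n_small, w_obs) {
  combos <- utils::combn(length(ranks), n_small)
  sums <- colSums(matrix(ranks[combos], nrow = n_small))
  tol <- 1e-9
  p_le <- mean(sums <= w_obs + tol)
  p_ge <- mean(sums >= w_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two independent samples
#'
#' Two-sided by default. When the smaller sample has at most `exact_max`
#' observations the null distribution of the rank sum is enumerated over all
#' allocations of the pooled (possibly tied) ranks; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' One-sided alternatives use the normal path.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest min(n) for which allocations are enumerated.
#' @param alternative `"two.sided"`, `"less"` (a shifted below b) or
#'   `"greater"`.
#' @return List with `test`, `statistic` (rank sum of `a`), `z`, `p`, `n`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 10,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  if (alternative == "two.sided" && min(n1, n2) <= exact_max) {
    if (!anyDuplicated(r)) {
      u <- w - n1 * (n1 + 1) / 2
      p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                          stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)))
    } else if (n1 <= n2) {
      p <- rank_sum_exact_p(r, n1, w)
    } else {
      p <- rank_sum_exact_p(r, n2, sum(r[n1 + seq_len(n2)]))
    }
    return(list(test = "wilcoxon_rank_sum", statistic = w, z = NA_real_,
                p = p, n = c(n1, n2), method = "exact"))
  }
  N <- n1 + n2
  mu_w <- n1 * (N + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z_num <- w - mu_w
  z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(-abs(z))),
    less = stats::pnorm(z),
    greater = stats::pnorm(-z))
  list(test = "wilcoxon_rank_sum", statistic = w, z = z, p = p,
       n = c(n1, n2), method = "normal")
}

#' Friedman test for a complete subjects-by-conditions block design
#'
#' Rank-based test of a condition main effect across matched subjects, with
#' tie correction: values are ranked within each subject and
#' `chi^2 = (k - 1) * (sum_j R_j^2 - n^2 k (k+1)^2 / 4) /
#'  (sum_ij r_ij^2 - n k (k+1)^2 / 4)`,
#' referred to a chi-squared distribution with `k - 1` degrees of freedom.
#' Without ties this reduces to the classic
#' `12 / (n k (k+1)) * sum R_j^2 - 3 n (k+1)`.
#'
#' @param values Numeric matrix, rows = subjects (blocks), columns =
#'   conditions; must be complete.
#' @return List with `test`, `statistic` (chi-squared), `df`, `p`, `n`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("incomplete block: missing values")
  n <- nrow(values); k <- ncol(values)
  if (n < 2) stop("Friedman test needs at least 2 subjects")
  if (k < 2) stop("Friedman test needs at least 2 conditions")
  rk <- t(apply(values, 1, rank))
  Rj <- colSums(rk)
  denom <- sum(rk^2) - n * k * (k + 1)^2 / 4
  if (denom <= .Machine$double.eps) {
    return(list(test = "friedman", statistic = 0, df = k - 1, p = 1, n = n))
  }
  stat <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4) / denom
  list(test = "friedman", statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE), n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values for one family of p-values, with rejection at
#' `q < q_threshold` (default 0.05).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed: passed through).
#' @param q_threshold Rejection threshold on q.
#' @return List with `q` (adjusted values, same order as `p`) and `reject`
#'   (logical, NA where p is NA).
#' @export
bh_fdr <- function(p, q_threshold = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(q = q, reject = q < q_threshold)
}

#' Spearman rank correlation with tie-corrected ranks
#'
#' `rho` is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 5 recommended).
#' @return List with `test`, `statistic` (rho), `p`, `n`; `rho` and `p` are NA
#'   when either vector is constant.
#' @export
spearman_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(test = "spearman", statistic = NA_real_, p = NA_real_, n = n,
                note = "undefined for constant input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(test = "spearman", statistic = rho, p = p, n = n)
}

# ---- Group-level battery --------------------------------------------------

#' Single-subject response screening
#'
#' For each subject, channel, condition and chromophore, tests the per-trial
#' middle-window medians against zero with the exact signed-rank test. A
#' (subject, channel, condition, chromophore) cell is a "responder" when the
#' uncorrected p-value is below `alpha` — the entry criterion of the
#' responder-only analysis mode (group-level results are FDR-corrected
#' separately).
#'
#' @param trial_tbl Tibble of per-trial values with columns `subject`,
#'   `channel`, `condition`, `chromophore`, `trial`, `value`.
#' @param alpha Screening threshold on the uncorrected p-value.
#' @return Tibble: subject, channel, condition, chromophore, p, responder.
#' @export
screen_single_subject <- function(trial_tbl, alpha = 0.05) {
  dplyr::summarise(
    dplyr::group_by(trial_tbl, .data$subject, .data$channel, .data$condition,
                    .data$chromophore),
    p = wilcoxon_signed_rank(.data$value)$p,
    .groups = "drop"
  ) |>
    dplyr::mutate(responder = .data$p < alpha)
}

# Long channels of a layout (the statistical family within each correction).
long_channels <- function(layout) {
  layout$channels$channel[!layout$channels$excluded_from_stats]
}

# One result row as a plain list; rows are bound into a tibble once per call
# site (cheaper than building hundreds of one-row tibbles).
test_row <- function(test, group, condition, chromophore, channel, res, mode,
                     family) {
  list(
    test = test, group = group, condition = condition,
    chromophore = chromophore, channel = as.integer(channel),
    statistic = if (is.null(res)) NA_real_ else as.numeric(res$statistic),
    z = if (is.null(res) || is.null(res$z)) NA_real_ else as.numeric(res$z),
    p = if (is.null(res)) NA_real_ else res$p,
    n = if (is.null(res)) NA_integer_ else as.integer(res$n[1]),
    family = family, mode = mode)
}

empty_test_tbl <- function() {
  tibble::tibble(test = character(), group = character(),
                 condition = character(), chromophore = character(),
                 channel = integer(), statistic = numeric(), z = numeric(),
                 p = numeric(), n = integer(), family = character(),
                 mode = character(), q = numeric(), significant = logical())
}

# Apply BH within each family id of a results tibble.
fdr_by_family <- function(res_tbl, q_threshold = 0.05) {
  if (!nrow(res_tbl)) {
    return(dplyr::mutate(res_tbl, q = numeric(0), significant = logical(0)))
  }
  dplyr::mutate(
    dplyr::group_by(res_tbl, .data$family),
    q = bh_fdr(.data$p, q_threshold)$q,
    significant = ifelse(is.na(.data$q), NA, .data$q < q_threshold)) |>
    dplyr::ungroup()
}

# Filter a per-subject block table down to screened responders (per channel x
# condition x chromophore cell) for the responder-only mode.
responder_filter <- function(block_tbl, screen) {
  dplyr::inner_join(
    block_tbl,
    dplyr::filter(screen, .data$responder)[, c("subject", "channel",
                                               "condition", "chromophore")],
    by = c("subject", "channel", "condition", "chromophore"))
}

#' Within-group statistical battery: main effect, post-hoc and baseline tests
#'
#' Per channel and chromophore (long channels only): a Friedman test of the
#' condition main effect across subjects; paired signed-rank post-hoc
#' contrasts between the three conditions; and per-condition signed-rank
#' tests of the block averages against baseline (zero, since trials are
#' normalized to a zero pre-stimulus median). Every test family (one test
#' type x condition/contrast x chromophore) is Benjamini-Hochberg corrected
#' across its 16 channels.
#'
#' In `mode = "Responders"`, only subjects whose single-subject screening was
#' significant for a given (channel, condition, chromophore) cell contribute;
#' cells with fewer than `min_n` surviving subjects are reported untested
#' (`p = NA`). Paired tests (Friedman, contrasts) require survival in all
#' conditions involved.
#'
#' @param block_tbl Per-subject block averages (`subject`, `channel`,
#'   `condition`, `chromophore`, `value`) for one group.
#' @param layout Probe layout (defines the channel family).
#' @param group Group label for the output.
#' @param mode `"All"` or `"Responders"`.
#' @param screen Screening table from [screen_single_subject()] (required for
#'   `"Responders"`).
#' @param q_threshold FDR threshold.
#' @param min_n Minimum subjects for a group test.
#' @return Tidy tibble of test results with q-values and significance flags.
#' @export
condition_contrasts <- function(block_tbl, layout, group = NA_character_,
                                mode = c("All", "Responders"), screen = NULL,
                                q_threshold = 0.05, min_n = 5,
                                tests = c("friedman", "posthoc", "vs_baseline")) {
  mode <- match.arg(mode)
  tests <- match.arg(tests, several.ok = TRUE)
  if (mode == "Responders") {
    if (is.null(screen)) stop("Responders mode requires a screening table")
    block_tbl <- responder_filter(block_tbl, screen)
    if (!nrow(block_tbl)) {
      warning("Responders mode: no (subject, channel) cell survived screening")
      return(empty_test_tbl())
    }
  }
  chans <- long_channels(layout)
  conds <- sort(unique(block_tbl$condition))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- list()
  for (chrom in unique(block_tbl$chromophore)) {
    sub <- dplyr::filter(block_tbl, .data$chromophore == chrom)
    wide <- tidyr::pivot_wider(sub[, c("subject", "channel", "condition", "value")],
                               names_from = "condition", values_from = "value")
    for (cond in setdiff(conds, names(wide))) wide[[cond]] <- NA_real_
    for (ch in chans) {
      chw <- dplyr::filter(wide, .data$channel == ch)
      if ("friedman" %in% tests) {
        # Friedman main effect on complete blocks
        m <- as.matrix(chw[, conds])
        m <- m[stats::complete.cases(m), , drop = FALSE]
        fam <- paste("friedman", chrom, group, sep = ".")
        res <- if (nrow(m) >= max(2, min_n)) friedman_test(m) else NULL
        rows[[length(rows) + 1L]] <- test_row("friedman", group, "main_effect",
                                              chrom, ch, res, mode, fam)
      }
      if ("posthoc" %in% tests) {
        # Post-hoc paired contrasts
        for (pr in pairs) {
          keep <- stats::complete.cases(chw[, pr])
          x <- chw[[pr[1]]][keep]; y <- chw[[pr[2]]][keep]
          fam <- paste("posthoc", pr[1], pr[2], chrom, group, sep = ".")
          res <- if (length(x) >= min_n) wilcoxon_signed_rank(x, y) else NULL
          rows[[length(rows) + 1L]] <- test_row("posthoc_signed_rank", group,
                                                paste(pr, collapse = "_vs_"),
                                                chrom, ch, res, mode, fam)
        }
      }
      if ("vs_baseline" %in% tests) {
        # Per-condition tests against baseline (0)
        for (cond in conds) {
          v <- chw[[cond]][is.finite(chw[[cond]])]
          fam <- paste("vs_baseline", cond, chrom, group, sep = ".")
          res <- if (length(v) >= min_n) wilcoxon_signed_rank(v) else NULL
          rows[[length(rows) + 1L]] <- test_row("vs_baseline_signed_rank", group,
                                                cond, chrom, ch, res, mode, fam)
        }
      }
    }
  }
  fdr_by_family(dplyr::bind_rows(rows), q_threshold)
}

#' Group analysis in one or both analysis modes
#'
#' Runs [condition_contrasts()] for a group in `"All"` mode (every long
#' channel and subject enters) and/or `"Responders"` mode (only cells passing
#' the single-subject screen enter).
#'
#' @param block_tbl Per-subject block averages for one group.
#' @param trial_tbl Per-trial values for the same subjects (used to compute
#'   the screening; required for Responders mode).
#' @param layout Probe layout.
#' @param group Group label.
#' @param modes Character vector of analysis modes to run.
#' @param screen_alpha Single-subject screening threshold.
#' @param q_threshold FDR threshold.
#' @param min_n Minimum subjects per group test.
#' @return Combined tidy results tibble (one row per test x channel x mode).
#' @export
run_analysis <- function(block_tbl, trial_tbl = NULL, layout,
                         group = NA_character_,
                         modes = c("All", "Responders"),
                         screen_alpha = 0.05, q_threshold = 0.05, min_n = 5,
                         tests = c("friedman", "posthoc", "vs_baseline")) {
  out <- list()
  screen <- NULL
  if ("Responders" %in% modes) {
    if (is.null(trial_tbl)) stop("Responders mode needs per-trial values")
    screen <- screen_single_subject(trial_tbl, alpha = screen_alpha)
  }
  for (mode in modes) {
    out[[mode]] <- condition_contrasts(block_tbl, layout, group = group,
                                       mode = mode, screen = screen,
                                       q_threshold = q_threshold, min_n = min_n,
                                       tests = tests)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "screen") <- screen
  res
}

#' Between-group comparison per channel and condition
#'
#' Unpaired rank-sum tests of HC versus CLBP block averages per long channel,
#' condition and chromophore, BH-corrected across channels within each
#' (condition, chromophore) family.
#'
#' @param hc_blocks,clbp_blocks Per-subject block tables for the two groups.
#' @param layout Probe layout.
#' @param q_threshold FDR threshold.
#' @return Tidy results tibble.
#' @export
between_group_compare <- function(hc_blocks, clbp_blocks, layout,
                                  q_threshold = 0.05) {
  chans <- long_channels(layout)
  rows <- list()
  for (chrom in unique(hc_blocks$chromophore)) {
    for (cond in unique(hc_blocks$condition)) {
      fam <- paste("between_group", cond, chrom, sep = ".")
      for (ch in chans) {
        a <- dplyr::filter(hc_blocks, .data$channel == ch,
                           .data$condition == cond,
                           .data$chromophore == chrom)$value
        b <- dplyr::filter(clbp_blocks, .data$channel == ch,
                           .data$condition == cond,
                           .data$chromophore == chrom)$value
        res <- if (length(a) && length(b)) wilcoxon_rank_sum(a, b) else NULL
        rows[[length(rows) + 1L]] <- test_row("between_group_rank_sum",
                                              "HC_vs_CLBP", cond, chrom, ch,
                                              res, "All", fam)
      }
    }
  }
  fdr_by_family(dplyr::bind_rows(rows), q_threshold)
}

#' Single-patient deviation map against the healthy-control norm
#'
#' Compares each patient's 15 per-trial values to the healthy-control grand
#' average (a scalar per channel, condition and chromophore) with signed-rank
#' tests, BH-corrected across the long channels within each patient x
#' condition x chromophore family. The deviation direction is the sign of
#' (patient median - HC grand median): `"stronger"`, `"weaker"` or `"none"`
#' when not significant.
#'
#' @param patient_trials Per-trial table for the patients (includes `subject`).
#' @param hc_grand Grand-average table from [grand_average()] on the HC group.
#' @param layout Probe layout.
#' @param q_threshold FDR threshold.
#' @return Tidy tibble: subject, channel, condition, chromophore, statistic,
#'   p, q, significant, direction, deviation.
#' @export
patient_vs_norm <- function(patient_trials, hc_grand, layout,
                            q_threshold = 0.05) {
  chans <- long_channels(layout)
  norm <- hc_grand[, c("channel", "condition", "chromophore", "median")]
  names(norm)[names(norm) == "median"] <- "hc_median"
  tt <- dplyr::inner_join(
    dplyr::filter(patient_trials, .data$channel %in% chans), norm,
    by = c("channel", "condition", "chromophore"))
  res <- dplyr::summarise(
    dplyr::group_by(tt, .data$subject, .data$channel, .data$condition,
                    .data$chromophore),
    statistic = wilcoxon_signed_rank(.data$value, mu = .data$hc_median[1])$statistic,
    p = wilcoxon_signed_rank(.data$value, mu = .data$hc_median[1])$p,
    direction = sign(stats::median(.data$value) - .data$hc_median[1]),
    .groups = "drop")
  res$family <- paste(res$subject, res$condition, res$chromophore, sep = ".")
  res <- fdr_by_family(res, q_threshold)
  res$deviation <- ifelse(!res$significant, "none",
                          ifelse(res$direction > 0, "stronger", "weaker"))
  res
}

#' Spearman correlation of pressure-pain thresholds with channel responses
#'
#' Correlates each subject's PPT (in N) with their block-average response
#' magnitude, per long channel (and condition), BH-corrected across channels
#' within each condition family. By default only the oxyhemoglobin responses
#' are used.
#'
#' @param subject_tbl Tibble with `subject` and `ppt` columns (all subjects,
#'   both groups).
#' @param block_tbl Per-subject block averages for the same subjects.
#' @param layout Probe layout.
#' @param chromophore Chromophore to correlate.
#' @param q_threshold FDR threshold.
#' @return Tidy tibble with rho per channel x condition.
#' @export
spearman_ppt_correlation <- function(subject_tbl, block_tbl, layout,
                                     chromophore = "o2hb",
                                     q_threshold = 0.05) {
  chans <- long_channels(layout)
  bt <- dplyr::inner_join(
    dplyr::filter(block_tbl, .data$chromophore == chromophore,
                  .data$channel %in% chans),
    subject_tbl[, c("subject", "ppt")], by = "subject")
  res <- dplyr::summarise(
    dplyr::group_by(bt, .data$channel, .data$condition),
    statistic = spearman_correlation(.data$ppt, .data$value)$statistic,
    p = spearman_correlation(.data$ppt, .data$value)$p,
    n = length(.data$value),
    .groups = "drop")
  res$test <- "spearman_ppt"
  res$family <- paste("spearman", res$condition, sep = ".")
  fdr_by_family(res, q_threshold)
}
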