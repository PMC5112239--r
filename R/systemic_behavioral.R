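#' Per-condition heart-rate trial summaries
#'
#' Summarizes a 1 Hz heart-rate series around each trial of the protocol.
#' For every trial, three half-open windows are evaluated: the stimulus
#' `[onset, onset + stimulus_s)`, the pre-ISI `[onset - isi_s, onset)` and the
#' post-ISI `[onset + stimulus_s, onset + stimulus_s + isi_s)`. Samples are
#' assigned by timestamp, so the boundary sample between stimulus and post-ISI
#' is never counted twice. Per condition, the per-trial window means and
#' maxima are averaged across that condition's trials (the per-trial maxima
#' are averaged by default; `max_mode = "max_of_max"` takes their maximum
#' instead), and `delta_hr_max = hr_max_stim - hr_max_post`.
#'
#' @param hr Tibble/data.frame with columns `time_s` and `hr_bpm` (1 Hz
#'   update interval; all values > 0).
#' @param protocol A `stimulus_protocol` with a generated sequence.
#' @param max_mode How to combine per-trial maxima across trials.
#' @return Tibble: condition, hr_mean_stim, hr_max_stim, hr_mean_pre,
#'   hr_max_pre, hr_mean_post, hr_max_post, delta_hr_max, n_trials.
#' @export
hr_trial_summaries <- function(hr, protocol,
                               max_mode = c("mean_of_trial_max", "max_of_max")) {
  max_mode <- match.arg(max_mode)
  if (is.null(protocol$sequence)) stop("protocol has no stimulus sequence")
  if (any(hr$hr_bpm <= 0)) stop("heart-rate samples must be positive")
  seqs <- protocol$sequence
  win_stat <- function(lo, hi, f) {
    vapply(seq_along(lo), function(i) {
      idx <- hr$time_s >= lo[i] & hr$time_s < hi[i]
      if (!any(idx)) stop(sprintf("empty HR window [%g, %g)", lo[i], hi[i]))
      f(hr$hr_bpm[idx])
    }, numeric(1))
  }
  on <- seqs$onset_s
  per_trial <- tibble::tibble(
    condition = seqs$condition,
    mean_stim = win_stat(on, on + protocol$stimulus_s, mean),
    max_stim = win_stat(on, on + protocol$stimulus_s, max),
    mean_pre = win_stat(on - protocol$isi_s, on, mean),
    max_pre = win_stat(on - protocol$isi_s, on, max),
    mean_post = win_stat(on + protocol$stimulus_s,
                         on + protocol$stimulus_s + protocol$isi_s, mean),
    max_post = win_stat(on + protocol$stimulus_s,
                        on + protocol$stimulus_s + protocol$isi_s, max))
  agg_max <- if (max_mode == "mean_of_trial_max") mean else max
  out <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$condition),
    hr_mean_stim = mean(.data$mean_stim),
    hr_max_stim = agg_max(.data$max_stim),
    hr_mean_pre = mean(.data$mean_pre),
    hr_max_pre = agg_max(.data$max_pre),
    hr_mean_post = mean(.data$mean_post),
    hr_max_post = agg_max(.data$max_post),
    n_trials = dplyr::n(),
    .groups = "drop")
  out$delta_hr_max <- out$hr_max_stim - out$hr_max_post
  out
}

#' Group-level heart-rate statistics
#'
#' Across subjects: (1) per condition, a paired signed-rank test of the
#' maximal heart rate during the stimulus against the maximal heart rate of
#' the following post-ISI, BH-corrected over the three conditions; (2) a
#' Friedman test of `delta_hr_max` across the three conditions.
#'
#' @param summaries Tibble binding per-subject [hr_trial_summaries()] outputs,
#'   with an added `subject` column.
#' @param q_threshold FDR threshold.
#' @return List with `stim_vs_post` (tidy tibble with q-values) and
#'   `friedman_delta` (single-row tibble).
#' @export
hr_statistics <- function(summaries, q_threshold = 0.05) {
  conds <- sort(unique(summaries$condition))
  rows <- lapply(conds, function(cond) {
    s <- summaries[summaries$condition == cond, ]
    res <- wilcoxon_signed_rank(s$hr_max_stim, s$hr_max_post)
    tibble::tibble(test = "hr_stim_vs_post", condition = cond,
                   statistic = res$statistic, p = res$p, n = res$n)
  })
  svp <- dplyr::bind_rows(rows)
  adj <- bh_fdr(svp$p, q_threshold)
  svp$q <- adj$q
  svp$significant <- adj$reject
  wide <- tidyr::pivot_wider(summaries[, c("subject", "condition", "delta_hr_max")],
                             names_from = "condition",
                             values_from = "delta_hr_max")
  fr <- friedman_test(as.matrix(wide[, conds]))
  list(stim_vs_post = svp,
       friedman_delta = tibble::tibble(test = "friedman_delta_hr_max",
                                       statistic = fr$statistic, df = fr$df,
                                       p = fr$p, n = fr$n))
}

#' Behavioral summary in the layout of the patients' questionnaire table
#'
#' Column-wise arithmetic means and sample standard deviations (n - 1
#' denominator) of a behavioral table, plus a display-rounded version
#' matching the printed precision: pressure-pain thresholds (PPT, Newtons) to
#' integers, questionnaire scores to one decimal. Rounding is half-up (44.5 N
#' displays as 45 N).
#'
#' @param records Data frame of subject records; all numeric columns are
#'   summarized (default columns: `pain_detect_current`, `pain_detect_ave4w`,
#'   `pain_detect_total`, `rmd`, `ppt`).
#' @return List with `raw` (tibble of exact means/SDs, one row per statistic)
#'   and `display` (same, rounded for presentation).
#' @export
behavioral_summary <- function(records) {
  num <- records[vapply(records, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("subject", "id"))]
  if (nrow(num) < 2) stop("need at least 2 records")
  means <- vapply(num, mean, numeric(1))
  sds <- vapply(num, stats::sd, numeric(1))
  raw <- tibble::tibble(statistic = c("mean", "sd"))
  disp <- tibble::tibble(statistic = c("MEAN", "SD"))
  for (col in names(num)) {
    raw[[col]] <- c(means[[col]], sds[[col]])
    digits <- if (grepl("ppt", col, ignore.case = TRUE)) 0 else 1
    disp[[col]] <- round_half_up(c(means[[col]], sds[[col]]), digits)
  }
  list(raw = raw, display = disp)
}

# Half-up decimal rounding (display convention of the behavioral tables;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pressure-pain threshold group comparison
#'
#' One-sided rank-sum test of the hypothesis that patients have lower
#' pressure-pain thresholds than healthy controls, with group descriptives.
#'
#' @param clbp_ppt,hc_ppt Numeric PPT vectors (Newtons) for the two groups.
#' @return List with `test` (rank-sum result, alternative CLBP < HC) and
#'   `descriptives` (tibble of group means/SDs/n).
#' @export
ppt_group_compare <- function(clbp_ppt, hc_ppt) {
  res <- wilcoxon_rank_sum(clbp_ppt, hc_ppt, alternative = "less")
  desc <- tibble::tibble(
    group = c("CLBP", "HC"),
    mean = c(mean(clbp_ppt), mean(hc_ppt)),
    sd = c(stats::sd(clbp_ppt), stats::sd(hc_ppt)),
    n = c(length(clbp_ppt), length(hc_ppt)))
  list(test = res, descriptives = desc)
}

#' Average repeated pressure-pain threshold readings
#'
#' The protocol determines the PPT by slowly increasing pressure until it
#' first becomes clearly painful, repeated 3-4 times; the final PPT is the
#' arithmetic mean of the readings.
#'
#' @param readings Numeric vector of 3-4 force readings (Newtons).
#' @return The mean reading.
#' @export
ppt_protocol_average <- function(readings) {
  if (length(readings) < 3) warning("fewer than 3 PPT readings")
  if (length(readings) > 4) warning("more than 4 PPT readings")
  mean(readings)
}

#' Load the packaged patients' behavioral table
#'
#' The package ships the behavioral table of the 12 chronic lower back pain
#' patients (questionnaire scores and individual pressure-pain thresholds) as
#' a plain-text fixture; [behavioral_summary()] on it reproduces the printed
#' MEAN and SD rows.
#'
#' @return Tibble with columns `subject`, `pain_detect_current`,
#'   `pain_detect_ave4w`, `pain_detect_total`, `rmd`, `ppt`.
#' @export
load_behavioral_table <- function() {
  path <- system.file("extdata", "clbp_behavioral.csv", package = "painfnirs",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
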