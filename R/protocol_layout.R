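#' Default probe layout for the 18-channel sensorimotor montage
#'
#' Builds the probe geometry used throughout the pipeline: 18 multi-distance
#' channels over the supplementary motor area (SMA, channels 1-6) and the
#' primary somatosensory cortex (S1, channels 7-18), recorded at two
#' wavelengths. Channels 2 and 10 are short-separation channels (~11 mm
#' source-detector distance) that sample only superficial (scalp) tissue and
#' drive the short-separation regression; they are excluded from all
#' channel-wise statistics. Long channels have separations between 25 and
#' 45 mm.
#'
#' Hemisphere labels are a convention (the montage is symmetric about the
#' midline); they can be overridden after construction and do not affect any
#' computation.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param wavelengths Numeric vector of the two wavelengths in nm.
#' @param long_separation_mm Source-detector separation assigned to long
#'   channels, in mm (single value or one per long channel), must lie in
#'   \[25, 45\].
#' @param short_separation_mm Separation of the two short channels in mm.
#'
#' @return An object of class `probe_layout`: a list with elements
#'   `channels` (tibble: channel, source, detector, separation_mm, roi,
#'   hemisphere, is_short, excluded_from_stats), `ssr_map` (named list mapping
#'   each short channel to the long channels it corrects), `wavelengths` and
#'   `sampling_rate`.
#' @export
build_default_layout <- function(sampling_rate = 7.81,
                                 wavelengths = c(760, 850),
                                 long_separation_mm = 30,
                                 short_separation_mm = 11) {
  short_ids <- c(2L, 10L)
  ids <- 1:18
  is_short <- ids %in% short_ids
  n_long <- sum(!is_short)
  if (length(long_separation_mm) == 1L) {
    long_separation_mm <- rep(long_separation_mm, n_long)
  }
  stopifnot(length(long_separation_mm) == n_long)
  if (any(long_separation_mm < 25 | long_separation_mm > 45)) {
    stop("long-channel separations must lie in [25, 45] mm")
  }
  separation <- numeric(18)
  separation[is_short] <- short_separation_mm
  separation[!is_short] <- long_separation_mm

  roi <- ifelse(ids <= 6, "SMA", "S1")
  hemisphere <- rep("left", 18)
  hemisphere[ids %in% c(4, 5, 6, 14:18)] <- "right"
  hemisphere[short_ids] <- "midline"

  # Sources/detectors: 8 of each; pairing is schematic (geometry beyond ROI
  # membership and separation is not used by the pipeline).
  source_id <- ((ids - 1L) %/% 3L) + 1L
  detector_id <- ((ids - 1L) %% 8L) + 1L

  channels <- tibble::tibble(
    channel = ids,
    source = source_id,
    detector = detector_id,
    separation_mm = separation,
    roi = roi,
    hemisphere = hemisphere,
    is_short = is_short,
    excluded_from_stats = is_short
  )
  layout <- structure(
    list(
      channels = channels,
      ssr_map = list(`2` = c(1L, 3L, 4L, 5L, 6L),
                     `10` = c(7L, 8L, 9L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L)),
      wavelengths = wavelengths,
      sampling_rate = sampling_rate
    ),
    class = "probe_layout"
  )
  validate_layout(layout)
  layout
}

#' Validate a probe layout
#'
#' Checks the structural invariants of a [build_default_layout()] object:
#' unique channel ids, exactly two short channels, short separations near
#' 11 mm, long separations in \[25, 45\] mm, and an SSR map that partitions the
#' long channels (every long channel corrected by exactly one short channel).
#'
#' @param layout A `probe_layout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  ch <- layout$channels
  if (anyDuplicated(ch$channel)) stop("channel ids must be unique")
  shorts <- ch$channel[ch$is_short]
  if (length(shorts) != 2L) stop("layout must have exactly 2 short channels")
  if (any(abs(ch$separation_mm[ch$is_short] - 11) > 3)) {
    stop("short-channel separation must be ~11 mm")
  }
  longs <- ch$channel[!ch$is_short]
  sep_long <- ch$separation_mm[!ch$is_short]
  if (any(sep_long < 25 | sep_long > 45)) {
    stop("long-channel separations must lie in [25, 45] mm")
  }
  mapped <- unlist(layout$ssr_map, use.names = FALSE)
  if (anyDuplicated(mapped)) stop("ssr_map: a long channel is mapped twice")
  if (!setequal(mapped, longs)) stop("ssr_map must cover every long channel exactly once")
  if (!setequal(as.integer(names(layout$ssr_map)), shorts)) {
    stop("ssr_map keys must be the short channels")
  }
  if (length(layout$wavelengths) != 2L) stop("layout requires exactly two wavelengths")
  invisible(layout)
}

#' Stimulus protocol parameters
#'
#' Describes the event protocol: a resting baseline followed by interleaved
#' trials of three stimulation conditions (painful pressure `PAPain`,
#' non-painful pressure `PAnP`, tactile brushing `Brush`), each applied
#' `trials_per_condition` times for `stimulus_s` seconds with an
#' inter-stimulus interval of `isi_s` seconds, in pseudo-random order with no
#' more than `max_consecutive_repeats` equal consecutive trials.
#'
#' @param baseline_s Baseline duration in s before the first trial.
#' @param conditions Character vector of condition labels.
#' @param trials_per_condition Number of trials per condition.
#' @param stimulus_s Stimulus duration in s.
#' @param isi_s Inter-stimulus interval in s.
#' @param max_consecutive_repeats Maximum allowed run of identical labels.
#' @return An object of class `stimulus_protocol` (no sequence yet; see
#'   [generate_stimulus_sequence()]).
#' @export
stimulus_protocol <- function(baseline_s = 300,
                              conditions = c("PAPain", "PAnP", "Brush"),
                              trials_per_condition = 15,
                              stimulus_s = 5,
                              isi_s = 15,
                              max_consecutive_repeats = 2) {
  stopifnot(trials_per_condition >= 1, stimulus_s > 0, isi_s >= 0,
            length(conditions) >= 1, baseline_s >= 0)
  structure(
    list(baseline_s = baseline_s,
         conditions = conditions,
         trials_per_condition = trials_per_condition,
         stimulus_s = stimulus_s,
         isi_s = isi_s,
         max_consecutive_repeats = max_consecutive_repeats,
         sequence = NULL),
    class = "stimulus_protocol"
  )
}

#' Total recording duration implied by a protocol, in seconds
#' @param protocol A `stimulus_protocol`.
#' @return Duration in s (baseline plus all trial/ISI slots).
#' @export
protocol_duration_s <- function(protocol) {
  n <- protocol$trials_per_condition * length(protocol$conditions)
  protocol$baseline_s + n * (protocol$stimulus_s + protocol$isi_s)
}

#' Generate a constraint-satisfying pseudo-random stimulus sequence
#'
#' Draws uniform random shuffles of the full trial list and rejects any with a
#' run of identical condition labels longer than
#' `max_consecutive_repeats` (rejection sampling, uniform over valid
#' sequences). Onset of trial k (0-based) is
#' `baseline_s + k * (stimulus_s + isi_s)` exactly.
#'
#' @param protocol A `stimulus_protocol`.
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @param max_attempts Safety bound on rejection-sampling attempts.
#' @return The protocol with `sequence` filled in: a tibble with columns
#'   `onset_s`, `duration_s`, `condition`.
#' @export
generate_stimulus_sequence <- function(protocol, seed, max_attempts = 100000) {
  if (protocol$max_consecutive_repeats < 1) {
    stop("max_consecutive_repeats < 1: constraint unsatisfiable")
  }
  labels <- rep(protocol$conditions, each = protocol$trials_per_condition)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ok <- FALSE
  for (i in seq_len(max_attempts)) {
    cand <- sample(labels)
    if (max(rle(cand)$lengths) <= protocol$max_consecutive_repeats) {
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("no valid sequence found: constraint appears unsatisfiable")
  n <- length(cand)
  protocol$sequence <- tibble::tibble(
    onset_s = protocol$baseline_s +
      (seq_len(n) - 1) * (protocol$stimulus_s + protocol$isi_s),
    duration_s = rep(protocol$stimulus_s, n),
    condition = cand
  )
  protocol
}

#' Validate a condition-label sequence against protocol constraints
#'
#' Checks that each condition occurs exactly `trials_per_condition` times and
#' that no run of identical labels exceeds `max_consecutive_repeats`.
#'
#' @param sequence Character vector of condition labels (or a protocol whose
#'   `sequence` is used).
#' @param protocol A `stimulus_protocol`.
#' @return A list with `valid` (logical) and `violations` (tibble with
#'   columns `type`, `position`, `detail`; zero rows when valid).
#' @export
validate_sequence <- function(sequence, protocol) {
  if (inherits(sequence, "stimulus_protocol")) sequence <- sequence$sequence$condition
  if (length(sequence) == 0) stop("sequence is empty")
  viol <- list()
  counts <- table(factor(sequence, levels = protocol$conditions))
  bad <- names(counts)[counts != protocol$trials_per_condition]
  for (b in bad) {
    viol[[length(viol) + 1L]] <- tibble::tibble(
      type = "count", position = NA_integer_,
      detail = sprintf("condition %s occurs %d times, expected %d",
                       b, counts[[b]], protocol$trials_per_condition))
  }
  extra <- setdiff(unique(sequence), protocol$conditions)
  for (e in extra) {
    viol[[length(viol) + 1L]] <- tibble::tibble(
      type = "label", position = match(e, sequence),
      detail = sprintf("unknown condition label %s", e))
  }
  r <- rle(as.character(sequence))
  ends <- cumsum(r$lengths)
  over <- which(r$lengths > protocol$max_consecutive_repeats)
  for (i in over) {
    pos <- ends[i] - r$lengths[i] + protocol$max_consecutive_repeats + 1L
    viol[[length(viol) + 1L]] <- tibble::tibble(
      type = "run", position = as.integer(pos),
      detail = sprintf("run of %d consecutive %s starting at %d",
                       r$lengths[i], r$values[i], ends[i] - r$lengths[i] + 1L))
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(type = character(), position = integer(), detail = character())
  list(valid = nrow(violations) == 0, violations = violations)
}

#' Write / read a 3-column events table (TSV)
#'
#' @param protocol A protocol with a generated sequence.
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the events tibble (onset_s, duration_s, condition).
#' @export
write_events_tsv <- function(protocol, path) {
  if (is.null(protocol$sequence)) stop("protocol has no sequence; generate one first")
  utils::write.table(protocol$sequence, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("events file has no rows")
  tibble::as_tibble(df[need])
}

# Seed scoping helpers: run code under a given seed and restore the caller's
# RNG state afterwards so library functions never perturb user randomness.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% (.Machine$integer.max - 1)))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
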