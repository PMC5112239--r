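#' Optical constants: extinction coefficients and DPF polynomial
#'
#' Bundles the chromophore extinction coefficients and the coefficients of the
#' general age- and wavelength-dependent differential pathlength factor (DPF)
#' polynomial used by the modified Beer-Lambert law (MBLL).
#'
#' The default extinction table is the widely used compiled spectrum of
#' hemoglobin molar extinction coefficients (base-10, in mM^-1 cm^-1) at
#' 760 and 850 nm:
#' \preformatted{
#'            O2Hb     HHb
#'   760 nm  0.5860  1.5485
#'   850 nm  1.0580  0.6913
#' }
#' Users can substitute any other table; the matrix must be non-singular.
#'
#' The DPF polynomial is
#' `DPF(lambda, age) = a + b*age^g - d*lambda^3 + e*lambda^2 - z*lambda`
#' with published coefficients `a = 223.3`, `b = 0.05624`, `g = 0.8493`,
#' `d = 5.723e-7`, `e = 0.001245`, `z = 0.9025` (lambda in nm, age in years).
#'
#' @param extinction 2x2 matrix, rows = wavelengths (in the order of the
#'   layout's `wavelengths`), columns = c("o2hb", "hhb"), in mM^-1 cm^-1.
#' @param wavelengths Wavelengths (nm) the extinction rows refer to.
#' @param dpf_coefficients Named numeric vector with elements
#'   `a, b, g, d, e, z`.
#' @return An object of class `optical_constants`.
#' @export
optical_constants <- function(extinction = NULL,
                              wavelengths = c(760, 850),
                              dpf_coefficients = c(a = 223.3, b = 0.05624,
                                                   g = 0.8493, d = 5.723e-7,
                                                   e = 0.001245, z = 0.9025)) {
  if (is.null(extinction)) {
    extinction <- matrix(c(0.5860, 1.5485,
                           1.0580, 0.6913),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(as.character(wavelengths),
                                         c("o2hb", "hhb")))
  }
  if (!all(dim(extinction) == c(2, 2))) stop("extinction must be a 2x2 matrix")
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  stopifnot(all(c("a", "b", "g", "d", "e", "z") %in% names(dpf_coefficients)))
  structure(list(extinction = extinction,
                 wavelengths = wavelengths,
                 dpf_coefficients = dpf_coefficients,
                 units_out = "uM"),
            class = "optical_constants")
}

#' Differential pathlength factor for a wavelength and age
#'
#' Evaluates the general DPF polynomial (see [optical_constants()]), which is
#' strictly increasing in age at fixed wavelength and yields values in the
#' physiological 4-8 range over 690-900 nm for adult ages.
#'
#' @param wavelength Wavelength in nm; must lie in \[690, 900\] unless
#'   `extrapolate = TRUE`.
#' @param age Age in years (> 0).
#' @param constants An [optical_constants()] object.
#' @param extrapolate Allow wavelengths outside the calibrated range.
#' @return Dimensionless DPF (vectorized over `wavelength` and `age`).
#' @export
compute_dpf <- function(wavelength, age, constants = optical_constants(),
                        extrapolate = FALSE) {
  if (!extrapolate && any(wavelength < 690 | wavelength > 900)) {
    stop("wavelength outside [690, 900] nm; set extrapolate = TRUE to override")
  }
  if (any(age <= 0)) stop("age must be positive")
  k <- constants$dpf_coefficients
  k[["a"]] + k[["b"]] * age^k[["g"]] - k[["d"]] * wavelength^3 +
    k[["e"]] * wavelength^2 - k[["z"]] * wavelength
}

#' Construct a raw intensity recording
#'
#' Container for per-channel, per-wavelength detector intensities on a uniform
#' time grid, together with the probe layout, the stimulus protocol and the
#' subject metadata the downstream stages need.
#'
#' @param intensity Numeric array `[channel x wavelength x time]`, strictly
#'   positive, in arbitrary detector units.
#' @param layout A `probe_layout`.
#' @param protocol A `stimulus_protocol` (with sequence, for downstream
#'   epoching).
#' @param subject List with `id`, `group` (`"CLBP"` or `"HC"`), `age` (years).
#' @param i0 Optional per-channel reference intensities (channel x wavelength
#'   matrix) when the recording was produced by the forward model.
#' @return Object of class `raw_intensity_recording` with a `time` vector in s.
#' @export
raw_intensity_recording <- function(intensity, layout, protocol, subject,
                                    i0 = NULL) {
  stopifnot(length(dim(intensity)) == 3)
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at channel %d, wavelength %d, sample %d",
                 bad[1], bad[2], bad[3]))
  }
  n_ch <- nrow(layout$channels)
  if (dim(intensity)[1] != n_ch) stop("intensity channel dimension != layout channels")
  if (dim(intensity)[2] != length(layout$wavelengths)) {
    stop("intensity wavelength dimension != layout wavelengths")
  }
  nt <- dim(intensity)[3]
  structure(list(intensity = intensity,
                 time = (seq_len(nt) - 1) / layout$sampling_rate,
                 layout = layout, protocol = protocol,
                 subject = subject, i0 = i0),
            class = "raw_intensity_recording")
}

#' Convert raw intensities to optical density changes
#'
#' Computes base-10 attenuation changes
#' `OD[c, w, t] = -log10(I[c, w, t] / I_ref[c, w])` where the per-channel,
#' per-wavelength reference `I_ref` is taken over a reference window.
#'
#' @param recording A [raw_intensity_recording()].
#' @param reference Reference definition: `"baseline"` (default; mean
#'   intensity over the protocol's baseline period), `"mean"` / `"median"`
#'   (whole recording), `"first_n_seconds"` (mean over the first `window_s`
#'   seconds) or `"i0"` (the stored forward-model reference, exact inverse of
#'   the simulator).
#' @param window_s Window length for `"first_n_seconds"`.
#' @return Object of class `od_series`: list with `od` array
#'   `[channel x wavelength x time]`, `time`, `layout`, `protocol`, `subject`.
#' @export
intensity_to_od <- function(recording,
                            reference = c("baseline", "mean", "median",
                                          "first_n_seconds", "i0"),
                            window_s = NULL) {
  reference <- match.arg(reference)
  I <- recording$intensity
  d <- dim(I)
  iref <- switch(reference,
    baseline = {
      idx <- recording$time < recording$protocol$baseline_s
      if (!any(idx)) stop("baseline reference window is empty")
      rowMeans(I[, , idx, drop = FALSE], dims = 2)
    },
    mean = rowMeans(I, dims = 2),
    median = apply(I, c(1, 2), stats::median),
    first_n_seconds = {
      if (is.null(window_s) || window_s <= 0) stop("window_s required for first_n_seconds")
      idx <- recording$time < window_s
      if (!any(idx)) stop("reference window is empty")
      rowMeans(I[, , idx, drop = FALSE], dims = 2)
    },
    i0 = {
      if (is.null(recording$i0)) stop("recording carries no i0 reference")
      recording$i0
    }
  )
  od <- -log10(I / as.vector(iref))  # iref recycles over the time dimension
  structure(list(od = od, time = recording$time, layout = recording$layout,
                 protocol = recording$protocol, subject = recording$subject),
            class = "od_series")
}

#' Convert optical density to hemoglobin concentration changes (MBLL)
#'
#' Solves, per channel and time point, the 2x2 modified Beer-Lambert system
#' `OD_w = (eps[w, o2hb] * dC_o2hb + eps[w, hhb] * dC_hhb) * d_cm * DPF(w, age)`
#' for the relative concentration changes `dC` (output in uM). `d_cm` is the
#' channel's source-detector separation in cm and the DPF is the
#' age/wavelength polynomial of [compute_dpf()], so short and long channels
#' each get their own effective pathlength.
#'
#' @param od An `od_series`.
#' @param constants [optical_constants()]; its extinction rows must match the
#'   layout wavelengths.
#' @param age Subject age in years (defaults to the recording's metadata).
#' @return Object of class `hb_series`: list with `o2hb` and `hhb` matrices
#'   `[channel x time]` in uM, `time`, `fs`, `layout`, `protocol`, `subject`
#'   and provenance flags `filtered`, `detrended`, `ssr_applied`.
#' @export
mbll_convert <- function(od, constants = optical_constants(), age = NULL) {
  layout <- od$layout
  if (is.null(age)) age <- od$subject$age
  if (is.null(age)) stop("subject age required for DPF")
  if (!isTRUE(all.equal(constants$wavelengths, layout$wavelengths))) {
    stop("extinction table wavelengths do not match layout wavelengths")
  }
  E <- constants$extinction
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  sep_cm <- layout$channels$separation_mm / 10
  if (any(!is.finite(sep_cm)) || any(sep_cm <= 0)) stop("missing channel separation")
  dpf <- compute_dpf(layout$wavelengths, age, constants)
  n_ch <- dim(od$od)[1]
  nt <- dim(od$od)[3]
  Einv <- solve(E)
  o2hb <- matrix(0, n_ch, nt)
  hhb <- matrix(0, n_ch, nt)
  for (w in 1:2) {
    # y_w = OD_w / (d * DPF_w), then dC = 1000 * Einv %*% y  (mM -> uM)
    yw <- od$od[, w, ] / (sep_cm * dpf[w])   # n_ch x nt, row-wise scaling
    o2hb <- o2hb + 1000 * Einv[1, w] * yw
    hhb <- hhb + 1000 * Einv[2, w] * yw
  }
  structure(list(o2hb = o2hb, hhb = hhb, time = od$time,
                 fs = layout$sampling_rate, layout = layout,
                 protocol = od$protocol, subject = od$subject,
                 filtered = FALSE, detrended = FALSE, ssr_applied = FALSE),
            class = "hb_series")
}

#' Forward MBLL: hemoglobin concentration changes to raw intensities
#'
#' Exact inverse of [intensity_to_od()] + [mbll_convert()]: maps uM
#' concentration changes through the MBLL to base-10 attenuation changes and
#' then to detector intensities `I = I0 * 10^(-OD)`. Used by the synthetic
#' generator so the full optics stage is exercised end to end.
#'
#' @param o2hb,hhb Matrices `[channel x time]` in uM.
#' @param layout A `probe_layout`.
#' @param protocol A `stimulus_protocol`.
#' @param subject Subject metadata list (needs `age`).
#' @param constants [optical_constants()].
#' @param i0 Baseline intensity per channel (scalar or channel x wavelength
#'   matrix); arbitrary positive units, only intensity ratios matter.
#' @return A [raw_intensity_recording()] carrying `i0` so the round trip is
#'   exact under `intensity_to_od(reference = "i0")`.
#' @export
forward_model <- function(o2hb, hhb, layout, protocol, subject,
                          constants = optical_constants(), i0 = 1e6) {
  E <- constants$extinction
  sep_cm <- layout$channels$separation_mm / 10
  dpf <- compute_dpf(layout$wavelengths, subject$age, constants)
  n_ch <- nrow(o2hb)
  nt <- ncol(o2hb)
  if (length(i0) == 1) i0 <- matrix(i0, n_ch, 2)
  I <- array(NA_real_, c(n_ch, 2, nt))
  for (w in 1:2) {
    odw <- (E[w, "o2hb"] * o2hb + E[w, "hhb"] * hhb) / 1000 * (sep_cm * dpf[w])
    I[, w, ] <- i0[, w] * 10^(-odw)
  }
  raw_intensity_recording(I, layout, protocol, subject, i0 = i0)
}
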