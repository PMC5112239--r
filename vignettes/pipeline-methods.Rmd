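---
title: "Methods: from raw two-wavelength intensities to channel-wise statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw two-wavelength intensities to channel-wise statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`painfnirs` implements a complete analysis chain for event-related,
continuous-wave fNIRS experiments in which painful pressure, non-painful
pressure and tactile brushing (`PAPain`, `PAnP`, `Brush`) are applied to the
lower back while cortical hemodynamics are recorded over the supplementary
motor area (SMA) and the primary somatosensory cortex (S1). This vignette
explains the model behind every stage, the tunable parameters and their
defaults, the design decisions taken where the methodology is genuinely open,
and what the packaged simulation studies do and do not demonstrate.

## Study structure

The montage has 18 channels at 7.81 Hz and two wavelengths (760/850 nm).
Channels 1–6 cover the SMA and 7–18 the S1; channels 2 and 10 are
short-separation channels (~11 mm source–detector distance) that sample only
superficial tissue, while long channels have 25–45 mm separations. A session
is 5 min of rest followed by 45 trials (15 per condition) of 5 s stimulation
with a 15 s inter-stimulus interval, in pseudo-random order with at most two
equal consecutive trials. `build_default_layout()` and `stimulus_protocol()`
encode this structure; `generate_stimulus_sequence()` draws a
constraint-satisfying order by rejection sampling over uniform shuffles,
which is exactly uniform over the set of valid sequences.

## Optics

Detector intensities are converted to base-10 optical density changes
against a reference window, `OD = -log10(I / I_ref)`. The reference is the
mean intensity over the 5 min baseline by default; because every downstream
stage works on changes (and epochs are re-normalized), the choice affects
only an additive constant per channel. The modified Beer–Lambert law then
gives relative concentration changes per channel and time point by solving

$$\mathrm{OD}_\lambda = \left(\varepsilon_{\lambda,\mathrm{O_2Hb}}\,
\Delta C_{\mathrm{O_2Hb}} + \varepsilon_{\lambda,\mathrm{HHb}}\,
\Delta C_{\mathrm{HHb}}\right)\, d \cdot \mathrm{DPF}(\lambda, \mathrm{age}),$$

a 2×2 linear system per channel. `d` is the channel's source–detector
separation in cm, so short and long channels each get their correct
pathlength. The differential pathlength factor uses the general
age-and-wavelength polynomial
`DPF = 223.3 + 0.05624 age^0.8493 − 5.723e-7 λ³ + 0.001245 λ² − 0.9025 λ`,
which is strictly increasing in age and lies in the physiological 4–8 range
across 690–900 nm for adult ages. Extinction coefficients default to the
standard compiled hemoglobin spectra (0.586/1.5485 and 1.058/0.6913
mM⁻¹cm⁻¹ at 760/850 nm); both the table and the DPF coefficients are
configurable in `optical_constants()`. Outputs are relative changes in µM;
no partial-volume correction is applied.

## Filtering

Two Savitzky–Golay stages, both degree 3: a 4 s smoothing window removes
cardiac pulsation and measurement noise, and an 80 s window estimates the
slow trend (drift, very-low-frequency vasomotion) which is then subtracted.
Window lengths in samples are the nearest odd integer to `window_s × fs`
(31 and 625 samples at 7.81 Hz). Edge samples are produced by the SG
projection matrix itself — the polynomial fit over the first/last full
window evaluated at the edge positions — so polynomials of degree ≤ 3 are
reproduced exactly everywhere, including the edges; this is also the
behavior verified by the filter-exactness tests. Interior samples are
computed by FFT convolution with the central SG kernel, identical to the
direct convolution to machine precision.

Two quantitative properties worth knowing: a degree-3 trend maps to zero
exactly under the detrend stage, and an isolated 25 s plateau loses roughly
20 % of its center amplitude to the 80 s trend fit. The pipeline is not
sensitive to the latter because trials are 12.8 s epochs that are re-based
per trial (below), but users filtering very slow block designs should keep
it in mind.

## Epoching and normalization

Trials are cut as 3.9 s pre-stimulus + 5 s stimulus + 3.9 s post-stimulus
(12.8 s). Onset samples are `floor(onset × fs)` and every epoch has exactly
`round(12.8 × fs)` = 100 samples, so trial stacks are rectangular. Per
channel and trial, a least-squares line over the whole epoch is subtracted
(within-trial drift), then the median of the 3.9 s pre-stimulus window
(30 samples) is subtracted, making the pre-window median exactly zero. The
block average — the single value per subject, channel, condition and
chromophore that all statistics use — is the median over the middle 2.5 s of
the stimulus window (`[onset+1.25 s, onset+3.75 s]`, 20 samples) pooled
across the 15 trials; a median-of-trial-medians variant is available.

## Short-separation regression

Superficial (scalp blood flow) contamination is removed by regressing each
long channel on its zone's short channel: channel 2 corrects channels 1 and
3–6, channel 10 corrects 7–9 and 11–18. The coefficient is the one-regressor
least-squares solution `β = ⟨long, short⟩ / ⟨short, short⟩` and the corrected
series is orthogonal to the regressor, so the correction can never increase
the sum of squares.

**Scope of the regression (a deliberate design decision).** The package fits
`β` on the whole filtered recording before segmentation
(`ssr_scope = "continuous"`), which is the form in which the short-channel
regression method was published. A per-epoch variant (`"per_epoch"`, one `β`
per trial after normalization) is provided, but it is not the default for a
quantitative reason: inside a 12.8 s epoch a single-cycle hemodynamic
response is nearly collinear with Mayer-band (≈ 0.1 Hz) activity of the
short channel, so a per-epoch single-regressor fit projects out a large
share of the evoked amplitude itself. In simulation with known ground truth,
the continuous fit recovers ~97 % of the injected amplitude at high SNR
while the per-epoch fit retains only ~30 %. The per-epoch regime is still
the right instrument for measuring *removal* of a strong injected scalp
component (see the verification studies), but as an estimation default it
would bias every downstream statistic toward zero. A second practical point:
with ~100 strongly autocorrelated samples per epoch the per-epoch `β` has
large sampling variance (the SG-smoothed epoch carries roughly 7 effective
degrees of freedom).

## Statistics

All tests are nonparametric. Single-subject screening applies a Wilcoxon
signed-rank test to the 15 per-trial middle-window medians against zero, per
channel, condition and chromophore; a cell is a *responder* at uncorrected
p < 0.05. Group analyses run in two modes: `All` (every long channel and
subject) and `Responders` (only screened cells contribute; paired tests
require survival in all involved conditions, and cells with fewer than five
surviving subjects are reported untested). Group-level tests per long
channel are: a tie-corrected Friedman test for the condition main effect,
paired signed-rank post-hoc contrasts between the three conditions, and
per-condition signed-rank tests of the block averages against zero —
"baseline" here is zero because trials are normalized to a zero pre-stimulus
median. Between-group comparisons use the unpaired rank-sum test (the groups
are independent, n = 12 vs 20). Each family — one test type × condition ×
chromophore × group, i.e. the 16 long channels — is Benjamini–Hochberg
corrected with significance at q < 0.05.

Exact p-values: signed-rank tests enumerate all 2ⁿ sign assignments of the
observed (possibly tied) ranks for n ≤ 15 (using the closed-form
distribution when there are no ties, which is identical), with a
tie-corrected, continuity-corrected normal approximation beyond; rank-sum
tests enumerate rank allocations when the smaller sample is ≤ 10. Zero
differences are discarded (classic treatment; Pratt's method is available).
The Friedman statistic uses the tie-corrected rank formula and the χ²
reference with k−1 degrees of freedom; at n = 12 blocks this tracks the
exact permutation distribution to within about 0.1 in the mid p-range,
which is the usual price of the asymptotic reference at these sample sizes.
The Spearman correlation between pressure-pain thresholds and channel
responses is the Pearson correlation of mid-ranks with the t approximation.

Single patients are compared against the healthy norm by signed-rank tests
of their 15 per-trial values against the HC grand-average scalar per channel
(BH across channels within patient × condition × chromophore), with the
deviation direction given by the sign of the median difference. Group grand
averages report the across-subject median with the standard error of the
median, `SEMed = 1.2533 · SD/√n` (asymptotic normal-theory constant
√(π/2) ≈ 1.2533); a bootstrap estimate is available and agrees within ~15 %
on Gaussian data.

Heart-rate analysis summarizes a 1 Hz series into per-condition means and
maxima over half-open windows — stimulus `[onset, onset+5)`, pre-ISI
`[onset−15, onset)`, post-ISI `[onset+5, onset+20)` — so no sample is
counted twice; per-trial maxima are averaged across trials by default.
`ΔHRmax = HRmax(stimulus) − HRmax(post-ISI)` feeds a Friedman test across
conditions, and per condition the stimulus and post-ISI maxima are compared
by paired signed-rank, BH-corrected over the three conditions.

## The synthetic-data generator

`sim_config()` / `simulate_cohort()` generate cohorts of 20 controls and 12
patients with known ground truth. A subject's concentration signal per long
channel is

*task* + *cerebral systemic* + *coupling × scalp* + *drift* + *noise*,

and each short channel carries the scalp component at unit weight plus
noise — short channels sample superficial tissue only, which is exactly the
premise of the short-channel regression. The pieces:

- **Task**: a gamma kernel with 6 s peak latency convolved with each
  condition's stimulus train. Amplitudes (defaults 0.5, 0.4, 0.15 µM
  oxyhemoglobin for painful pressure, non-painful pressure and brushing;
  deoxyhemoglobin at −⅓ of that) are *calibrated*: the scale is chosen so
  that the noise-free signal, passed through the epoch pipeline, yields a
  block value equal to the configured amplitude. The stored ground truth is
  computed by running the actual noise-free injected signal through the
  epoch pipeline, so it also accounts for response overlap between
  neighboring trials (tails of one trial reaching into the next trial's
  pre-window).
- **Cerebral systemic**: narrowband oscillations near 0.1 Hz (Mayer),
  0.25 Hz (respiration) and 1.1 Hz (cardiac), each a sinusoid with
  random-walk phase. The phase diffusion matters: physiological rhythms
  drift, and a mathematically pure 0.1 Hz sinusoid is an exact harmonic of
  the 20 s trial cycle — it would be phase-locked to every epoch and never
  average out, which is an artifact of the simulation, not a property of
  physiology.
- **Scalp component**: a slow AR(1) fluctuation (0.3 µM), a scalp-borne
  Mayer oscillation (0.3 µM), and a stimulus-evoked scalp response
  (0.15 µM) with its own *fast* gamma kernel (peak ≈ 1.5 s), reflecting
  sympathetic scalp blood-flow reactions that are quicker than neurovascular
  coupling. Long channels receive this component at per-channel coupling
  weights drawn from U(0.3, 0.7).
- **Drift and noise**: a random-walk drift (0.05 µM/√s) and white noise
  (0.2 µM per sample) per channel.

The concentration signals are passed through the forward Beer–Lambert model
to two-wavelength intensities (`I = I₀·10^(−OD)`), so the full optics stage
is exercised end to end; the forward/inverse pair round-trips to machine
precision. Heart rate is a per-subject baseline (group means 62.0/63.3 bpm
with the observed between-subject SDs) plus a small evoked bump peaking
~8 s after onset — i.e. inside the post-ISI window, reproducing the
characteristic post-stimulus elevation — plus noise. Behavioral records draw
pressure-pain thresholds from the groups' observed distributions
(45 ± 18 N patients, 57 ± 7.3 N controls, truncated positive) and
questionnaire scores around the patient cohort's published means.

What the generator does **not** emulate: motion artifacts, optode-coupling
changes, spatially structured (anatomical) channel correlations, habituation
or sensitization across trials, and any dependence of response amplitude on
the individual pressure force. Passing the packaged studies therefore shows
that the pipeline is correct and well-calibrated under stationary,
artifact-free physiology — not that it is robust to everything real
recordings contain.

## Verification studies and problem sizes

Four seeded studies (in `R/studies.R`) back the package's claims; the test
suite runs them at full size and the reproduction script reports their
numbers.

- `study_null_fdr()`: 200 cohorts of 12 + 20 subjects with zero amplitude
  everywhere; the full pipeline plus the complete statistical battery. The
  fraction of channel-wise tests with q < 0.05 must stay at or below
  0.05 + 3·SE. Recordings are shortened to 12 s baseline and 3 trials per
  condition so 200 cohorts run in minutes on one CPU; the group-level null
  tests do not depend on trial count.
- `study_amplitude_recovery()`: full-length subjects; the pooled median of
  recovered/true block amplitude must be within 10 % of unity at high SNR
  (nuisance amplitudes ~10× smaller) and 25 % at the default noise level.
  Per-channel worst cases at default SNR are larger for the weakest
  condition (brushing, 0.15 µM), as its single-channel SNR implies.
- `study_ssr_efficacy()`: a designed removal experiment — a pronounced scalp
  component (slow 1.2 µM, Mayer-band 1.5 µM, evoked 0.5 µM) with null
  cortical amplitudes, per-epoch regression — measuring the variance of the
  injected component that survives correction: `(w − β)²·var(s)` against
  `w²·var(s)`, summed over epochs and channels; required ≤ 5 %, observed
  1–2 %. The injection is strong on purpose: at weak contamination the
  statistic measures the coefficient's sampling noise instead of removal.
- `study_responders_specificity()`: cohorts in which half the long channels
  are null; the false-positive channel rate of the responder-screened mode
  must not exceed the all-channel mode's (observed: screening drives it to
  ~0 while retaining > 50 % sensitivity on true channels at 6 trials per
  condition — the smallest trial count at which a single-subject exact test
  can reach p < 0.05).

## Known limitations

The asymptotic SEMed constant assumes approximate normality; the Friedman χ²
reference is asymptotic at n = 12; the per-epoch SSR variant should be used
for methodological comparisons, not estimation; the published group-level
statistics of the original pressure-pain dataset cannot be reproduced
without the original recordings, which were not deposited — the packaged
studies verify the pipeline's properties on synthetic data with known truth
instead, plus an exact reproduction of the published behavioral summary
table.
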