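---
title: "Quantifying slow drifts in alpha-band frequency and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying slow drifts in alpha-band frequency and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG analyses routinely assume that, absent experimental manipulation, an
oscillator's spectral content is stationary over a recording session: alpha
activity (8–13 Hz) is pictured as fluctuating spontaneously around a stable
individual peak frequency and power. Over the course of an hour-long session
this assumption can fail in a structured way — the peak alpha frequency
slides slowly downward while alpha power ramps up. Because the two drifts
can arise from one process or from several superimposed alpha generators
with different centre frequencies, disentangling them requires more than a
before/after comparison: it takes single-trial trend statistics with proper
familywise-error control, distribution-matching controls, and source
separation.

`alphadrift` implements that analysis chain end to end:

1. **Split-half spectral analysis** (`split_half_analysis`) — trial
   baselines are Hamming-windowed, zero-padded to a 0.1 Hz grid and Fourier
   transformed; per subject the peak alpha frequency and power are compared
   between session halves with paired t-tests.
2. **Instantaneous alpha frequency** (`epoch_instfreq`) — a plateau-shaped
   zero-phase band-pass, the Hilbert-transform phase derivative, and a
   median-filter bank for spike suppression, binned at 20 ms to match the
   sliding-window Hanning time–frequency power (`timefreq_power`).
3. **Trend statistics** (`trial_order_rho`, `cluster_permutation`) —
   per-datapoint Spearman correlations of each measure with trial order,
   tested across subjects with spatio-temporal cluster-based sign-flip
   permutation correction; polynomial fits (`poly_trend_fit`) and the
   two-line test (`two_line_test`) characterize the shape of the trends and
   of the frequency–power relationship.
4. **Stratification** (`stratified_split_half`) — histogram-based trial
   subsampling equalizes one measure's distribution between session halves
   to ask whether the other measure's drift survives.
5. **Component analysis** (`extract_alpha_components`, `component_trend`,
   `circular_summary`) — PCA + ICA source separation of 5–15 Hz filtered
   baselines, per-component permutation trend tests, classification into
   mixed / unique-power / unique-frequency drift types, and circular
   statistics (Rayleigh, circular T², BCa bootstrap centroid CIs) on the
   joint trend distribution.
6. **Synthetic cohorts** (`generate_cohort`, `scenario_preset`) — a
   first-class generator that plants known drifts so that every stage above
   is validated by parameter recovery.

## The generator and its three scenarios

Each synthetic source is a sinusoid whose per-trial frequency is drawn as

$$f_i = f_0 + \Delta f \, u_i + \varepsilon_i, \qquad
  \varepsilon_i \sim \mathcal N(0, \sigma_b^2),$$

where $u_i = (i-1)/(N-1)$ is session progress, $\Delta f$ the planted total
frequency drift (Hz per session) and $\sigma_b$ the cycle-to-cycle jitter
that gives the spectral peak its width. The amplitude ramps as
$a_i = a_0 (1 + \Delta p\, u_i)$, optionally with multiplicative log-normal
jitter. Sources are projected through unit-norm Gaussian scalp topographies
over a 60-channel layout (shipped as `inst/extdata/layout60.csv`; at a 5 cm
cutoff it yields a mean of 6.4, median 7, range 3–8 neighbours per
electrode, matching a typical 60-electrode montage), and 1/f background
noise (spectra shaped by $f^{-\gamma/2}$, $\gamma = 1$ by default) is added
independently per channel and trial.

We parameterize progress as $u=(i-1)/(N-1)$ so the first trial sits exactly
at $f_0$ and the last at $f_0 + \Delta f$; "drift per session" then means
the difference between the last and first trial's means. For a linear
drift, the expected difference between second- and first-half means is
$\Delta f/2$, so `session_drift_estimate()` doubles the split-half delta to
produce a method-of-moments estimate of the planted session drift.

`scenario_preset()` encodes the three generative models that can all
produce the same sensor-level pattern (frequency down, power up):

* **A** — one oscillator at 10 Hz with both drifts (−0.25 Hz and +20 % per
  session; these magnitudes correspond to the order of drift reported for
  hour-long sessions). A `coupled = TRUE` variant derives the entire
  frequency slide deterministically from the power ramp
  (−1.25 Hz per unit relative amplitude × +20 % = −0.25 Hz), which is the
  configuration the stratification analysis must *abolish*.
* **B** — two spatially and spectrally distinct oscillators, one with a
  unique power increase, one with a unique frequency decrease.
* **C** — two oscillators at 9 and 11 Hz with *no* frequency drift at all;
  only the lower one gains power (+60 % from a 0.75 relative baseline).
  Because the sensor spectrum is their weighted sum, the in-band argmax
  slides toward 9 Hz as the power ratio changes — an emergent frequency
  drift without any drifting oscillator. In scenario C both sources project
  to the same scalp site, since the effect requires the analyzed electrode
  to see both spectra; the jitter is widened to 1 Hz so the two peaks merge
  into a single movable maximum.

The generator's per-trial frequency is constant within a trial by default
(the spontaneous-fluctuation model); an optional within-trial random-walk
mode (`within_trial_walk_sd`) exists to stress-test the instantaneous
frequency estimator, and the planted walk is stored in the ground truth so
tests can compare bin means against a decimated oracle. What the generator
does **not** emulate: artifacts (blinks, muscle), non-sinusoidal waveform
shape, volume-conduction head modelling (topographies are phenomenological
Gaussian bumps), or trial-to-trial autocorrelation beyond the planted
ramps. Passing recovery tests therefore demonstrate the correctness of the
analysis chain, not robustness to every property of real recordings.

## Numerical choices

**Plateau band-pass.** The filter's amplitude response is exactly 1 across
the passband, falls to 0 over raised-cosine transition zones spanning 15 %
of each band edge (6.8–8 Hz and 13–14.95 Hz for the alpha band), and is 0
elsewhere. We realize this response directly in the frequency domain with a
purely real transfer function: the phase is identically zero (symmetric
equivalent impulse response, no group delay), which is the property a
forward–backward two-pass FIR application is designed to approximate. A
windowed FIR at the conventional order (~3 cycles of the lower band edge)
misses the passband-flatness requirement by 10–20 % at the band centre,
which would bias amplitude-sensitive checks; the spectral realization has
no passband ripple by construction. Epoch edges are extended by odd
reflection (half a second) before transforming to limit boundary
transients.

**Instantaneous frequency.** The analytic signal is obtained by the
frequency-domain Hilbert transform, the phase is unwrapped, and the forward
difference scaled by $f_s/2\pi$ gives a per-sample frequency one sample
shorter than the input; the last value is replicated so the 20 ms bin grid
covers the epoch (that bin touches the epoch edge and is excluded from
interior analyses). All-zero inputs have undefined phase and are returned
as NaN. Spike denoising applies ten median filters with windows linearly
spaced from 10 to 400 ms (converted to odd sample counts) and takes the
pointwise median of the ten outputs — pointwise, because the bank's purpose
is per-sample robustness; this convention is asserted by an
order-statistic property test. Interior behaviour matches `stats::runmed`;
at the array edges we use shrinking symmetric windows.

**Spectra.** Baselines are Hamming-windowed and zero-padded to a 0.1 Hz
grid. Since zero-padding only interpolates the DFT, the retained band is
computed as a band-restricted DFT (one matrix product), which is
numerically identical to the padded FFT (asserted to 1e-15) and much
cheaper. Band edges are inclusive (8.0 and 13.0 Hz bins count); argmax ties
break toward the lower frequency, electrode ties toward the lower index.
With Savitzky–Golay smoothing (11-point, 3rd order; component selection),
the in-band maximum must additionally be a strict local maximum away from
the band edges, so monotone 1/f spectra and boundary bumps yield "no peak".

**Split halves.** Trials are split by ascending acquisition order; odd
counts give the extra trial to the first half. Deltas are always second
minus first; a proportional variant divides by the first half. Degenerate
cohorts whose deltas have zero variance return NA group statistics rather
than failing.

**Cluster permutation.** Suprathreshold samples (|t| above the two-tailed
5 % quantile) are clustered by spatial adjacency (distance cutoff, default
5 cm) at the same timepoint plus temporal adjacency (consecutive 20 ms
bins) on the same channel. Following the published membership rule, a
sample must also have at least one suprathreshold neighbour in space *and*
in time (`require_neighbours = TRUE`, one pruning pass). The sign-flip null
flips whole subjects' rho maps, retains each permutation's most extreme
positive and negative cluster masses, and applies the $+1$ p-value
correction; significance is two-tailed at the 97.5th percentiles. Because a
sign flip leaves each datapoint's second moment untouched, the permuted
t-maps are computed from the flipped means alone — one matrix product per
batch of permutations. Connected components are labelled in C++ and checked
against an R flood-fill oracle. On sparse montages the neighbour
requirement makes cluster formation rare and the test strongly
conservative; the familywise-error calibration therefore exercises the
plain connected-component mode, while the neighbour rule remains the
default for the 60-channel pipeline it was described for.

**Stratification.** 100 equal-width bins span the pooled range of the
equalized measure; within each bin the larger half is subsampled without
replacement to the smaller count, making the retained per-bin histograms
exactly equal. The peak electrode is re-selected from the retained trials
on each of the (default 100) iterations — the closest reading of the
original procedure — with `reselect_electrode = FALSE` available to fix it
once. The equalized variables are the baseline-averaged 8–13 Hz power and
baseline-averaged instantaneous alpha frequency, each averaged over all
electrodes. Equalizing a *measured* proxy leaves a residual of the true
quantity proportional to the measurement noise; the coupled-variant
validation therefore runs at low noise so that it probes the coupling
logic rather than proxy reliability, and the result object reports the
achieved residual difference.

**Components.** Epochs are filtered at 5–15 Hz, baselines concatenated,
reduced to 20 principal components and unmixed with FastICA
(`ica::icafast`; the published analysis used extended infomax — any ICA
recovering sources up to permutation, sign and scale is acceptable, and
recovery is what the tests assert). ICA treats time samples as
exchangeable observations, so the unmixing is estimated on a deterministic
stride subset of at most `max_ica_samples` samples; activations are always
computed by projecting the full *unfiltered* epochs through the spatial
filters (an identity asserted at machine precision). Per-component trends
use baseline-averaged Hilbert power and instantaneous frequency, Spearman
correlation with trial order, and a trial-order shuffle null (default
10000 shuffles): $z$ standardizes the observed rho by the null's mean and
SD, and $p$ is two-tailed with the $+1$ correction. Classification at
$\alpha = .05$ (uncorrected, per component): both significant = mixed, one
= unique-power / unique-frequency, neither = none. The circular summary
takes each component's angle $\operatorname{atan2}(z_f, z_p)$, tests
non-uniformity with Rayleigh's $z = n\bar R^2$ (Zar's p approximation) and
the centroid against the origin with the circular T² statistic referred to
$F(2, 2n-2)$ via $F = n\,T^2_{circ}$, with BCa bootstrap (1000 resamples)
confidence intervals for the centroid coordinates and a
resultant-length-based circular CI for the mean angle. Equivalent-dipole
anatomical localization is out of scope; all alpha-peaked components enter
classification.

## Validation design and problem sizes

Every stage is validated two ways: against independent oracles (dense-grid
DFT, exhaustive average-rank Spearman, flood-fill clustering, full
$2^n$ sign-flip enumeration, analytic chirps and two-Gaussian spectral
mixtures) and by parameter recovery on generated cohorts. The recovery
suite runs: 500 drift-free cohorts (10 subjects × 8 channels × 20
timepoints × 200 trials, 500 permutations) for familywise-error
calibration; a 20-subject scenario-A cohort (24 channels, 500 trials) for
split-half drift recovery; 10–12-subject scenario-B and coupled cohorts
(20 channels, 400–500 trials, 40 stratification iterations) for the
dissociation tests; twenty 4-subject scenario-C cohorts (16 channels, 400
trials) for the emergent-shift sign test; and fifty single-subject
composite cohorts (24 channels, 700 baseline-only trials, three planted
sources) for ICA recovery and classification. Montage and trial counts are
scaled relative to a full 60-channel, 700–800-trial session while keeping
the planted effect sizes at the session scale; the generator defaults
remain at the full scale. `scripts/acceptance.R` re-runs the same chain
from scratch under a caller-supplied seed and writes the recovered
quantities as JSON.

## Known limitations

* The split-half drift estimator assumes a linear-in-trial drift; for
  strongly curved drifts the ×2 scaling is biased (the polynomial fits
  exist to check curvature, and in this setting quadratic terms add little).
* Spectral peak extraction is argmax-based at 0.1 Hz; for multi-peaked
  spectra it reports the dominant lobe, which is exactly what makes
  scenario C's emergent shift visible, but means "the" peak is undefined
  when lobes tie.
* The circular T² test assumes approximately bivariate-normal trend
  coordinates; with few components the BCa intervals fall back to
  percentile intervals when the acceleration estimate is degenerate.
* Stratification equalizes a measured proxy, so residual true-signal
  differences scale with measurement noise (reported per subject as
  `residual_diff`).
* The ICA stage assumes more channels than effective sources and works on
  statistical independence; two sources with heavily overlapping
  topographies *and* identical spectra will not be separated.
* An oscillator whose jitter distribution straddles a band edge converts a
  frequency drift into an apparent power drift through the filter
  roll-off, and residual unmixing leakage lets a strong neighbouring trend
  bleed weakly into a component's other measure. Both effects inflate
  "mixed" classifications for sources near the band edges — a caveat that
  applies to real recordings as much as to the simulations, and the reason
  the composite validation cohort keeps its sources' jitter ranges inside
  the 8–13 Hz plateau.
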