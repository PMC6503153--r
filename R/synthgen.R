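#' Specification of one synthetic alpha source
#'
#' Describes a neural assembly oscillating at a mean (peak) alpha frequency
#' with optional slow, session-long drifts in that frequency and in its
#' amplitude. Per trial, the oscillation frequency is drawn around the
#' drifting mean with SD \code{bandwidth_hz} (the spontaneous cycle-to-cycle
#' jitter that gives the spectral peak its width), and the amplitude follows
#' a linear ramp scaled by \code{power_drift}.
#'
#' @param centre_freq_hz mean oscillation frequency in Hz, within [8, 13].
#' @param freq_drift_hz signed total frequency change over the session (Hz);
#'   e.g. -0.25 plants a linear slide from \code{centre} at the first trial
#'   to \code{centre - 0.25} at the last.
#' @param base_amplitude oscillation amplitude at the start of the session
#'   (arbitrary units; downstream analyses z-score, so scale is irrelevant).
#' @param power_drift signed fractional amplitude change over the session
#'   (+0.2 = +20 percent at the last trial relative to the first).
#' @param bandwidth_hz SD of the per-trial Gaussian frequency jitter (Hz),
#'   must be > 0 unless a noise-free check is wanted (0 allowed).
#' @param amp_jitter_sd SD of multiplicative log-normal amplitude jitter per
#'   trial (0 = none).
#' @param freq_power_coupling Hz of frequency offset per unit of relative
#'   amplitude fluctuation. When non-zero the per-trial frequency is a
#'   deterministic function of the realized amplitude (fully coupled
#'   frequency/power non-stationarity); the independent jitter is then
#'   disabled.
#' @param quad_freq optional quadratic frequency-drift coefficient: adds
#'   \code{quad_freq * u^2} Hz where u is session progress in [0, 1].
#' @param topography unit-norm channel weight vector, or \code{NULL} to
#'   derive a Gaussian scalp bump from \code{topo_centre}.
#' @param topo_centre channel index at which the Gaussian topography peaks.
#' @param topo_sigma_cm spatial SD of the Gaussian topography (cm).
#' @return object of class \code{source_spec}.
#' @export
source_spec <- function(centre_freq_hz, freq_drift_hz = 0, base_amplitude = 1,
                        power_drift = 0, bandwidth_hz = 0.5,
                        amp_jitter_sd = 0, freq_power_coupling = 0,
                        quad_freq = 0, topography = NULL,
                        topo_centre = 1L, topo_sigma_cm = 4) {
  if (centre_freq_hz < 8 || centre_freq_hz > 13)
    stop("centre_freq_hz must lie within [8, 13]")
  if (bandwidth_hz < 0) stop("bandwidth_hz must be >= 0")
  if (!is.null(topography)) {
    topography <- topography / sqrt(sum(topography^2))
  }
  structure(list(centre_freq_hz = centre_freq_hz,
                 freq_drift_hz = freq_drift_hz,
                 base_amplitude = base_amplitude,
                 power_drift = power_drift,
                 bandwidth_hz = bandwidth_hz,
                 amp_jitter_sd = amp_jitter_sd,
                 freq_power_coupling = freq_power_coupling,
                 quad_freq = quad_freq,
                 topography = topography,
                 topo_centre = as.integer(topo_centre),
                 topo_sigma_cm = topo_sigma_cm),
            class = "source_spec")
}

# Ground-truth drift class implied by the planted parameters.
source_class <- function(spec) {
  f <- spec$freq_drift_hz != 0 || spec$freq_power_coupling != 0
  p <- spec$power_drift != 0
  if (f && p) "mixed"
  else if (p) "unique-power"
  else if (f) "unique-frequency"
  else "stationary"
}

#' Configuration of a synthetic EEG cohort
#'
#' Defines the study conditions for a simulated session: cohort size, trial
#' count, montage, sampling, the alpha sources present and the 1/f background
#' noise. The seed fully determines the generated cohort.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject (>= 2); sessions in the emulated
#'   experiments held 702-800 trials.
#' @param sources list of \code{\link{source_spec}} objects.
#' @param n_channels montage size (default 60).
#' @param fs_hz sampling rate, >= 100 Hz (default 250).
#' @param epoch_span_s epoch limits relative to nominal stimulus onset.
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_amplitude RMS scale of the background noise per channel.
#' @param within_trial_walk_sd SD (Hz/sqrt(sample)) of an optional
#'   within-trial random walk added to the oscillation frequency (0 = the
#'   default constant-frequency-per-trial mode).
#' @param seed integer RNG seed.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects, n_trials, sources, n_channels = 60,
                          fs_hz = 250, epoch_span_s = c(-1, 1),
                          noise_exponent = 1, noise_amplitude = 1,
                          within_trial_walk_sd = 0, seed = 1L) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (fs_hz < 100) stop("fs_hz must be >= 100 Hz")
  for (s in sources) {
    ends <- s$centre_freq_hz + c(0, s$freq_drift_hz + s$quad_freq)
    if (any(ends < 5 | ends > 15))
      stop("source frequency trajectory leaves the 5-15 Hz analysis band")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels), fs_hz = fs_hz,
                 epoch_span_s = epoch_span_s, sources = sources,
                 noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude,
                 within_trial_walk_sd = within_trial_walk_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Gaussian-bump topography over the layout, unit Euclidean norm.
gaussian_topography <- function(layout, centre_channel, sigma_cm = 4) {
  p0 <- as.numeric(layout[centre_channel, c("x", "y", "z")])
  d2 <- (layout$x - p0[1])^2 + (layout$y - p0[2])^2 + (layout$z - p0[3])^2
  w <- exp(-d2 / (2 * sigma_cm^2))
  w / sqrt(sum(w^2))
}

# 1/f ("pink") noise: spectra shaped by f^(-exponent/2), independent per
# column, unit variance per column. Synthesized from complex Gaussian
# spectra with a single inverse FFT at a power-of-2 length (the real part
# of an unconstrained complex-Gaussian spectrum is a real Gaussian process
# with the same power spectral shape).
pink_noise <- function(n_samples, n_series, exponent = 1) {
  nfft <- stats::nextn(n_samples, 2)
  k <- seq_len(nfft - 1)
  f <- c(1, pmin(k, nfft - k))               # |frequency index|, mirrored
  shape <- f^(-exponent / 2)
  shape[1] <- 0                              # remove DC
  spec <- matrix(complex(real = stats::rnorm(nfft * n_series),
                         imaginary = stats::rnorm(nfft * n_series)),
                 nfft, n_series) * shape
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n_samples), ,
                                              drop = FALSE]
  sweep(x, 2, matrixStats::colSds(x), "/")
}

#' Generate one subject's synthetic epochs with planted ground truth
#'
#' Per trial, each source contributes a sinusoid whose frequency equals its
#' (possibly drifting) mean plus Gaussian jitter, and whose amplitude follows
#' the planted ramp; source waveforms are projected through their scalp
#' topographies and summed with 1/f channel noise. The returned ground truth
#' records exactly the per-trial frequency and amplitude trajectories that
#' were planted.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param subject_index subject number (determines the per-subject RNG
#'   stream together with \code{config$seed}).
#' @return list with elements \code{epochs} (an \code{\link{epoch_set}}) and
#'   \code{truth} (list: per-source \code{freq} and \code{amp} trial
#'   trajectories, \code{topography} matrix, \code{class} labels, and
#'   \code{waveform}, the planted noise-free source signals as a
#'   sources x trials x samples array).
#' @export
generate_subject <- function(config, subject_index = 1L) {
  set.seed(derive_seed(config$seed, subject_index))
  fs <- config$fs_hz
  times <- seq(config$epoch_span_s[1], config$epoch_span_s[2] - 1 / fs,
               by = 1 / fs)
  n_sm <- length(times)
  n_tr <- config$n_trials
  n_ch <- config$n_channels
  layout <- default_layout(n_ch)
  n_src <- length(config$sources)

  u <- if (n_tr > 1) (seq_len(n_tr) - 1) / (n_tr - 1) else 0
  freq_traj <- matrix(NA_real_, n_src, n_tr)
  amp_traj <- matrix(NA_real_, n_src, n_tr)
  topo <- matrix(NA_real_, n_ch, n_src)
  labels <- character(n_src)

  data <- array(0, dim = c(n_ch, n_tr, n_sm))
  waves <- array(NA_real_, dim = c(n_src, n_tr, n_sm))
  truth_walk <- NULL
  for (k in seq_len(n_src)) {
    s <- config$sources[[k]]
    labels[k] <- source_class(s)
    topo[, k] <- if (!is.null(s$topography)) s$topography
                 else gaussian_topography(layout, s$topo_centre, s$topo_sigma_cm)
    amp_mean <- s$base_amplitude * (1 + s$power_drift * u)
    amp <- amp_mean *
      if (s$amp_jitter_sd > 0) exp(stats::rnorm(n_tr, 0, s$amp_jitter_sd)) else 1
    f_mean <- s$centre_freq_hz + s$freq_drift_hz * u + s$quad_freq * u^2
    if (s$freq_power_coupling != 0) {
      freq <- f_mean + s$freq_power_coupling * (amp / amp_mean[1] - 1)
    } else {
      freq <- f_mean +
        if (s$bandwidth_hz > 0) stats::rnorm(n_tr, 0, s$bandwidth_hz) else 0
    }
    freq_traj[k, ] <- freq
    amp_traj[k, ] <- amp
    phase0 <- stats::runif(n_tr, 0, 2 * pi)
    if (config$within_trial_walk_sd > 0) {
      dfreq <- matrix(stats::rnorm(n_tr * n_sm, 0, config$within_trial_walk_sd),
                      n_sm, n_tr)
      inst_f <- sweep(apply(dfreq, 2, cumsum), 2, freq, "+")
      if (is.null(truth_walk)) truth_walk <- array(NA_real_, c(n_src, n_tr, n_sm))
      truth_walk[k, , ] <- t(inst_f)
      phase <- 2 * pi * apply(inst_f, 2, cumsum) / fs
      wave <- sin(sweep(phase, 2, phase0, "+"))       # samples x trials
    } else {
      wave <- sin(outer(times - times[1], 2 * pi * freq) +
                    matrix(phase0, n_sm, n_tr, byrow = TRUE))
    }
    wave <- wave * matrix(amp, n_sm, n_tr, byrow = TRUE)
    waves[k, , ] <- t(wave)
    # project: data[ch, tr, sm] += topo[ch] * wave[sm, tr]
    data <- data + outer(topo[, k], t(wave))
  }
  if (config$noise_amplitude > 0) {
    noise <- pink_noise(n_sm, n_tr * n_ch, config$noise_exponent) *
      config$noise_amplitude
    data <- data + aperm(array(noise, c(n_sm, n_tr, n_ch)), c(3, 2, 1))
  }
  epochs <- epoch_set(data, fs = fs, times = times, channels = layout)
  truth <- list(freq = freq_traj, amp = amp_traj, topography = topo,
                class = labels, waveform = waves,
                within_trial_freq = truth_walk)
  list(epochs = epochs, truth = truth)
}

#' Generate a cohort of synthetic subjects
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list of per-subject lists as returned by
#'   \code{\link{generate_subject}}; deterministic under the config seed.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}

#' Preset cohort configurations for the three generative drift scenarios
#'
#' \describe{
#'   \item{A}{a single alpha source that simultaneously increases its power
#'     (+20 percent) and slides its frequency down (-0.25 Hz) over the
#'     session.}
#'   \item{B}{two spatially and spectrally distinct sources with independent
#'     drifts: one shows a unique power increase, the other a unique
#'     frequency decrease.}
#'   \item{C}{two sources with offset centre frequencies (9 and 11 Hz) and
#'     no frequency drift at all; only the lower-frequency source gains
#'     power, so any sensor-level peak-frequency decrease is an emergent
#'     consequence of the changing low/high power ratio.}
#' }
#'
#' @param name one of "A", "B", "C".
#' @param n_subjects,n_trials,n_channels,noise_amplitude,seed overrides of
#'   the cohort-level defaults (20 subjects, 750 trials, 60 channels).
#' @param coupled (scenario A only) if TRUE, the frequency slide is a
#'   deterministic function of the power ramp (fully coupled processes)
#'   rather than an independently jittered drift.
#' @return a \code{\link{cohort_config}}.
#' @export
scenario_preset <- function(name = c("A", "B", "C"), n_subjects = 20,
                            n_trials = 750, n_channels = 60,
                            noise_amplitude = 0.5, seed = 1L,
                            coupled = FALSE) {
  name <- match.arg(name)
  # two distinct scalp sites, scaled to the montage size, plus the spatial
  # nearest neighbour of site 1 (indices along the layout spiral are not
  # spatially adjacent)
  site1 <- max(1L, as.integer(round(0.75 * n_channels)))
  site2 <- max(1L, as.integer(round(0.20 * n_channels)))
  lay <- default_layout(n_channels)
  d1 <- (lay$x - lay$x[site1])^2 + (lay$y - lay$y[site1])^2 +
    (lay$z - lay$z[site1])^2
  d1[site1] <- Inf
  site1_nb <- which.min(d1)
  sources <- switch(name,
    A = list(
      if (coupled)
        # fully coupled: the whole -0.25 Hz slide is induced by the +20%
        # power ramp through the coupling (-1.25 Hz per unit relative
        # amplitude), with no independent frequency drift
        source_spec(10, freq_drift_hz = 0, power_drift = 0.2,
                    bandwidth_hz = 0, amp_jitter_sd = 0.4,
                    freq_power_coupling = -1.25, topo_centre = site1)
      else
        source_spec(10, freq_drift_hz = -0.25, power_drift = 0.2,
                    bandwidth_hz = 0.5, amp_jitter_sd = 0.25,
                    topo_centre = site1)
    ),
    B = list(
      # spectrally adjacent, spatially overlapping processes whose wide
      # jitter merges their spectral lobes into one alpha peak -- as in
      # real recordings -- so the sensor-level apex carries the lower
      # source's power ramp and the upper source's frequency slide at once
      source_spec(9.6, power_drift = 0.3, bandwidth_hz = 0.6,
                  amp_jitter_sd = 0.25, topo_centre = site1),
      source_spec(10.8, base_amplitude = 1.15, freq_drift_hz = -0.3,
                  bandwidth_hz = 0.6, amp_jitter_sd = 0.25,
                  topo_centre = site1_nb)
    ),
    C = list(
      # overlapping generators: both project to the same scalp site, so
      # every electrode sees their weighted spectral sum and the peak can
      # slide with the power ratio alone
      source_spec(9, base_amplitude = 0.75, power_drift = 0.6,
                  bandwidth_hz = 1.0, amp_jitter_sd = 0.25,
                  topo_centre = site1),
      source_spec(11, power_drift = 0, bandwidth_hz = 1.0,
                  amp_jitter_sd = 0.25, topo_centre = site1)
    )
  )
  cohort_config(n_subjects = n_subjects, n_trials = n_trials,
                sources = sources, n_channels = n_channels,
                noise_amplitude = noise_amplitude, seed = seed)
}

#' Write ground truth as a JSON sidecar and trial order as TSV
#'
#' @param subject a list as returned by \code{\link{generate_subject}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_ground_truth <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- subject$truth[setdiff(names(subject$truth),
                                 c("waveform", "within_trial_freq"))]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  utils::write.table(
    data.frame(trial = seq_along(subject$epochs$trial_order),
               order = subject$epochs$trial_order),
    file.path(dir, "trial_order.tsv"), sep = "\t", row.names = FALSE)
  invisible(dir)
}
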