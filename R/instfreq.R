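# --- plateau band-pass filtering -------------------------------------------

# Target amplitude response: exactly 1 on [f1, f2], raised-cosine
# transitions spanning 15% of each band edge (f1*0.85 -> f1 rising,
# f2 -> f2*1.15 falling), exactly 0 elsewhere.
plateau_amplitude <- function(f, band = c(8, 13), transition = 0.15) {
  f1 <- band[1] * (1 - transition)
  f2 <- band[2] * (1 + transition)
  d <- numeric(length(f))
  rise <- f >= f1 & f < band[1]
  fall <- f > band[2] & f <= f2
  d[f >= band[1] & f <= band[2]] <- 1
  d[rise] <- 0.5 * (1 - cos(pi * (f[rise] - f1) / (band[1] - f1)))
  d[fall] <- 0.5 * (1 + cos(pi * (f[fall] - band[2]) / (f2 - band[2])))
  d
}

#' Zero-phase plateau-shaped band-pass filter
#'
#' Filters each column of \code{x} with a plateau-shaped band-pass: the
#' amplitude response is exactly 1 across the passband, falls to 0 over
#' raised-cosine transition zones spanning 15 percent of each band edge
#' (8 Hz edge: 6.8-8 Hz; 13 Hz edge: 13-14.95 Hz), and is exactly 0
#' elsewhere. The filter is realized in the frequency domain with a purely
#' real (zero-phase) transfer function, so the group delay is identically
#' zero and the equivalent impulse response is symmetric -- the same net
#' result a forward-backward two-pass application is designed to achieve,
#' without passband ripple. Epoch edges are extended by odd reflection
#' before transforming to limit boundary transients.
#'
#' @param x numeric vector or samples-by-series matrix.
#' @param fs sampling rate (Hz); must exceed twice the upper transition
#'   edge.
#' @param band passband edges in Hz.
#' @param transition fractional transition-zone width (0.15 = 15 percent of
#'   each edge frequency).
#' @return filtered data, same shape as \code{x}.
#' @export
plateau_bandpass <- function(x, fs, band = c(8, 13), transition = 0.15) {
  if (fs <= 2 * band[2] * (1 + transition))
    stop("sampling rate too low for the requested band")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- min(n - 1L, as.integer(round(fs / 2)))
  top <- 2 * x[rep(1, pad), , drop = FALSE] - x[(pad + 1):2, , drop = FALSE]
  bot <- 2 * x[rep(n, pad), , drop = FALSE] - x[(n - 1):(n - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np, 2)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  freqs <- pmin(freqs, fs - freqs)             # fold to |f|
  H <- plateau_amplitude(freqs, band, transition)
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  out <- y[(pad + 1):(pad + n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Realized amplitude response of the filter at given frequencies (the
# transfer function actually applied is the plateau itself).
plateau_response <- function(fs, freqs, band = c(8, 13), transition = 0.15) {
  plateau_amplitude(freqs, band, transition)
}

# --- instantaneous frequency ------------------------------------------------

#' Instantaneous frequency from the Hilbert phase derivative
#'
#' The analytic signal of each (already band-limited) column is computed via
#' the Hilbert transform; the instantaneous frequency is the first difference
#' of the unwrapped phase angle scaled by \eqn{fs / 2\pi}. Noise-induced
#' spikes are attenuated by a bank of 10 median filters with window lengths
#' linearly spaced from 10 to 400 ms (converted to odd sample counts), whose
#' outputs are combined by a pointwise median.
#'
#' Constant (all-zero) input has undefined phase; such columns are returned
#' as NaN.
#'
#' @param x band-limited vector or samples-by-series matrix (output of
#'   \code{\link{plateau_bandpass}}).
#' @param fs sampling rate (Hz).
#' @param denoise apply the median-filter bank (default TRUE).
#' @return matrix (or vector) of per-sample frequency estimates in Hz, one
#'   sample shorter than the input (forward difference).
#' @export
instantaneous_frequency <- function(x, fs, denoise = TRUE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  z <- analytic_signal(x)
  phi <- unwrap_phase(Arg(z))
  raw <- diff(phi) * fs / (2 * pi)
  bad <- matrixStats::colSds(x) == 0
  if (denoise) {
    wins <- seq(0.010, 0.400, length.out = 10)
    ks <- pmax(3L, as.integer(round(wins * fs) %/% 2L * 2L + 1L))
    n <- nrow(raw)
    ks <- pmin(ks, if (n %% 2 == 1) n else n - 1L)
    out <- median_filter_bank_cpp(raw, ks)
  } else {
    out <- raw
  }
  out[, bad] <- NaN
  if (vec) drop(out) else out
}

#' Epoch-wise instantaneous alpha frequency at 20 ms resolution
#'
#' Per channel and trial: plateau band-pass (8-13 Hz), instantaneous
#' frequency via the Hilbert phase derivative with median-bank denoising,
#' cropping to \code{span}, then averaging within consecutive 20 ms bins so
#' the output time grid matches the sliding time-frequency power.
#'
#' @param epochs an \code{\link{epoch_set}} covering \code{span}.
#' @param band alpha band (Hz).
#' @param span analysed epoch limits in s (default [-1, 1]).
#' @param bin_s output bin width in s (default 0.02).
#' @return list of class \code{instfreq_series}: \code{values_hz} array
#'   channels x trials x bins, \code{times} bin centres (s), \code{fs},
#'   \code{bin_s}.
#' @export
epoch_instfreq <- function(epochs, band = ALPHA_BAND, span = c(-1, 1),
                           bin_s = 0.02) {
  fs <- epochs$fs
  d <- dim(epochs$data)
  if (min(epochs$times) > span[1] + 1e-9 ||
      max(epochs$times) < span[2] - 1 / fs - 1e-9)
    stop("epochs do not cover the requested span")
  n_ch <- d[1]; n_tr <- d[2]; n_sm <- d[3]
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_sm)  # sm x (ch*tr)
  filt <- plateau_bandpass(flat, fs, band)
  if_raw <- instantaneous_frequency(filt, fs)      # (n_sm-1) x (ch*tr)
  # forward difference i -> i+1 assigned to sample i; the final sample is
  # replicated so the bin grid covers the epoch (the last bin touches the
  # epoch edge and is excluded from interior analyses anyway)
  if_raw <- rbind(if_raw, if_raw[nrow(if_raw), , drop = FALSE])
  t_if <- epochs$times
  keep <- t_if >= span[1] - 1e-9 & t_if < span[2] - 1e-9
  if_c <- if_raw[keep, , drop = FALSE]
  tt <- t_if[keep]
  per_bin <- as.integer(round(bin_s * fs))
  n_bins <- nrow(if_c) %/% per_bin
  idx <- seq_len(n_bins * per_bin)
  grp <- rep(seq_len(n_bins), each = per_bin)
  binned <- rowsum(if_c[idx, , drop = FALSE], grp) / per_bin
  times <- rowsum(tt[idx], grp) / per_bin
  vals <- aperm(array(binned, c(n_bins, n_ch, n_tr)), c(2, 3, 1))
  structure(list(values_hz = vals, times = as.numeric(times),
                 fs = fs, bin_s = bin_s),
            class = "instfreq_series")
}

# --- sliding-window time-frequency power ------------------------------------

#' Sliding-window Hanning-taper time-frequency power
#'
#' Decomposes each trial with overlapping 0.5 s segments stepped forward in
#' 20 ms increments; each segment is Hanning-tapered and zero-padded to a
#' 1 Hz frequency grid (1-40 Hz). Power is the squared magnitude of the
#' complex spectra. Only window centres for which the full 0.5 s segment
#' lies inside the epoch are produced.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param freqs frequency grid in Hz (integers 1-40 by default).
#' @param window_s segment length (s).
#' @param step_s hop size (s).
#' @return list of class \code{tf_power}: \code{power} array channels x
#'   trials x freqs x timepoints, \code{freqs_hz}, \code{times} (window
#'   centres, s).
#' @export
timefreq_power <- function(epochs, freqs = 1:40, window_s = 0.5,
                           step_s = 0.02) {
  fs <- epochs$fs
  d <- dim(epochs$data)
  n_ch <- d[1]; n_tr <- d[2]; n_sm <- d[3]
  wlen <- as.integer(round(window_s * fs))
  if (wlen > n_sm) stop("analysis window exceeds the epoch length")
  step <- as.integer(round(step_s * fs))
  starts <- seq(1L, n_sm - wlen + 1L, by = step)
  centres <- epochs$times[starts] + (wlen - 1) / (2 * fs)
  taper <- signal::hanning(wlen)
  nfft <- as.integer(round(fs))                   # 1 Hz resolution
  bins <- as.integer(round(freqs)) + 1L
  out <- array(NA_real_, c(n_ch, n_tr, length(freqs), length(starts)))
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_sm)
  for (w in seq_along(starts)) {
    seg <- flat[starts[w]:(starts[w] + wlen - 1L), , drop = FALSE] * taper
    padded <- rbind(seg, matrix(0, nfft - wlen, ncol(seg)))
    P <- abs(stats::mvfft(padded)[bins, , drop = FALSE])^2
    out[, , , w] <- aperm(array(P, c(length(freqs), n_ch, n_tr)), c(2, 3, 1))
  }
  structure(list(power = out, freqs_hz = freqs, times = centres),
            class = "tf_power")
}
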