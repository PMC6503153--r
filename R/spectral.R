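ALPHA_BAND <- c(8, 13)

# Number of FFT points giving the requested frequency-grid spacing.
nfft_for_resolution <- function(fs, resolution = 0.1) {
  as.integer(round(fs / resolution))
}

# Per-trial, per-channel power spectra of the 1 s baselines.
# Returns array trials x channels x freq within `band`, plus the freq grid.
# Each baseline is Hamming-windowed, zero-padded to a 0.1 Hz grid and
# Fourier transformed; power = squared magnitude.
trial_spectra <- function(epochs, band = c(1, 40), resolution = 0.1) {
  idx <- baseline_samples(epochs)
  fs <- epochs$fs
  if (length(idx) < fs) stop("baseline shorter than 1 s")
  nfft <- nfft_for_resolution(fs, resolution)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  keep <- which(freqs >= band[1] & freqs <= band[2] + 1e-9)
  d <- dim(epochs$data)
  n_ch <- d[1]; n_tr <- d[2]; n_sm <- length(idx)
  w <- signal::hamming(n_sm)
  # samples x (channels*trials), chunked to bound memory
  cols <- n_ch * n_tr
  flat <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(3, 1, 2)),
                 nrow = n_sm)                      # samples x (ch*tr)
  flat <- flat * w
  # zero-padding to nfft only interpolates the DFT onto the fine grid, so
  # the kept bins can be computed directly as a band-restricted DFT
  # (matrix product), which is much cheaper than full-length FFTs
  ang <- outer(freqs[keep], (seq_len(n_sm) - 1) * (-2 * pi / fs))
  out_flat <- (cos(ang) %*% flat)^2 + (sin(ang) %*% flat)^2
  out <- aperm(array(out_flat, c(length(keep), n_ch, n_tr)), c(3, 2, 1))
  list(power = out, freqs = freqs[keep])
}

#' Trial-averaged baseline power spectrum
#'
#' Computes per-channel power spectra of the 1 s pre-stimulus baselines: each
#' baseline is multiplied by a Hamming window, zero-padded to a 0.1 Hz
#' frequency grid, Fourier transformed, converted to power and averaged over
#' the requested trials.
#'
#' @param epochs an \code{\link{epoch_set}} whose time axis covers
#'   \eqn{[-1, 0)} s.
#' @param trials integer vector of trial indices to average (default: all).
#' @param band frequency limits of the returned grid (Hz).
#' @param half_label bookkeeping label ("first", "second" or "all").
#' @return object of class \code{power_spectrum}: list with \code{freqs_hz},
#'   \code{power} (channels x freqs), \code{n_trials}, \code{half},
#'   \code{channels}.
#' @export
baseline_spectrum <- function(epochs, trials = NULL, band = c(1, 40),
                              half_label = "all") {
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[2])
  if (length(trials) == 0) stop("empty trial subset")
  ts <- trial_spectra(epochs, band = band)
  power <- colMeans(ts$power[trials, , , drop = FALSE])
  structure(list(freqs_hz = ts$freqs, power = power,
                 n_trials = length(trials), half = half_label,
                 channels = epochs$channels),
            class = "power_spectrum")
}

# Build a power_spectrum from an already-computed trial_spectra cache.
spectrum_from_cache <- function(cache, trials, channels, half_label = "all") {
  power <- colMeans(cache$power[trials, , , drop = FALSE])
  structure(list(freqs_hz = cache$freqs, power = power,
                 n_trials = length(trials), half = half_label,
                 channels = channels),
            class = "power_spectrum")
}

#' Select the electrode with the highest mean alpha power
#'
#' Mean power over the 8-13 Hz bins (band edges inclusive); ties are broken
#' towards the lowest channel index.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param band alpha band limits in Hz.
#' @return integer channel index (with the channel label as its name).
#' @export
select_peak_electrode <- function(spectrum, band = ALPHA_BAND) {
  bins <- spectrum$freqs_hz >= band[1] - 1e-9 & spectrum$freqs_hz <= band[2] + 1e-9
  m <- rowMeans(spectrum$power[, bins, drop = FALSE])
  i <- which.max(m)                       # which.max takes the first maximum
  names(i) <- spectrum$channels$label[i]
  i
}

#' Extract the alpha peak from one channel of a power spectrum
#'
#' In \code{smoothing = "none"} mode (the split-half analysis) the peak is
#' the raw argmax over the 8-13 Hz bins, band edges inclusive, ties broken
#' towards the lower frequency. In \code{"savitzky_golay"} mode (component
#' selection) the spectrum is first smoothed with an 11-point, 3rd-order
#' Savitzky-Golay filter and a peak is only reported if the smoothed curve
#' has a true local maximum strictly inside the band; monotone spectra (e.g.
#' pure 1/f decay) yield no peak.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param electrode channel index.
#' @param band search band in Hz.
#' @param smoothing "none" or "savitzky_golay".
#' @return list with \code{peak_freq_hz}, \code{peak_power},
#'   \code{electrode} (NA frequencies signal "no peak").
#' @export
extract_alpha_peak <- function(spectrum, electrode, band = ALPHA_BAND,
                               smoothing = c("none", "savitzky_golay")) {
  smoothing <- match.arg(smoothing)
  f <- spectrum$freqs_hz
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9)
    stop("search band outside the spectrum's frequency grid")
  p <- spectrum$power[electrode, ]
  if (smoothing == "savitzky_golay") {
    p <- signal::sgolayfilt(p, p = 3, n = 11)
    closed <- which(f >= band[1] - 1e-9 & f <= band[2] + 1e-9)
    i <- closed[which.max(p[closed])]
    # the in-band maximum must be a true local maximum strictly inside the
    # band; band-edge maxima (e.g. monotone 1/f decay) are rejected
    interior <- i > closed[1] && i < closed[length(closed)] &&
      i > 1 && i < length(p) && p[i] > p[i - 1] && p[i] >= p[i + 1]
    if (!interior)
      return(list(peak_freq_hz = NA_real_, peak_power = NA_real_,
                  electrode = electrode))
  } else {
    inband <- which(f >= band[1] - 1e-9 & f <= band[2] + 1e-9)
    i <- inband[which.max(p[inband])]
  }
  list(peak_freq_hz = f[i], peak_power = p[i], electrode = electrode)
}

# First/second half split of trials by ascending acquisition order;
# odd counts give the extra trial to the first half.
split_half_indices <- function(n_trials) {
  n1 <- ceiling(n_trials / 2)
  list(first = seq_len(n1), second = seq(n1 + 1, n_trials))
}

#' Split-half analysis of peak alpha frequency and power
#'
#' For each subject, trials are split into first and second session halves by
#' acquisition order, one peak electrode is chosen from the all-trials
#' spectrum (highest mean 8-13 Hz power), and the alpha peak frequency and
#' power are extracted from each half's trial-averaged baseline spectrum at
#' that electrode. Group-level paired t-tests (expressed as one-sample tests
#' on the second-minus-first deltas) quantify systematic session-long changes
#' in both measures, and a Spearman correlation relates the per-subject
#' frequency deltas to the power deltas.
#'
#' @param cohort list of \code{\link{epoch_set}} objects (one per subject).
#' @param proportional if TRUE, deltas are proportional changes
#'   \eqn{(second - first)/first} instead of raw differences.
#' @param band alpha band (Hz).
#' @return object of class \code{split_half_result}: per-subject table
#'   (\code{subjects}) and group statistics (\code{freq_t}, \code{freq_p},
#'   \code{freq_d}, \code{power_t}, \code{power_p}, \code{power_d},
#'   \code{dof}, \code{delta_cor_rho}, \code{delta_cor_p}).
#' @export
split_half_analysis <- function(cohort, proportional = FALSE,
                                band = ALPHA_BAND) {
  rows <- lapply(seq_along(cohort), function(si) {
    ep <- cohort[[si]]
    n_tr <- dim(ep$data)[2]
    if (n_tr < 2) stop("each subject needs >= 2 trials")
    cache <- trial_spectra(ep, band = c(5, 18))
    halves <- split_half_indices(n_tr)
    all_spec <- spectrum_from_cache(cache, seq_len(n_tr), ep$channels)
    el <- select_peak_electrode(all_spec, band)
    pk <- lapply(halves, function(tr)
      extract_alpha_peak(spectrum_from_cache(cache, tr, ep$channels),
                         el, band))
    data.frame(subject = si, electrode = unname(el),
               freq_first = pk$first$peak_freq_hz,
               freq_second = pk$second$peak_freq_hz,
               power_first = pk$first$peak_power,
               power_second = pk$second$peak_power)
  })
  tab <- do.call(rbind, rows)
  if (proportional) {
    tab$freq_delta <- (tab$freq_second - tab$freq_first) / tab$freq_first
    tab$power_delta <- (tab$power_second - tab$power_first) / tab$power_first
  } else {
    tab$freq_delta <- tab$freq_second - tab$freq_first
    tab$power_delta <- tab$power_second - tab$power_first
  }
  res <- list(subjects = tab, proportional = proportional)
  if (nrow(tab) >= 2) {
    ft <- safe_one_sample_t(tab$freq_delta)
    pt <- safe_one_sample_t(tab$power_delta)
    res$freq_t <- ft$t; res$freq_p <- ft$p
    res$power_t <- pt$t; res$power_p <- pt$p
    res$freq_d <- ft$d
    res$power_d <- pt$d
    res$dof <- nrow(tab) - 1L
    ct <- tryCatch(suppressWarnings(
      stats::cor.test(tab$freq_delta, tab$power_delta, method = "spearman")),
      error = function(e) list(estimate = NA_real_, p.value = NA_real_))
    res$delta_cor_rho <- unname(ct$estimate); res$delta_cor_p <- ct$p.value
  }
  structure(res, class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("<split_half_result> n = %d subjects%s\n", nrow(x$subjects),
              if (isTRUE(x$proportional)) " (proportional deltas)" else ""))
  if (!is.null(x$freq_t)) {
    cat(sprintf("  peak frequency: mean delta %+.3f Hz, t(%d) = %.3f, p = %.4g, d = %.3f\n",
                mean(x$subjects$freq_delta), x$dof, x$freq_t, x$freq_p, x$freq_d))
    cat(sprintf("  peak power:     mean delta %+.3f,    t(%d) = %.3f, p = %.4g, d = %.3f\n",
                mean(x$subjects$power_delta), x$dof, x$power_t, x$power_p, x$power_d))
    cat(sprintf("  delta correlation: rho = %.3f, p = %.4g\n",
                x$delta_cor_rho, x$delta_cor_p))
  }
  invisible(x)
}

#' Estimate the per-session linear drift from a split-half delta
#'
#' For a measure drifting linearly across the session, the expected
#' difference between the second- and first-half means is half the total
#' session drift, so the method-of-moments estimate of the session drift is
#' twice the split-half delta.
#'
#' @param result a \code{split_half_result}.
#' @param measure "freq" or "power".
#' @return scalar estimated drift over the whole session.
#' @export
session_drift_estimate <- function(result, measure = c("freq", "power")) {
  measure <- match.arg(measure)
  2 * mean(result$subjects[[paste0(measure, "_delta")]])
}

#' Write a split-half result as JSON summary plus per-subject TSV
#'
#' @param result a \code{split_half_result}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_split_half <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$subjects, file.path(dir, "split_half_subjects.tsv"),
                     sep = "\t", row.names = FALSE)
  grp <- result[setdiff(names(result), "subjects")]
  jsonlite::write_json(grp, file.path(dir, "split_half_group.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
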