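#' Histogram-based stratification of two trial sets
#'
#' Equalizes the distribution of a scalar measure between two sets of trials
#' (the histogram method): 100 equal-width bins span the pooled min-max
#' range; within each bin the larger set is randomly subsampled (without
#' replacement) down to the smaller set's count, so the retained per-bin
#' histograms are exactly equal. Matching the bin counts approximately
#' equalizes the mean, variance and higher-order statistics of the two
#' distributions.
#'
#' @param values1,values2 measure values for the trials of each half.
#' @param n_bins number of histogram bins (default 100).
#' @return list with integer index vectors \code{keep1}, \code{keep2}
#'   (positions within each half's own ordering).
#' @export
histogram_stratify <- function(values1, values2, n_bins = 100) {
  if (length(values1) == 0 || length(values2) == 0)
    stop("both halves must be non-empty")
  pooled <- range(c(values1, values2))
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1)
  bin <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE),
                               1L), n_bins)
  b1 <- bin(values1); b2 <- bin(values2)
  keep1 <- integer(0); keep2 <- integer(0)
  for (k in sort(unique(c(b1, b2)))) {
    i1 <- which(b1 == k); i2 <- which(b2 == k)
    m <- min(length(i1), length(i2))
    if (m == 0) next
    keep1 <- c(keep1, if (length(i1) > m) sample(i1, m) else i1)
    keep2 <- c(keep2, if (length(i2) > m) sample(i2, m) else i2)
  }
  if (length(keep1) == 0)
    warning("stratification retained no trials (disjoint supports?)")
  list(keep1 = sort(keep1), keep2 = sort(keep2))
}

#' Per-trial baseline-averaged alpha power and instantaneous frequency
#'
#' The two stratification variables: single-trial alpha (8-13 Hz) baseline
#' power from the trial spectra and single-trial baseline-averaged
#' instantaneous alpha frequency, each averaged over all electrodes.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param band alpha band (Hz).
#' @return list with numeric vectors \code{power} and \code{instfreq}, one
#'   value per trial.
#' @export
baseline_trial_measures <- function(epochs, band = ALPHA_BAND) {
  cache <- trial_spectra(epochs, band = band)
  power <- rowMeans(rowMeans(cache$power, dims = 2))     # mean over freq, ch
  iaf <- epoch_instfreq(epochs, band = band,
                        span = c(max(-1, min(epochs$times)), 0))
  instfreq <- rowMeans(colMeans(iaf$values_hz))          # mean over ch, bins
  list(power = as.numeric(power), instfreq = as.numeric(instfreq))
}

#' Split-half analysis after stratifying away one measure
#'
#' Tests whether the session-long drift of one alpha measure survives when
#' the distribution of the other measure is equalized between the first and
#' second half of the session. Per subject, single-trial baseline-averaged
#' alpha power and instantaneous alpha frequency (averaged over all
#' electrodes) are computed; the chosen measure's first- and second-half
#' distributions are equalized by \code{\link{histogram_stratify}}, and the
#' split-half FFT peak extraction is re-run on the retained trials. Because
#' the subsampling is stochastic, the procedure is repeated \code{n_iter}
#' times and the per-half peak frequency and power are averaged over
#' iterations before the group-level paired t-tests.
#'
#' The peak electrode (highest mean 8-13 Hz power) is re-selected from the
#' retained trials on every iteration; set \code{reselect_electrode = FALSE}
#' to fix it once from all trials.
#'
#' @param cohort list of \code{\link{epoch_set}} objects.
#' @param equalize_on "power" or "instfreq": the measure held constant.
#' @param n_iter stratification iterations (default 100).
#' @param n_bins histogram bins.
#' @param min_retained warn when fewer trials than this remain in a half.
#' @param reselect_electrode see Description.
#' @param seed optional RNG seed.
#' @param measures optional list (one element per subject) of precomputed
#'   \code{baseline_trial_measures} results, to avoid recomputing the
#'   stratification variables when both stratifications are run on the same
#'   cohort.
#' @return object of class \code{stratification_result}: per-subject
#'   iteration-averaged table (\code{subjects}, including retained trial
#'   counts and the achieved residual difference in the equalized measure),
#'   group statistics for both measures, and the retained indices of the
#'   last iteration (\code{retained}).
#' @export
stratified_split_half <- function(cohort, equalize_on = c("power", "instfreq"),
                                  n_iter = 100, n_bins = 100,
                                  min_retained = 20,
                                  reselect_electrode = TRUE, seed = NULL,
                                  measures = NULL) {
  equalize_on <- match.arg(equalize_on)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(cohort))
  retained_last <- vector("list", length(cohort))
  for (si in seq_along(cohort)) {
    ep <- cohort[[si]]
    n_tr <- dim(ep$data)[2]
    halves <- split_half_indices(n_tr)
    meas <- if (is.null(measures)) baseline_trial_measures(ep)
            else measures[[si]]
    v <- meas[[equalize_on]]
    cache <- trial_spectra(ep, band = c(5, 18))
    acc <- matrix(0, n_iter, 6)
    colnames(acc) <- c("freq1", "freq2", "pow1", "pow2", "n1", "n2")
    resid <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      st <- histogram_stratify(v[halves$first], v[halves$second], n_bins)
      t1 <- halves$first[st$keep1]
      t2 <- halves$second[st$keep2]
      if (length(t1) < min_retained || length(t2) < min_retained)
        warning("fewer than ", min_retained, " trials retained for subject ", si)
      resid[it] <- mean(v[t2]) - mean(v[t1])
      el <- if (reselect_electrode || it == 1) {
        select_peak_electrode(spectrum_from_cache(cache, c(t1, t2),
                                                  ep$channels))
      } else el
      p1 <- extract_alpha_peak(spectrum_from_cache(cache, t1, ep$channels), el)
      p2 <- extract_alpha_peak(spectrum_from_cache(cache, t2, ep$channels), el)
      acc[it, ] <- c(p1$peak_freq_hz, p2$peak_freq_hz,
                     p1$peak_power, p2$peak_power,
                     length(t1), length(t2))
      if (it == n_iter) retained_last[[si]] <- list(first = t1, second = t2)
    }
    m <- colMeans(acc)
    rows[[si]] <- data.frame(
      subject = si,
      freq_first = m["freq1"], freq_second = m["freq2"],
      power_first = m["pow1"], power_second = m["pow2"],
      freq_delta = m["freq2"] - m["freq1"],
      power_delta = m["pow2"] - m["pow1"],
      n_retained_first = m["n1"], n_retained_second = m["n2"],
      residual_diff = mean(resid), row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  res <- list(subjects = tab, equalize_on = equalize_on, n_iter = n_iter,
              retained = retained_last)
  if (nrow(tab) >= 2) {
    ft <- safe_one_sample_t(tab$freq_delta)
    pt <- safe_one_sample_t(tab$power_delta)
    res$freq_t <- ft$t; res$freq_p <- ft$p
    res$power_t <- pt$t; res$power_p <- pt$p
    res$dof <- nrow(tab) - 1L
  }
  structure(res, class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<stratification_result> equalized on %s, %d iterations, n = %d subjects\n",
              x$equalize_on, x$n_iter, nrow(x$subjects)))
  cat(sprintf("  retained per half: %.0f (mean)\n",
              mean(c(x$subjects$n_retained_first, x$subjects$n_retained_second))))
  if (!is.null(x$freq_t)) {
    cat(sprintf("  freq delta:  %+.4f Hz, t(%d) = %.3f, p = %.4g\n",
                mean(x$subjects$freq_delta), x$dof, x$freq_t, x$freq_p))
    cat(sprintf("  power delta: %+.4f,    t(%d) = %.3f, p = %.4g\n",
                mean(x$subjects$power_delta), x$dof, x$power_t, x$power_p))
  }
  invisible(x)
}
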