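# --- extraction -------------------------------------------------------------

#' Extract candidate alpha components by PCA + ICA on baseline data
#'
#' Epochs are band-pass filtered at 5-15 Hz, the baseline periods are
#' concatenated across trials, dimensionality is reduced to
#' \code{n_components} by PCA, and an ICA unmixing is estimated on the
#' reduced data (FastICA with a fixed seed). Each component's spatial filter
#' (a weight per channel) is returned, and the \emph{unfiltered} epochs are
#' projected through the filters to obtain per-trial activation time series.
#'
#' @param epochs an \code{\link{epoch_set}} with >= 20 channels.
#' @param n_components number of components (default 20; capped at the
#'   channel count).
#' @param seed RNG seed for the ICA initialisation.
#' @param maxit,tol FastICA iteration controls.
#' @param max_ica_samples upper bound on the number of time samples used to
#'   estimate the PCA/ICA unmixing (a deterministic stride subset is taken
#'   when the concatenated baselines are longer; ICA treats samples as
#'   exchangeable observations, so subsampling only adds estimation noise).
#'   Activations are always computed from all samples.
#' @return list of \code{alpha_component} objects, each with
#'   \code{filter} (channel weights), \code{activation} (trials x samples
#'   of the unfiltered projection), \code{psd} (smoothable baseline
#'   spectrum), \code{freqs_hz}, \code{peak_freq_hz} (NA until selection),
#'   \code{index}.
#' @export
extract_alpha_components <- function(epochs, n_components = 20, seed = 1L,
                                     maxit = 200, tol = 1e-5,
                                     max_ica_samples = 30000) {
  d <- dim(epochs$data)
  n_ch <- d[1]; n_tr <- d[2]
  if (n_ch < 20) stop("component extraction expects >= 20 channels")
  n_components <- min(n_components, n_ch)
  idx <- baseline_samples(epochs)
  # 5-15 Hz band-pass, then concatenate baselines: (tr*len) x ch
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  filt <- plateau_bandpass(flat, epochs$fs, band = c(5, 15))
  filt <- array(filt, c(d[3], n_ch, n_tr))[idx, , , drop = FALSE]
  X <- matrix(aperm(filt, c(1, 3, 2)), ncol = n_ch)     # (len*tr) x ch
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (nrow(Xc) > max_ica_samples) {
    stride <- ceiling(nrow(Xc) / max_ica_samples)
    Xc <- Xc[seq(1L, nrow(Xc), by = stride), , drop = FALSE]
  }
  # PCA reduction
  sv <- svd(Xc, nu = 0, nv = n_components)
  scores <- Xc %*% sv$v
  set.seed(seed)
  ic <- ica::icafast(scores, nc = n_components, maxit = maxit, tol = tol)
  # icafast satisfies scores_centred = S %*% t(M); the unmixing matrix is
  # the pseudoinverse of t(M), giving channel-space spatial filters
  # (rows of W_ch) with activation = X %*% t(W_ch).
  W_un <- ic$M %*% solve(crossprod(ic$M))               # scores -> sources
  W_ch <- t(sv$v %*% W_un)                              # comps x channels
  # activations of the *unfiltered* epochs
  act_flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = n_ch) %*% t(W_ch)
  lapply(seq_len(n_components), function(k) {
    structure(list(filter = W_ch[k, ],
                   activation = t(matrix(act_flat[, k], d[3], n_tr)),
                   index = k, fs = epochs$fs, times = epochs$times,
                   peak_freq_hz = NA_real_),
              class = "alpha_component")
  })
}

# Trial-averaged baseline power spectrum of a component activation
# (Hamming window, zero-padded to 0.1 Hz, as for channel spectra).
component_psd <- function(comp, band = c(2, 30)) {
  bl <- which(comp$times >= -1 & comp$times < 0)
  x <- t(comp$activation[, bl, drop = FALSE])           # samples x trials
  n_sm <- nrow(x)
  nfft <- nfft_for_resolution(comp$fs, 0.1)
  freqs <- (seq_len(nfft) - 1) * comp$fs / nfft
  keep <- which(freqs >= band[1] & freqs <= band[2] + 1e-9)
  w <- signal::hamming(n_sm)
  padded <- rbind(x * w, matrix(0, nfft - n_sm, ncol(x)))
  P <- rowMeans(abs(stats::mvfft(padded)[keep, , drop = FALSE])^2)
  list(freqs_hz = freqs[keep], power = P)
}

#' Keep components with a validated interior alpha peak
#'
#' A candidate is retained when its Savitzky-Golay-smoothed (11-point,
#' 3rd-order) baseline power spectrum exhibits a true local maximum strictly
#' inside 8-13 Hz; components with monotone (e.g. 1/f-only) spectra or
#' band-edge maxima are rejected. The validated peak frequency is stored on
#' the returned components.
#'
#' @param candidates list from \code{\link{extract_alpha_components}}.
#' @param band alpha band (Hz).
#' @return filtered list of \code{alpha_component} objects with
#'   \code{peak_freq_hz} and \code{psd} populated.
#' @export
select_alpha_peaked <- function(candidates, band = ALPHA_BAND) {
  kept <- lapply(candidates, function(comp) {
    psd <- component_psd(comp)
    spec <- structure(list(freqs_hz = psd$freqs_hz,
                           power = matrix(psd$power, nrow = 1),
                           channels = data.frame(label = "comp")),
                      class = "power_spectrum")
    pk <- extract_alpha_peak(spec, 1, band, smoothing = "savitzky_golay")
    if (is.na(pk$peak_freq_hz)) return(NULL)
    comp$peak_freq_hz <- pk$peak_freq_hz
    comp$psd <- psd
    comp
  })
  kept[!vapply(kept, is.null, logical(1))]
}

# --- per-component trend statistics -----------------------------------------

# Per-trial baseline-averaged Hilbert power and Inst-AF of an activation.
component_trial_measures <- function(comp, band = ALPHA_BAND) {
  x <- t(comp$activation)                               # samples x trials
  filt <- plateau_bandpass(x, comp$fs, band)
  z <- analytic_signal(filt)
  bl <- which(comp$times >= -1 & comp$times < 0)
  power <- colMeans(abs(z[bl, , drop = FALSE])^2)
  instf <- instantaneous_frequency(filt, comp$fs)
  bl_if <- bl[bl < nrow(instf)]
  instfreq <- colMeans(instf[bl_if, , drop = FALSE])
  list(power = power, instfreq = instfreq)
}

#' Time-on-task trend of one component with a permutation null
#'
#' Computes, per trial, the baseline-averaged Hilbert power (squared
#' magnitude of the analytic signal of the 8-13 Hz-filtered activation) and
#' the baseline-averaged instantaneous alpha frequency; correlates each with
#' trial order (Spearman); and refers the observed rho values to a null
#' distribution obtained from random shuffles of the trial order. z is the
#' observed rho standardized by the null's mean and SD; p uses the +1
#' correction, two-tailed.
#'
#' @param comp an \code{alpha_component}.
#' @param trial_order acquisition positions (default 1..N).
#' @param n_shuffles permutation count (default 10000).
#' @param seed optional RNG seed.
#' @return list of class \code{component_trend}: \code{power_rho},
#'   \code{power_z}, \code{power_p}, \code{freq_rho}, \code{freq_z},
#'   \code{freq_p}, \code{peak_freq_hz}, \code{n_shuffles}.
#' @export
component_trend <- function(comp, trial_order = NULL, n_shuffles = 10000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meas <- component_trial_measures(comp)
  n <- length(meas$power)
  if (n < 10) stop("need at least 10 trials for the trend permutation test")
  if (is.null(trial_order)) trial_order <- seq_len(n)
  if (stats::sd(meas$power) == 0) stop("constant activation")
  ro <- rank(trial_order); ro <- (ro - mean(ro)) / stats::sd(ro)
  one <- function(v) {
    rv <- rank(v); rv <- (rv - mean(rv)) / stats::sd(rv)
    rho <- sum(rv * ro) / (n - 1)
    # permuted trial orders: permuting ro against fixed rv
    perm <- matrix(ro[vapply(seq_len(n_shuffles), function(i) sample.int(n),
                             integer(n))], n, n_shuffles)
    null <- as.numeric(crossprod(perm, rv)) / (n - 1)
    z <- (rho - mean(null)) / stats::sd(null)
    p <- (sum(abs(null) >= abs(rho) - 1e-12) + 1) / (n_shuffles + 1)
    list(rho = rho, z = z, p = p)
  }
  pw <- one(meas$power)
  fq <- one(meas$instfreq)
  structure(list(power_rho = pw$rho, power_z = pw$z, power_p = pw$p,
                 freq_rho = fq$rho, freq_z = fq$z, freq_p = fq$p,
                 peak_freq_hz = comp$peak_freq_hz,
                 n_shuffles = n_shuffles),
            class = "component_trend")
}

#' Classify component trends into mixed / unique drift types
#'
#' mixed: both power and frequency permutation p below \code{alpha};
#' unique-power / unique-frequency: only the respective p below
#' \code{alpha}; none: neither.
#'
#' @param trends list of \code{component_trend} objects (or a data.frame
#'   with \code{power_p} and \code{freq_p} columns).
#' @param alpha per-component significance level (default 0.05,
#'   uncorrected).
#' @return data.frame with one row per component: rho/z/p for both
#'   measures, \code{peak_freq_hz}, \code{label}, \code{angle_deg}
#'   (atan2 of frequency z over power z, degrees in [0, 360)).
#' @export
classify_components <- function(trends, alpha = 0.05) {
  if (is.data.frame(trends)) {
    tab <- trends
  } else {
    tab <- do.call(rbind, lapply(trends, function(tr)
      data.frame(power_rho = tr$power_rho, power_z = tr$power_z,
                 power_p = tr$power_p, freq_rho = tr$freq_rho,
                 freq_z = tr$freq_z, freq_p = tr$freq_p,
                 peak_freq_hz = tr$peak_freq_hz)))
  }
  sig_p <- tab$power_p < alpha
  sig_f <- tab$freq_p < alpha
  tab$label <- ifelse(sig_p & sig_f, "mixed",
                ifelse(sig_p, "unique-power",
                 ifelse(sig_f, "unique-frequency", "none")))
  ang <- atan2(tab$freq_z, tab$power_z) * 180 / pi
  tab$angle_deg <- (ang + 360) %% 360
  tab
}

# --- circular statistics ----------------------------------------------------

#' Circular and bivariate summary of component trend directions
#'
#' Each component contributes a point (power z, frequency z); its direction
#' is the phase angle of the surrogate complex number power_z + i freq_z.
#' The angle distribution is tested for non-uniformity with a Rayleigh test
#' (z = n R-bar^2 with the standard large-sample p approximation), the
#' bivariate centroid is tested against the origin with the circular
#' T-squared test (statistic referred to F with (2, 2n-2) dof), and BCa
#' bootstrap confidence intervals (1000 resamples) are computed for the two
#' centroid coordinates, together with the resultant-length-based circular
#' confidence interval of the mean angle.
#'
#' @param trends data.frame from \code{\link{classify_components}} (columns
#'   \code{power_z}, \code{freq_z}).
#' @param n_boot bootstrap resamples (default 1000; 0 skips the bootstrap
#'   CIs).
#' @param conf confidence level.
#' @param seed optional RNG seed for the bootstrap.
#' @return list of class \code{circular_summary}: \code{mean_angle_deg},
#'   \code{resultant_length}, \code{angle_ci_deg}, \code{rayleigh_z},
#'   \code{rayleigh_p}, \code{t2circ}, \code{t2circ_F}, \code{t2circ_dof},
#'   \code{t2circ_p}, \code{centroid}, \code{centroid_ci} (2x2: rows
#'   power/frequency), \code{n}.
#' @export
circular_summary <- function(trends, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  x <- trends$power_z; y <- trends$freq_z
  n <- length(x)
  if (n < 3) stop("need at least 3 components")
  if (!is.null(seed)) set.seed(seed)
  theta <- atan2(y, x)
  C <- mean(cos(theta)); S <- mean(sin(theta))
  Rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  rz <- n * Rbar^2
  # Zar's approximation to the Rayleigh p-value
  rp <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * Rbar)^2)) - (1 + 2 * n))
  rp <- min(1, rp)
  # circular CI of the mean angle (resultant-length based normal approx)
  sigma <- sqrt(-2 * log(Rbar)) / sqrt(n)
  half <- stats::qnorm(1 - (1 - conf) / 2) * sigma
  # T2circ: centroid of the bivariate points vs the origin
  zx <- mean(x); zy <- mean(y)
  ss <- sum((x - zx)^2 + (y - zy)^2)
  t2 <- (n - 1) * (zx^2 + zy^2) / ss
  Fstat <- n * t2
  t2p <- stats::pf(Fstat, 2, 2 * n - 2, lower.tail = FALSE)
  centroid_ci <- NULL
  if (n_boot > 0) {
    bca <- function(v) {
      bt <- boot::boot(v, function(d, i) mean(d[i]), R = n_boot)
      suppressWarnings(tryCatch(
        boot::boot.ci(bt, conf = conf, type = "bca")$bca[1, 4:5],
        error = function(e)
          stats::quantile(bt$t, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)))
    }
    centroid_ci <- rbind(power = bca(x), frequency = bca(y))
    colnames(centroid_ci) <- c("lower", "upper")
  }
  structure(list(mean_angle_deg = (mu * 180 / pi + 360) %% 360,
                 resultant_length = Rbar,
                 angle_ci_deg = half * 180 / pi,
                 rayleigh_z = rz, rayleigh_p = rp,
                 t2circ = t2, t2circ_F = Fstat,
                 t2circ_dof = c(2, 2 * n - 2), t2circ_p = t2p,
                 centroid = c(power = zx, frequency = zy),
                 centroid_ci = centroid_ci, n = n),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary> n = %d components\n", x$n))
  cat(sprintf("  mean angle %.2f deg +/- %.2f, R-bar = %.3f, Rayleigh z = %.3f, p = %.3g\n",
              x$mean_angle_deg, x$angle_ci_deg, x$resultant_length,
              x$rayleigh_z, x$rayleigh_p))
  cat(sprintf("  T2circ(%d,%d) = %.4f, p = %.3g; centroid (%.3f, %.3f)\n",
              x$t2circ_dof[1], x$t2circ_dof[2], x$t2circ, x$t2circ_p,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

# --- spectral comparison of component classes -------------------------------

#' Compare peak alpha frequencies between component classes
#'
#' Independent two-sample t-tests of the validated peak frequencies between
#' the mixed, unique-frequency and unique-power classes.
#'
#' @param classified data.frame from \code{\link{classify_components}}.
#' @return data.frame with one row per class pair: group means, t, dof, p.
#' @export
compare_class_peak_frequencies <- function(classified) {
  pairs <- list(c("mixed", "unique-frequency"),
                c("mixed", "unique-power"),
                c("unique-frequency", "unique-power"))
  rows <- lapply(pairs, function(pr) {
    a <- classified$peak_freq_hz[classified$label == pr[1]]
    b <- classified$peak_freq_hz[classified$label == pr[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    if (stats::sd(c(a, b)) == 0) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(class1 = pr[1], class2 = pr[2],
               mean1 = mean(a), mean2 = mean(b),
               n1 = length(a), n2 = length(b),
               t = unname(tt$statistic), dof = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class1 = character(), class2 = character(),
                      mean1 = numeric(), mean2 = numeric(),
                      n1 = integer(), n2 = integer(), t = numeric(),
                      dof = numeric(), p = numeric())
  out
}

#' Write classified component trends as TSV plus circular-summary JSON
#'
#' @param classified data.frame from \code{\link{classify_components}}.
#' @param summary optional \code{circular_summary}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_component_trends <- function(classified, summary = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(classified, file.path(dir, "component_trends.tsv"),
                     sep = "\t", row.names = FALSE)
  if (!is.null(summary))
    jsonlite::write_json(unclass(summary),
                         file.path(dir, "circular_summary.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
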