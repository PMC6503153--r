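#' @useDynLib alphadrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Analytic signal of every column of a real matrix via the frequency-domain
# Hilbert transform (positive frequencies doubled, negative zeroed).
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

# Phase unwrapping along columns (2*pi jumps removed).
unwrap_phase <- function(phi) {
  phi <- as.matrix(phi)
  if (nrow(phi) < 2) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cum <- apply(d, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  rbind(phi[1, , drop = FALSE],
        sweep(cum, 2, phi[1, ], "+"))
}

# Column z-score (population of the supplied values).
zscore <- function(x) {
  (x - mean(x)) / stats::sd(x)
}

#' Spearman rank correlation against an exhaustive rank-based definition
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks.
#' Used throughout the trend analyses; kept separate from
#' \code{stats::cor(..., method = "spearman")} so tests can compare the two.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar rho.
#' @keywords internal
spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# One-sample t-test that tolerates zero-variance input (degenerate deltas
# occur e.g. when both halves hold identical trials); returns t, p and the
# paired Cohen's d (mean / SD).
safe_one_sample_t <- function(v) {
  if (stats::sd(v) == 0)
    return(list(t = NA_real_, p = NA_real_, d = NA_real_))
  tt <- stats::t.test(v)
  list(t = unname(tt$statistic), p = tt$p.value, d = mean(v) / stats::sd(v))
}

# Derive a child RNG seed (< 2^31) from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}
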