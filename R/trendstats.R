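# --- frequency-power relationship (two-line solution) -----------------------

#' Two-line test for an inverted-U relationship
#'
#' Fits, per subject, ordinary least-squares regressions of \code{y} on
#' \code{x} separately for predictor values below and above zero (the
#' variables are expected to be z-scored within subject, so zero is the
#' subject mean). Group-level one-sample t-tests on the two slope sets
#' decide the verdict: an inverted U requires a significantly positive low
#' segment and a significantly negative high segment; two significant slopes
#' of the same sign indicate a monotonic relationship.
#'
#' @param x,y numeric vectors (z-scored predictor and outcome).
#' @param subject subject id per pair.
#' @param alpha significance level for the verdict.
#' @return list of class \code{two_line_result}: per-subject \code{slopes}
#'   data.frame, group statistics \code{low_t}, \code{low_p}, \code{high_t},
#'   \code{high_p}, \code{dof}, and \code{verdict}.
#' @export
two_line_test <- function(x, y, subject, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  per <- lapply(split(seq_along(x), subject), function(i) {
    lo <- i[x[i] < 0]; hi <- i[x[i] > 0]
    if (length(lo) < 2 || length(hi) < 2)
      stop("a subject has no samples on one side of zero")
    c(low = stats::cov(x[lo], y[lo]) / stats::var(x[lo]),
      high = stats::cov(x[hi], y[hi]) / stats::var(x[hi]))
  })
  slopes <- do.call(rbind, per)
  lt <- stats::t.test(slopes[, "low"])
  ht <- stats::t.test(slopes[, "high"])
  sig_lo <- lt$p.value < alpha; sig_hi <- ht$p.value < alpha
  m_lo <- mean(slopes[, "low"]); m_hi <- mean(slopes[, "high"])
  verdict <- if (sig_lo && sig_hi && m_lo > 0 && m_hi < 0) "inverted-U"
    else if (sig_lo && sig_hi && m_lo < 0 && m_hi < 0) "monotonic-negative"
    else if (sig_lo && sig_hi && m_lo > 0 && m_hi > 0) "monotonic-positive"
    else "inconclusive"
  structure(list(slopes = as.data.frame(slopes),
                 low_t = unname(lt$statistic), low_p = lt$p.value,
                 high_t = unname(ht$statistic), high_p = ht$p.value,
                 dof = nrow(slopes) - 1, verdict = verdict),
            class = "two_line_result")
}

# --- Spearman trend maps ----------------------------------------------------

#' Spearman correlation of a measure with trial order, per channel/timepoint
#'
#' @param measure numeric array trials x channels x timepoints (or a
#'   trials x datapoints matrix).
#' @param trial_order acquisition positions (default 1..N).
#' @return matrix channels x timepoints (or vector) of Spearman rho;
#'   datapoints with a constant measure are NA.
#' @export
trial_order_rho <- function(measure, trial_order = NULL) {
  d <- dim(measure)
  if (is.null(d) || length(d) == 1) measure <- matrix(measure, ncol = 1)
  out_dims <- NULL
  if (length(dim(measure)) == 3) {
    out_dims <- dim(measure)[2:3]
    measure <- matrix(measure, nrow = dim(measure)[1])
  }
  n <- nrow(measure)
  if (n < 3) stop("need at least 3 trials")
  if (is.null(trial_order)) trial_order <- seq_len(n)
  ro <- rank(trial_order)
  ro <- (ro - mean(ro)) / stats::sd(ro)
  rk <- matrixStats::colRanks(measure, ties.method = "average",
                              preserveShape = TRUE)
  sds <- matrixStats::colSds(rk)
  rk <- sweep(rk, 2, colMeans(rk), "-")
  rho <- as.numeric(crossprod(rk, ro)) / (n - 1) / sds
  rho[sds == 0] <- NA_real_
  if (!is.null(out_dims)) matrix(rho, out_dims[1], out_dims[2]) else rho
}

#' Channel neighbourhood from electrode positions
#'
#' Two electrodes are neighbours when their Euclidean distance is at most
#' \code{cutoff_cm}. The relation is symmetric and never includes the
#' electrode itself.
#'
#' @param layout data.frame with columns \code{x}, \code{y}, \code{z} (cm)
#'   and optionally \code{label}.
#' @param cutoff_cm distance cutoff (default 5 cm).
#' @return object of class \code{neighbourhood}: logical adjacency
#'   \code{matrix}, per-channel index \code{list}, \code{labels}.
#' @export
build_neighbourhood <- function(layout, cutoff_cm = 5) {
  if (anyNA(layout[, c("x", "y", "z")])) stop("channel positions missing")
  pos <- as.matrix(layout[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  adj <- d <= cutoff_cm
  diag(adj) <- FALSE
  structure(list(matrix = adj,
                 list = lapply(seq_len(nrow(adj)), function(i) which(adj[i, ])),
                 labels = if ("label" %in% names(layout)) layout$label
                          else sprintf("ch%02d", seq_len(nrow(adj)))),
            class = "neighbourhood")
}

#' @export
print.neighbourhood <- function(x, ...) {
  cnt <- rowSums(x$matrix)
  cat(sprintf("<neighbourhood> %d channels, neighbours: mean %.1f, median %g, range [%d, %d]\n",
              nrow(x$matrix), mean(cnt), stats::median(cnt), min(cnt), max(cnt)))
  invisible(x)
}

# One-sample t-map of rho values across subjects (rows of R, one column per
# datapoint); returns list(t, n).
group_t_map <- function(R) {
  n <- nrow(R)
  m <- colMeans(R)
  v <- (colMeans(R^2) - m^2) * n / (n - 1)
  list(t = m / sqrt(v / n), n = n)
}

#' Spatio-temporal cluster-based permutation test on trend maps
#'
#' One-sample t-tests of per-subject Spearman rho maps against zero at every
#' channel/timepoint; samples exceeding the uncorrected two-tailed
#' \code{cluster_alpha} threshold are grouped into spatio-temporally
#' contiguous clusters (separately for positive and negative t), and each
#' cluster's summed t is compared with a null distribution built by flipping
#' the sign of whole subjects' rho maps. Per permutation the most extreme
#' positive and negative cluster masses are retained; a cluster is
#' significant when it is more extreme than the 97.5th percentile of its
#' sign's null (two-tailed 5 percent level, with the +1 small-sample p-value
#' correction).
#'
#' Following the published procedure, a suprathreshold sample additionally
#' needs at least one suprathreshold neighbour in space and one in time to
#' enter a cluster (\code{require_neighbours = TRUE}); set it to FALSE for
#' plain maximal connected components.
#'
#' @param rho array subjects x channels x timepoints of Spearman rho.
#' @param neighbourhood a \code{\link{build_neighbourhood}} result.
#' @param n_perm number of sign-flip permutations.
#' @param cluster_alpha uncorrected threshold for cluster membership.
#' @param test_alpha familywise two-tailed level for cluster significance.
#' @param require_neighbours see Description.
#' @param seed optional RNG seed for the permutations.
#' @return object of class \code{trend_result}: \code{t_map}, signed cluster
#'   \code{labels} (positive ids for positive clusters, negative for
#'   negative), \code{clusters} data.frame (id, sign, mass, n_samples, p,
#'   significant), null distributions and \code{n_perm}.
#' @export
cluster_permutation <- function(rho, neighbourhood, n_perm = 2000,
                                cluster_alpha = 0.05, test_alpha = 0.05,
                                require_neighbours = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(length(dim(rho)) == 3)
  n <- dim(rho)[1]; nch <- dim(rho)[2]; nt <- dim(rho)[3]
  if (n < 2) stop("group test undefined for fewer than 2 subjects")
  if (nch != nrow(neighbourhood$matrix))
    stop("neighbourhood does not match the channel dimension")
  R <- matrix(rho, n, nch * nt)
  if (anyNA(R)) stop("rho contains NA (constant measure at some datapoint)")
  tcrit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  obs <- group_t_map(R)
  tmap <- matrix(obs$t, nch, nt)

  lab_pos <- cluster_label_cpp(tmap > tcrit, neighbourhood$list,
                               require_neighbours)
  lab_neg <- cluster_label_cpp(tmap < -tcrit, neighbourhood$list,
                               require_neighbours)
  masses <- function(lab) {
    ids <- sort(unique(lab[lab > 0]))
    vapply(ids, function(k) sum(tmap[lab == k]), numeric(1))
  }
  mass_pos <- masses(lab_pos); mass_neg <- masses(lab_neg)

  # sign-flip null: per-point mean under flips; second moment is invariant
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  msq <- colMeans(R^2)
  pm <- S %*% R / n
  pv <- sweep(-pm^2, 2, msq, "+") * n / (n - 1)
  pt_all <- pm / sqrt(pv / n)
  null_pos <- numeric(n_perm); null_neg <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    mm <- max_cluster_masses_cpp(matrix(pt_all[i, ], nch, nt), tcrit,
                                 neighbourhood$list, require_neighbours)
    null_pos[i] <- mm[1]; null_neg[i] <- mm[2]
  }
  p_pos <- vapply(mass_pos, function(m) (sum(null_pos >= m) + 1) / (n_perm + 1),
                  numeric(1))
  p_neg <- vapply(mass_neg, function(m) (sum(null_neg <= m) + 1) / (n_perm + 1),
                  numeric(1))
  clusters <- rbind(
    if (length(mass_pos))
      data.frame(id = seq_along(mass_pos), sign = "positive", mass = mass_pos,
                 n_samples = tabulate(lab_pos[lab_pos > 0], max(lab_pos)),
                 p = p_pos),
    if (length(mass_neg))
      data.frame(id = -seq_along(mass_neg), sign = "negative", mass = mass_neg,
                 n_samples = tabulate(lab_neg[lab_neg > 0], max(lab_neg)),
                 p = p_neg)
  )
  if (is.null(clusters))
    clusters <- data.frame(id = integer(), sign = character(),
                           mass = numeric(), n_samples = integer(),
                           p = numeric())
  clusters$significant <- clusters$p <= test_alpha / 2
  labels <- lab_pos
  labels[lab_neg > 0] <- -lab_neg[lab_neg > 0]
  structure(list(t_map = tmap, labels = labels, clusters = clusters,
                 null_pos = null_pos, null_neg = null_neg,
                 n_perm = n_perm, n_subjects = n, tcrit = tcrit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %d subjects, %d x %d map, %d permutations\n",
              x$n_subjects, nrow(x$t_map), ncol(x$t_map), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Write a trend result as long-format TSV plus JSON summary
#'
#' @param result a \code{trend_result}.
#' @param dir output directory.
#' @param times optional timepoint axis for the TSV.
#' @return \code{dir}, invisibly.
#' @export
write_trend_result <- function(result, dir, times = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- nrow(result$t_map); nt <- ncol(result$t_map)
  long <- data.frame(channel = rep(seq_len(nch), nt),
                     time = rep(if (is.null(times)) seq_len(nt) else times,
                                each = nch),
                     t = as.numeric(result$t_map),
                     cluster_id = as.integer(result$labels))
  utils::write.table(long, file.path(dir, "trend_map.tsv"), sep = "\t",
                     row.names = FALSE)
  jsonlite::write_json(list(clusters = result$clusters,
                            n_perm = result$n_perm,
                            n_subjects = result$n_subjects),
                       file.path(dir, "trend_summary.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}

# --- polynomial trend fits --------------------------------------------------

#' Polynomial fits of a pooled trend with coefficient confidence intervals
#'
#' Least-squares fits of degree 1..\code{max_degree} of a (typically
#' z-scored) measure against trial number. A degree is "supported" when the
#' 95 percent confidence interval of its highest-order coefficient excludes
#' zero. The predictor is centred and scaled internally for numerical
#' conditioning; support decisions and adjusted R-squared are invariant to
#' that rescaling.
#'
#' @param y response values.
#' @param trial trial numbers.
#' @param max_degree highest polynomial degree fitted (default 3).
#' @param level confidence level for the coefficient intervals.
#' @return object of class \code{poly_trend_fit}: per-degree list with
#'   \code{coefficients}, \code{ci}, \code{adj_r_squared}, \code{supported}.
#' @export
poly_trend_fit <- function(y, trial, max_degree = 3, level = 0.95) {
  if (length(y) < max_degree + 2) stop("too few points for the requested degree")
  x <- as.numeric(scale(trial))
  fits <- lapply(seq_len(max_degree), function(d) {
    X <- stats::poly(x, degree = d, raw = TRUE)
    fit <- stats::lm(y ~ X)
    if (any(is.na(stats::coef(fit)))) stop("rank-deficient polynomial fit")
    ci <- stats::confint(fit, level = level)
    rownames(ci) <- names(stats::coef(fit))
    top <- nrow(ci)
    list(degree = d,
         coefficients = unname(stats::coef(fit)),
         ci = unname(ci),
         adj_r_squared = summary(fit)$adj.r.squared,
         supported = ci[top, 1] > 0 || ci[top, 2] < 0)
  })
  structure(list(fits = fits, max_degree = max_degree, level = level),
            class = "poly_trend_fit")
}

#' @export
print.poly_trend_fit <- function(x, ...) {
  for (f in x$fits)
    cat(sprintf("  degree %d: adj R^2 = %.4f, top coefficient CI [%.4g, %.4g]%s\n",
                f$degree, f$adj_r_squared, f$ci[nrow(f$ci), 1],
                f$ci[nrow(f$ci), 2], if (f$supported) " *" else ""))
  invisible(x)
}

# --- paired frequency/power samples -----------------------------------------

#' Paired, z-scored instantaneous-frequency and alpha-power samples
#'
#' Computes instantaneous alpha frequency and sliding-window alpha power
#' (mean over the 8-13 Hz bins) on a shared 20 ms grid within the baseline,
#' then z-scores each variable within the subject across all retained
#' datapoints, trials and electrodes. With \code{level = "baseline"}, values
#' are first averaged over each trial's baseline before z-scoring (one pair
#' per trial and electrode).
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param level "pointwise" (20 ms resolution) or "baseline"
#'   (baseline-averaged per trial).
#' @param band alpha band (Hz).
#' @return data.frame with columns \code{x} (Inst-AF z), \code{y} (power z),
#'   \code{trial}, \code{channel} and, for pointwise pairs, \code{time}.
#' @export
frequency_power_pairs <- function(epochs, level = c("pointwise", "baseline"),
                                  band = ALPHA_BAND) {
  level <- match.arg(level)
  iaf <- epoch_instfreq(epochs, band = band,
                        span = c(max(-1, min(epochs$times)), 0))
  tfp <- timefreq_power(epochs, freqs = seq(band[1], band[2]))
  apw <- apply(tfp$power, c(1, 2, 4), mean)        # ch x tr x time
  # align the two 20 ms grids on shared baseline bin times
  ti <- round(iaf$times, 3); tp <- round(tfp$times, 3)
  common <- intersect(ti, tp)
  common <- common[common < 0]
  ii <- match(common, ti); ip <- match(common, tp)
  f <- iaf$values_hz[, , ii, drop = FALSE]
  p <- apw[, , ip, drop = FALSE]
  d <- dim(f)
  if (level == "baseline") {
    f <- apply(f, c(1, 2), mean)
    p <- apply(p, c(1, 2), mean)
    df <- data.frame(x = zscore(as.numeric(f)), y = zscore(as.numeric(p)),
                     channel = rep(seq_len(d[1]), d[2]),
                     trial = rep(seq_len(d[2]), each = d[1]))
  } else {
    df <- data.frame(x = zscore(as.numeric(f)), y = zscore(as.numeric(p)),
                     channel = rep(seq_len(d[1]), d[2] * d[3]),
                     trial = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
                     time = rep(common, each = d[1] * d[2]))
  }
  df
}
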