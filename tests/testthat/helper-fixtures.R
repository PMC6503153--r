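# Shared fixtures, built in code at test time.

FS <- 250

# epoch_set holding the same per-trial waveforms in every channel
sine_epochs <- function(freqs_by_trial, n_channels = 1, fs = FS,
                        span = c(-1, 1), amp = 1) {
  times <- seq(span[1], span[2] - 1 / fs, by = 1 / fs)
  n_tr <- length(freqs_by_trial)
  if (length(amp) == 1) amp <- rep(amp, n_tr)
  data <- array(NA_real_, c(n_channels, n_tr, length(times)))
  for (tr in seq_len(n_tr)) {
    w <- amp[tr] * sin(2 * pi * freqs_by_trial[tr] * (times - times[1]))
    for (ch in seq_len(n_channels)) data[ch, tr, ] <- w
  }
  epoch_set(data, fs, times)
}

# 1-D chain of electrodes 4 cm apart (each interior channel has 2
# spatial neighbours at the 5 cm cutoff)
chain_layout <- function(n = 8) {
  data.frame(label = sprintf("c%d", seq_len(n)), x = 4 * (seq_len(n) - 1),
             y = 0, z = 0)
}

# per-subject Spearman rho maps for a drift-free measure
null_rho_cohort <- function(n_subj, n_ch, n_t, n_tr) {
  rho <- array(NA_real_, c(n_subj, n_ch, n_t))
  for (s in seq_len(n_subj)) {
    m <- array(stats::rnorm(n_tr * n_ch * n_t), c(n_tr, n_ch, n_t))
    rho[s, , ] <- trial_order_rho(m)
  }
  rho
}

# brute-force Spearman rho: average ranks computed by enumeration
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# flood-fill connected components over spatial (same time) + temporal
# (same channel) adjacency; reference for the C++ labelling
oracle_flood_fill <- function(mask, adj_list) {
  nch <- nrow(mask); nt <- ncol(mask)
  lab <- matrix(0L, nch, nt)
  nxt <- 0L
  for (c0 in seq_len(nch)) for (t0 in seq_len(nt)) {
    if (!mask[c0, t0] || lab[c0, t0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(c0, t0)); lab[c0, t0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cc <- cur[1]; tt <- cur[2]
      cand <- rbind(
        if (length(adj_list[[cc]])) cbind(adj_list[[cc]], tt),
        if (tt > 1) c(cc, tt - 1),
        if (tt < nt) c(cc, tt + 1))
      for (r in seq_len(NROW(cand))) {
        c2 <- cand[r, 1]; t2 <- cand[r, 2]
        if (mask[c2, t2] && lab[c2, t2] == 0L) {
          lab[c2, t2] <- nxt
          queue[[length(queue) + 1]] <- c(c2, t2)
        }
      }
    }
  }
  lab
}

# composite cohort config: one mixed, one unique-power and one
# unique-frequency source with distinct scalp sites and centre frequencies
composite_config <- function(n_trials = 700, n_channels = 24, seed = 1,
                             noise_amplitude = 0.2) {
  cohort_config(
    n_subjects = 1, n_trials = n_trials, n_channels = n_channels,
    epoch_span_s = c(-1, 0), noise_amplitude = noise_amplitude, seed = seed,
    sources = list(
      source_spec(9, freq_drift_hz = -0.3, power_drift = 0.3,
                  bandwidth_hz = 0.35, amp_jitter_sd = 0.2,
                  topo_centre = 18L),
      source_spec(10.5, power_drift = 0.3, bandwidth_hz = 0.35,
                  amp_jitter_sd = 0.2, topo_centre = 5L),
      source_spec(11.8, freq_drift_hz = -0.3, bandwidth_hz = 0.35,
                  amp_jitter_sd = 0.2, topo_centre = 11L)))
}

# greedy matching of selected components to planted sources on the
# 5-15 Hz filtered baseline activations; returns component index and
# |correlation| per source
match_components <- function(comps, subject) {
  ep <- subject$epochs
  bl <- which(ep$times >= -1 & ep$times < 0)
  n_src <- dim(subject$truth$waveform)[1]
  actf <- lapply(comps, function(cmp)
    as.numeric(plateau_bandpass(t(cmp$activation[, bl, drop = FALSE]),
                                ep$fs, c(5, 15))))
  out <- matrix(NA_real_, 2, n_src)
  used <- integer(0)
  for (k in seq_len(n_src)) {
    w <- as.numeric(t(subject$truth$waveform[k, , bl]))
    cors <- vapply(seq_along(comps), function(j)
      if (j %in% used) 0 else abs(stats::cor(actf[[j]], w)), numeric(1))
    out[1, k] <- which.max(cors); out[2, k] <- max(cors)
    used <- c(used, out[1, k])
  }
  out
}
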