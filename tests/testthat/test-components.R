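test_that("component activations equal the filter-weighted channel sums", {
  cfg <- composite_config(n_trials = 40, seed = 2)
  s <- generate_subject(cfg, 1)
  comps <- extract_alpha_components(s$epochs, seed = 1, maxit = 60,
                                    tol = 1e-3, max_ica_samples = 5000)
  cmp <- comps[[1]]
  d <- dim(s$epochs$data)
  manual <- matrix(cmp$filter %*% matrix(s$epochs$data, d[1]), d[2], d[3])
  expect_equal(cmp$activation, manual, tolerance = 1e-10)
  expect_error(extract_alpha_components(
    generate_subject(composite_config(n_trials = 5, n_channels = 24), 1)$epochs
    , n_components = 2), NA)
})

test_that("extraction is deterministic under the seed and needs 20 channels", {
  cfg <- composite_config(n_trials = 30, seed = 4)
  s <- generate_subject(cfg, 1)
  a <- extract_alpha_components(s$epochs, seed = 5, maxit = 40, tol = 1e-3,
                                max_ica_samples = 4000)
  b <- extract_alpha_components(s$epochs, seed = 5, maxit = 40, tol = 1e-3,
                                max_ica_samples = 4000)
  expect_equal(a[[3]]$filter, b[[3]]$filter)
  small <- generate_subject(cohort_config(
    1, 10, n_channels = 8, sources = list(source_spec(10))), 1)
  expect_error(extract_alpha_components(small$epochs), "20 channels")
})

test_that("alpha-peak selection keeps oscillatory components and drops 1/f-only ones", {
  # pure-noise input: most components carry no validated alpha peak
  cfg <- cohort_config(1, 60, n_channels = 24, epoch_span_s = c(-1, 0),
                       noise_amplitude = 1, seed = 6,
                       sources = list(source_spec(10, base_amplitude = 0)))
  s <- generate_subject(cfg, 1)
  cands <- extract_alpha_components(s$epochs, seed = 1, maxit = 40,
                                    tol = 1e-3, max_ica_samples = 5000)
  kept_noise <- select_alpha_peaked(cands)
  expect_lt(length(kept_noise), length(cands))
  # strong alpha sources: their components survive with peaks near truth
  s2 <- generate_subject(composite_config(n_trials = 60, seed = 7), 1)
  kept <- select_alpha_peaked(extract_alpha_components(
    s2$epochs, seed = 1, maxit = 60, tol = 1e-3, max_ica_samples = 5000))
  expect_gte(length(kept), 3)
  expect_true(all(vapply(kept, function(k) k$peak_freq_hz, 0) > 8 &
                  vapply(kept, function(k) k$peak_freq_hz, 0) < 13))
})

test_that("component trends are sign-invariant and exact in the extreme case", {
  cfg <- composite_config(n_trials = 60, seed = 8)
  s <- generate_subject(cfg, 1)
  comps <- select_alpha_peaked(extract_alpha_components(
    s$epochs, seed = 1, maxit = 60, tol = 1e-3, max_ica_samples = 5000))
  cmp <- comps[[1]]
  tr1 <- component_trend(cmp, n_shuffles = 400, seed = 9)
  flipped <- cmp
  flipped$filter <- -flipped$filter
  flipped$activation <- -flipped$activation
  tr2 <- component_trend(flipped, n_shuffles = 400, seed = 9)
  expect_equal(tr1$power_rho, tr2$power_rho)
  expect_equal(tr1$freq_rho, tr2$freq_rho)
  # strictly increasing noise-free power ramp: rho = 1, minimal p
  fs <- FS
  times <- seq(-1, 0 - 1 / fs, by = 1 / fs)
  n_tr <- 30
  act <- t(sapply(seq_len(n_tr), function(i)
    i * sin(2 * pi * 10 * (times + 1))))
  ramp <- list(activation = act, fs = fs, times = times,
               peak_freq_hz = 10)
  tr3 <- component_trend(ramp, n_shuffles = 500, seed = 10)
  expect_equal(tr3$power_rho, 1)
  expect_equal(tr3$power_p, 1 / 501)
  expect_gt(tr3$power_z, 3)
  expect_error(component_trend(ramp, trial_order = 1:30, n_shuffles = 10,
                               seed = 1)$ok, NA)
  zero <- list(activation = act * 0, fs = fs, times = times)
  expect_error(component_trend(zero), "constant")
})

test_that("classification maps the two p-values onto the four labels", {
  tab <- data.frame(power_rho = 0.2, power_z = c(3, 3, -1, 0.5),
                    power_p = c(.01, .01, .06, .5),
                    freq_rho = -0.2, freq_z = c(-3, 0.1, -2.5, 0.2),
                    freq_p = c(.01, .5, .04, .6),
                    peak_freq_hz = 10)
  got <- classify_components(tab)
  expect_identical(got$label, c("mixed", "unique-power", "unique-frequency",
                                "none"))
  expect_true(all(got$angle_deg >= 0 & got$angle_deg < 360))
  # angle quadrant: power up / frequency down lies in (270, 360)
  expect_gt(got$angle_deg[1], 270)
})

test_that("circular summaries match closed forms and detect planted direction", {
  # all angles identical: resultant 1, Rayleigh z = n
  tab <- data.frame(power_z = c(2, 4, 6), freq_z = c(-2, -4, -6))
  cs <- circular_summary(tab, n_boot = 200, seed = 1)
  expect_equal(cs$resultant_length, 1)
  expect_equal(cs$rayleigh_z, 3)
  expect_equal(cs$mean_angle_deg, 315)
  expect_error(circular_summary(data.frame(power_z = 1:2, freq_z = 1:2)),
               "3 components")
  # planted power-up/frequency-down cloud: fourth quadrant, CIs exclude 0
  set.seed(13)
  tab2 <- data.frame(power_z = rnorm(60, 2), freq_z = rnorm(60, -1.5))
  cs2 <- circular_summary(tab2, seed = 2)
  expect_gt(cs2$mean_angle_deg, 270); expect_lt(cs2$mean_angle_deg, 360)
  expect_lt(cs2$rayleigh_p, 0.001)
  expect_lt(cs2$t2circ_p, 1e-10)
  expect_identical(cs2$t2circ_dof, c(2, 118))
  expect_gt(cs2$centroid_ci["power", "lower"], 0)
  expect_lt(cs2$centroid_ci["frequency", "upper"], 0)
  # CIs bracket the point estimates
  expect_gt(cs2$centroid["power"], cs2$centroid_ci["power", "lower"])
  expect_lt(cs2$centroid["power"], cs2$centroid_ci["power", "upper"])
})

test_that("Rayleigh p-values are near-uniform for uniform angle clouds", {
  set.seed(14)
  ps <- replicate(300, {
    th <- runif(40, 0, 2 * pi)
    circular_summary(data.frame(power_z = cos(th), freq_z = sin(th)),
                     n_boot = 0)$rayleigh_p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("class peak-frequency comparisons use pooled-variance t-tests", {
  tab <- data.frame(label = rep(c("mixed", "unique-frequency", "unique-power"),
                                each = 6),
                    peak_freq_hz = c(rnorm(6, 9, 0.3), rnorm(6, 11.5, 0.3),
                                     rnorm(6, 11, 0.3)))
  cmpr <- compare_class_peak_frequencies(tab)
  expect_identical(nrow(cmpr), 3L)
  mf <- cmpr[cmpr$class1 == "mixed" & cmpr$class2 == "unique-frequency", ]
  expect_identical(mf$dof, 10)
  expect_lt(mf$t, 0)
  # identical values in two classes: t exactly 0
  tab2 <- data.frame(label = rep(c("mixed", "unique-power"), each = 4),
                     peak_freq_hz = rep(10, 8))
  cmp2 <- compare_class_peak_frequencies(tab2)
  expect_equal(cmp2$t, 0)
  expect_identical(nrow(compare_class_peak_frequencies(
    data.frame(label = "mixed", peak_freq_hz = 10))), 0L)
})

test_that("component writers emit the TSV and circular-summary JSON", {
  tab <- data.frame(power_rho = .2, power_z = 3, power_p = .01,
                    freq_rho = -.2, freq_z = -3, freq_p = .01,
                    peak_freq_hz = 10)
  cls <- classify_components(tab)
  set.seed(15)
  tab2 <- data.frame(power_z = rnorm(20, 2), freq_z = rnorm(20, -2))
  cs <- circular_summary(tab2, n_boot = 100, seed = 3)
  dir <- withr::local_tempdir()
  write_component_trends(cls, cs, dir)
  expect_true(file.exists(file.path(dir, "component_trends.tsv")))
  js <- jsonlite::read_json(file.path(dir, "circular_summary.json"))
  expect_equal(js$n, 20)
})
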