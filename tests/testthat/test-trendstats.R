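test_that("trial-order rho reproduces exact monotone cases and flags constants", {
  expect_equal(trial_order_rho(matrix(10:1, ncol = 1)), -1)
  expect_equal(trial_order_rho(matrix(1:10, ncol = 1)), 1)
  expect_true(is.na(trial_order_rho(matrix(rep(1, 10), ncol = 1))))
  expect_error(trial_order_rho(matrix(1:2, ncol = 1)), "3 trials")
  # monotone invariance: any strictly increasing transform leaves rho fixed
  set.seed(2)
  v <- rnorm(30)
  expect_equal(trial_order_rho(matrix(v, ncol = 1)),
               trial_order_rho(matrix(exp(3 * v), ncol = 1)))
})

test_that("trial-order rho with ties equals the exhaustive average-rank oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    v <- sample(1:4, n, replace = TRUE)      # heavy ties
    got <- trial_order_rho(matrix(v, ncol = 1))
    want <- oracle_spearman(seq_len(n), v)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
    expect_equal(got, suppressWarnings(
      stats::cor(seq_len(n), v, method = "spearman")))
  }
})

test_that("neighbourhoods follow the distance cutoff and the shipped layout matches montage statistics", {
  two <- data.frame(label = c("a", "b"), x = c(0, 4), y = 0, z = 0)
  expect_true(build_neighbourhood(two, 5)$matrix[1, 2])
  two$x[2] <- 6
  expect_false(build_neighbourhood(two, 5)$matrix[1, 2])
  nb <- build_neighbourhood(default_layout(), 5)
  expect_true(isSymmetric(nb$matrix))
  expect_true(all(diag(nb$matrix) == FALSE))
  cnt <- rowSums(nb$matrix)
  expect_gte(min(cnt), 2)                    # montage reports min 3, max 8
  expect_lte(max(cnt), 9)
  expect_gt(mean(cnt), 5.3); expect_lt(mean(cnt), 7.3)
  expect_lt(abs(stats::median(cnt) - 7), 1 + 1e-9)
  expect_error(build_neighbourhood(data.frame(x = 1, y = NA, z = 1)), "positions")
})

test_that("cluster labelling equals a flood-fill oracle on random small grids", {
  set.seed(11)
  lay <- chain_layout(6)
  nb <- build_neighbourhood(lay, 5)
  for (rep in 1:25) {
    mask <- matrix(runif(6 * 9) < 0.4, 6, 9)
    got <- alphadrift:::cluster_label_cpp(mask, nb$list, FALSE)
    want <- oracle_flood_fill(mask, nb$list)
    # same partition up to label permutation; union equals the mask
    expect_identical(got > 0, mask)
    expect_identical(want > 0, mask)
    for (k in unique(want[want > 0]))
      expect_length(unique(got[want == k]), 1)
    expect_identical(max(got), max(want))
  }
})

test_that("the neighbour requirement prunes isolated suprathreshold samples", {
  nb <- build_neighbourhood(chain_layout(4), 5)
  mask <- matrix(FALSE, 4, 5)
  mask[2, 2] <- TRUE                          # isolated: no cluster
  expect_true(all(alphadrift:::cluster_label_cpp(mask, nb$list, TRUE) == 0))
  # a 2-channel x 2-timepoint block: every member has both neighbours
  mask[2:3, 2:3] <- TRUE
  lab <- alphadrift:::cluster_label_cpp(mask, nb$list, TRUE)
  expect_identical(sum(lab > 0), 4L)
})

test_that("cluster permutation recovers a planted global trend and rejects bad input", {
  set.seed(21)
  nb <- build_neighbourhood(chain_layout(8), 5)
  rho <- null_rho_cohort(8, 8, 15, 60) - 0.25       # strong negative shift
  res <- cluster_permutation(rho, nb, n_perm = 300, seed = 1)
  neg <- res$clusters[res$clusters$sign == "negative", ]
  expect_gte(nrow(neg), 1)
  expect_true(any(neg$significant))
  expect_gte(max(neg$n_samples), 0.9 * 8 * 15)      # spans most of the grid
  expect_true(all(res$clusters$p > 0 & res$clusters$p <= 1))
  expect_error(cluster_permutation(rho[1, , , drop = FALSE], nb), "2 subjects")
  expect_error(cluster_permutation(rho, nb, n_perm = 0), "n_perm")
})

test_that("Monte-Carlo permutation p agrees with full sign-flip enumeration", {
  set.seed(31)
  n <- 8
  nb <- build_neighbourhood(chain_layout(4), 5)
  rho <- null_rho_cohort(n, 4, 6, 30) + 0.2
  res <- cluster_permutation(rho, nb, n_perm = 2000, require_neighbours = FALSE,
                             seed = 2)
  pos <- res$clusters[res$clusters$sign == "positive", ]
  expect_gte(nrow(pos), 1)
  biggest <- pos$mass[which.max(pos$mass)]
  # exhaustive null: all 2^n sign assignments
  R <- matrix(rho, n, 4 * 6)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  msq <- colMeans(R^2)
  pm <- signs %*% R / n
  pv <- sweep(-pm^2, 2, msq, "+") * n / (n - 1)
  pt_all <- pm / sqrt(pv / n)
  tcrit <- stats::qt(0.975, n - 1)
  null_max <- vapply(seq_len(nrow(signs)), function(i)
    alphadrift:::max_cluster_masses_cpp(matrix(pt_all[i, ], 4, 6), tcrit,
                                        nb$list, FALSE)[1], numeric(1))
  p_exact <- mean(null_max >= biggest)
  p_mc <- pos$p[which.max(pos$mass)]
  # agreement within ~3 binomial SEs of the Monte-Carlo estimate
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 2000)
})

test_that("two-line verdicts separate inverted-U from monotonic relationships", {
  set.seed(41)
  mk <- function(fun) {
    x <- rnorm(200 * 15)
    y <- fun(x) + 0.2 * rnorm(length(x))
    two_line_test(x, y, rep(1:15, each = 200))
  }
  u <- mk(function(x) -x^2)
  expect_identical(u$verdict, "inverted-U")
  expect_gt(u$low_t, 0); expect_lt(u$high_t, 0)
  neg <- mk(function(x) -x)
  expect_identical(neg$verdict, "monotonic-negative")
  pos <- mk(function(x) x)
  expect_identical(pos$verdict, "monotonic-positive")
  # two-line symmetry: negating x swaps and negates the slopes
  x <- rnorm(500); y <- -x^2 + 0.1 * rnorm(500)
  a <- two_line_test(x, y, rep(1:5, each = 100))
  b <- two_line_test(-x, y, rep(1:5, each = 100))
  expect_equal(sort(unname(a$slopes$low)), sort(unname(-b$slopes$high)),
               tolerance = 1e-10)
  expect_error(two_line_test(abs(x), y, rep(1:5, each = 100)), "side of zero")
})

test_that("two-line false positives stay near the nominal rate under independence", {
  set.seed(51)
  hits <- replicate(200, {
    x <- rnorm(80 * 8); y <- rnorm(80 * 8)
    tl <- two_line_test(x, y, rep(1:8, each = 80))
    tl$low_p < 0.05 || tl$high_p < 0.05
  })
  # two chances at alpha = .05: expect ~9.75%, allow binomial spread
  expect_lt(mean(hits), 0.2)
  expect_gt(mean(hits), 0.02)
})

test_that("polynomial trend fits support exactly the generating degree", {
  tr <- 1:60
  lin <- poly_trend_fit(0.5 + 0.02 * tr, tr)
  expect_true(lin$fits[[1]]$supported)
  expect_false(lin$fits[[2]]$supported)
  expect_false(lin$fits[[3]]$supported)
  expect_equal(lin$fits[[1]]$adj_r_squared, 1)
  quad <- poly_trend_fit((tr - 30)^2, tr)
  expect_true(quad$fits[[2]]$supported)
  expect_error(poly_trend_fit(1:4, 1:4, max_degree = 3), "few points")
  # planted weak linear drift: small adjusted R^2, tiny quadratic gain
  set.seed(61)
  n <- 4000
  y <- as.numeric(0.11 * scale(1:n)) + rnorm(n)
  fit <- poly_trend_fit(y, 1:n)
  expect_lt(fit$fits[[1]]$adj_r_squared, 0.05)
  expect_gt(fit$fits[[1]]$adj_r_squared, 0.001)
  expect_lt(fit$fits[[2]]$adj_r_squared - fit$fits[[1]]$adj_r_squared, 0.005)
})

test_that("paired frequency/power samples are z-scored on a shared grid", {
  ep <- sine_epochs(c(10, 10.5, 9.5, 11), n_channels = 2)
  pw <- frequency_power_pairs(ep, "pointwise")
  expect_equal(mean(pw$x), 0, tolerance = 1e-10)
  expect_equal(stats::sd(pw$y), 1, tolerance = 1e-6)
  expect_true(all(pw$time < 0))
  bl <- frequency_power_pairs(ep, "baseline")
  expect_identical(nrow(bl), 2L * 4L)
})

test_that("trend writer emits the long-format map and JSON summary", {
  set.seed(71)
  nb <- build_neighbourhood(chain_layout(4), 5)
  rho <- null_rho_cohort(6, 4, 5, 40)
  res <- cluster_permutation(rho, nb, n_perm = 100, seed = 3)
  dir <- withr::local_tempdir()
  write_trend_result(res, dir)
  long <- utils::read.table(file.path(dir, "trend_map.tsv"), header = TRUE)
  expect_identical(nrow(long), 20L)
  expect_true(file.exists(file.path(dir, "trend_summary.json")))
})
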