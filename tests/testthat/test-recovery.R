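test_that("marker detection needs one locus covering >= 70% of the marker", {
  marker <- rand_dna(2000, 1)
  cat <- marker_catalog(tibble::tibble(marker_id = "M1", sequence = marker))
  pad <- function(n, seed) rand_dna(n, seed)

  full <- tibble::tibble(contig_id = "c1",
                         sequence = paste0(pad(500, 2), marker, pad(500, 3)))
  expect_equal(detect_markers(full, cat)$marker_id, "M1")

  trunc69 <- tibble::tibble(
    contig_id = "c1",
    sequence = paste0(pad(500, 4), substring(marker, 1, 1380), pad(500, 5)))
  expect_equal(nrow(detect_markers(trunc69, cat)), 0)

  split40 <- tibble::tibble(
    contig_id = c("c1", "c2"),
    sequence = c(paste0(pad(500, 6), substring(marker, 1, 800)),
                 paste0(substring(marker, 1201, 2000), pad(500, 7))))
  expect_equal(nrow(detect_markers(split40, cat)), 0)

  # recovered locus sequence is returned verbatim in the error-free case
  det <- detect_markers(full, cat)
  expect_identical(det$sequence, marker)
})

test_that("completeness and genome-size arithmetic follow the estimator", {
  expect_equal(completeness(rep("x", 184), 248)$percent, 74.2)
  expect_equal(completeness(rep("x", 169), 248)$percent, 68.2)
  expect_equal(completeness(character(), 248)$percent, 0.0)
  expect_equal(estimate_genome_size(48.1, 74.2), 64.8)
  expect_equal(estimate_genome_size(32.3, 68.2), 47.4)
  expect_equal(estimate_genome_size(10, 100), 10)
  expect_error(estimate_genome_size(10, 0), "positive")
})

test_that("Michaelis-Menten fitting recovers noiseless parameters", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  crv <- saturation_curve(x, 62.7 * x / (2 + x))
  fit <- fit_michaelis_menten(crv)
  expect_lt(abs(fit$vmax - 62.7), 1e-4)
  expect_lt(abs(fit$km - 2), 1e-4)
  expect_false(fit$diverged)
  # functional identity: y(Km) = Vmax / 2
  expect_equal(fit$fitted(fit$km), fit$vmax / 2, tolerance = 1e-9)
  expect_error(fit_michaelis_menten(saturation_curve(c(1, 2), c(1, 2))),
               "distinct")
})

test_that("nonlinear MM fits agree with a brute-force grid-search oracle", {
  vmax <- 100; km <- 0.15
  x <- rep(c(0.17, 0.33, 0.50, 0.67, 0.83), each = 5)
  for (seed in 1:3) {
    y <- withr::with_seed(seed, vmax * x / (km + x) + rnorm(length(x), 0, 2))
    fit <- fit_michaelis_menten(tibble::tibble(x = x, y = y))
    # independent oracle: exhaustive grid search over (vmax, km)
    grid <- expand.grid(v = seq(80, 120, by = 0.25),
                        k = seq(0.05, 0.40, by = 0.005))
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum((y - grid$v[i] * x / (grid$k[i] + x))^2)
    }, 0)
    best <- grid[which.min(sse), ]
    expect_lt(abs(fit$vmax - best$v) / best$v, 0.01)
    expect_lt(abs(fit$km - best$k), 0.02)
  }
})

test_that("decreasing pseudo-saturation data are flagged as diverged", {
  crv <- saturation_curve(1:5, c(50, 40, 30, 20, 10))
  expect_warning(fit <- fit_michaelis_menten(crv), "decreases")
  expect_true(fit$diverged)
})

test_that("tidy and glance summarize MM fits", {
  x <- c(1, 2, 4, 8)
  fit <- fit_michaelis_menten(saturation_curve(x, 10 * x / (1 + x)))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("vmax", "km"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_points, 4)
  expect_s3_class(
    ggplot2::autoplot(saturation_curve(x, 10 * x / (1 + x)), fit = fit),
    "ggplot")
})

test_that("cumulative curves are flat for identical cells and anchored at k=1", {
  sc <- fixture_scenario(n_sags = 1, genome_len = 1e5, p = 0.3, seed = 77)
  one <- sc$sags[[1]]
  clones <- lapply(1:4, function(i) {
    x <- one
    x$sag_id <- sprintf("C%d", i)
    x
  })
  res <- cumulative_coassembly_curve(clones, n_orderings = 3, seed = 1)
  expect_equal(res$mode, "truth")
  single <- sum(one$truth$intervals$end - one$truth$intervals$start)
  expect_true(all(res$curve$y == single))
  # k = 1 mean equals the mean single-cell value in a mixed scenario
  sc2 <- fixture_scenario(n_sags = 4, genome_len = 1e5, p = 0.25, seed = 78)
  res2 <- cumulative_coassembly_curve(sc2$sags, n_orderings = 30, seed = 2)
  k1 <- mean(res2$curve$y[res2$curve$x == 1])
  singles <- vapply(sc2$sags, function(s) {
    sum(s$truth$intervals$end - s$truth$intervals$start)
  }, 0)
  expect_lt(abs(k1 - mean(singles)) / mean(singles), 0.05)
})

test_that("prefix means increase monotonically within standard error", {
  sc <- fixture_scenario(n_sags = 6, genome_len = 1.5e5, p = 0.2, seed = 81)
  res <- cumulative_coassembly_curve(sc$sags, n_orderings = 20, seed = 3)
  agg <- dplyr::summarise(dplyr::group_by(res$curve, x),
                          m = mean(y), se = sd(y) / sqrt(dplyr::n()),
                          .groups = "drop")
  expect_true(all(diff(agg$m) >= -agg$se[-1] - 1e-9))
})

test_that("the MM asymptote matches the least-squares oracle on union curves", {
  # Independent coverage at fraction p makes the expected union curve
  # G * (1 - (1-p)^k); the best least-squares MM fit to that exponential
  # saturation overshoots the true genome size (the MM tail rises more
  # slowly), so the honest oracle is the LS optimum itself, computed here
  # by exhaustive grid search on the analytic curve.
  k <- 1:14; p <- 0.2; truth <- 1e6
  y_analytic <- truth * (1 - (1 - p)^k)
  grid <- expand.grid(v = seq(0.8e6, 1.8e6, by = 5e3),
                      K = seq(0.5, 10, by = 0.05))
  sse <- mapply(function(v, K) sum((y_analytic - v * k / (K + k))^2),
                grid$v, grid$K)
  oracle <- grid[which.min(sse), ]

  sc <- fixture_scenario(n_sags = 14, genome_len = truth, p = p,
                         mean_block = 10000, seed = 90)
  res <- cumulative_coassembly_curve(sc$sags, n_orderings = 20, seed = 4)
  expect_lt(abs(res$fit$vmax - oracle$v) / oracle$v, 0.15)
  # the extrapolation brackets the truth from above: vmax >= observed max
  expect_gte(res$fit$vmax, max(res$curve$y))
  expect_gte(res$fit$vmax, truth * 0.95)
})

test_that("union completeness dominates the best single cell", {
  sc <- fixture_scenario(n_sags = 5, genome_len = 2e5, p = 0.3,
                         n_markers = 20, marker_len = 1000, seed = 95)
  cat <- marker_catalog(sc$genome)
  singles <- vapply(sc$sags, function(s) {
    sagco:::.truth_completeness(sagco:::.iv_reduce(s$truth$intervals),
                                sc$genome, cat, 0.70)
  }, 0)
  union_iv <- sagco:::.iv_reduce(
    dplyr::bind_rows(lapply(sc$sags, function(s) s$truth$intervals)))
  u <- sagco:::.truth_completeness(union_iv, sc$genome, cat, 0.70)
  expect_gte(u, max(singles))
})
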