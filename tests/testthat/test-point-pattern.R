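unit_sq <- pp_window(0, 1, 0, 1)

test_that("summary statistics match hand-computed nearest neighbours", {
  pp <- point_pattern(c(0, 1), c(0, 0), unit_sq)
  ss <- summary_stats(pp)
  expect_equal(ss$intensity, 2)
  expect_equal(ss$mean_nn_distance, 1)

  empty <- point_pattern(numeric(0), numeric(0), unit_sq)
  ss0 <- summary_stats(empty)
  expect_equal(ss0$intensity, 0)
  expect_true(is.na(ss0$mean_nn_distance))

  # collinear points at 0, 1, 3: NN distances 1, 1, 2
  big <- pp_window(0, 10, 0, 10)
  pp3 <- point_pattern(c(0, 1, 3), c(5, 5, 5), big)
  expect_equal(summary_stats(pp3)$mean_nn_distance, (1 + 1 + 2) / 3)
})

test_that("Clark-Evans index matches its closed form and CSR calibration", {
  pp <- point_pattern(c(0, 1), c(0, 0), unit_sq)
  expect_equal(clark_evans(pp), 2 * sqrt(2))
  expect_error(clark_evans(point_pattern(0.5, 0.5, unit_sq)), "at least 2")

  # definitional CSR calibration at large n
  idx <- vapply(1:20, function(s) {
    clark_evans(gen_point_process("poisson", unit_sq,
                                  list(lambda = 1000), seed = s),
                correction = "donnelly")
  }, numeric(1))
  expect_lt(abs(mean(idx) - 1), 0.05)
})

test_that("Hopkins-Skellam separates CSR, clustering and regularity", {
  hs_csr <- vapply(1:20, function(s) {
    hopkins_skellam(gen_point_process("poisson", unit_sq,
                                      list(lambda = 400), seed = s),
                    rng_seed = s + 100)
  }, numeric(1))
  expect_lt(abs(mean(hs_csr) - 1), 0.1)

  # one tight cluster in a large window: numerator collapses
  set.seed(3)
  tight <- point_pattern(0.5 + runif(30, 0, 0.01),
                         0.5 + runif(30, 0, 0.01), unit_sq)
  expect_lt(hopkins_skellam(tight, rng_seed = 1), 0.05)

  # regular grid: dispersal
  g <- seq(0.05, 0.95, by = 0.1)
  grid_pp <- point_pattern(rep(g, 10), rep(g, each = 10), unit_sq)
  expect_gt(hopkins_skellam(grid_pp, rng_seed = 1), 1)
})

test_that("uncorrected K matches its closed form and brute-force oracle", {
  pp <- point_pattern(c(0, 0.6), c(0.5, 0.5), unit_sq)
  k <- k_function(pp, c(0, 0.3, 0.59, 0.6, 0.7), correction = "none")
  expect_equal(k$value, c(0, 0, 0, 1, 1))

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:6, 1)
    px <- runif(n); py <- runif(n)
    pps <- point_pattern(px, py, unit_sq)
    r_grid <- seq(0, 0.5, by = 0.05)
    expect_equal(k_function(pps, r_grid, correction = "none")$value,
                 oracle_k_uncorrected(px, py, 1, r_grid))
  }
})

test_that("translation weights are at least 1 so corrected K dominates", {
  pp <- point_pattern(c(0.1, 0.9), c(0.2, 0.8), unit_sq)
  r_grid <- seq(0, 0.25, length.out = 32)
  # max r constraint keeps both estimators on the same grid
  pp2 <- point_pattern(c(0.1, 0.3), c(0.2, 0.25), unit_sq)
  k_none <- k_function(pp2, r_grid, correction = "none")
  k_tr <- k_function(pp2, r_grid, correction = "translation")
  expect_true(all(k_tr$value >= k_none$value))
})

test_that("K and L estimators are CSR-calibrated for all corrections", {
  r_grid <- seq(0, 0.25, length.out = 33)
  for (corr in c("translation", "isotropic", "border")) {
    lval <- vapply(1:20, function(s) {
      pp <- gen_point_process("poisson", unit_sq, list(lambda = 150),
                              seed = s)
      l_function(pp, r_grid, correction = corr, centred = TRUE)$value
    }, numeric(33))
    avg <- rowMeans(lval, na.rm = TRUE)[-1]
    se <- apply(lval, 1, sd, na.rm = TRUE)[-1] / sqrt(20)
    expect_true(mean(abs(avg)) < 3 * mean(se),
                label = paste("centred L near zero for", corr))
  }
})

test_that("summary function estimates are monotone with proper ranges", {
  pp <- gen_point_process("poisson", unit_sq, list(lambda = 100), seed = 2)
  k <- k_function(pp, correction = "translation")
  expect_true(all(diff(k$value) >= 0))
  es <- empty_space_functions(pp, grid_spacing = 1 / 64,
                              correction = "km")
  for (f in list(es$F, es$G)) {
    expect_true(all(f$value >= 0 & f$value <= 1))
    expect_true(all(diff(f$value) >= -1e-12))
  }
})

test_that("G saturates at the maximum NN distance and hard cores empty G", {
  pp <- point_pattern(c(0.2, 0.4, 0.8), c(0.5, 0.5, 0.5), unit_sq)
  r_grid <- seq(0, 0.5, by = 0.05)
  es <- empty_space_functions(pp, r_grid)
  nn_max <- max(c(0.2, 0.2, 0.4))
  expect_true(all(es$G$value[es$G$r >= nn_max] == 1, na.rm = TRUE))

  hard <- gen_point_process("inhibition", unit_sq,
                            list(n = 60, h = 0.08), seed = 1)
  esh <- empty_space_functions(hard, seq(0, 0.1, by = 0.005))
  expect_true(all(esh$G$value[esh$G$r < 0.08] == 0, na.rm = TRUE))
})

test_that("J is near 1 under CSR over the informative r range", {
  # informative range: r where F stays well below saturation
  # (lambda 150: F(0.05) ~ 0.7)
  r_grid <- seq(0, 0.05, length.out = 26)
  jvals <- vapply(1:20, function(s) {
    pp <- gen_point_process("poisson", unit_sq, list(lambda = 150), seed = s)
    empty_space_functions(pp, r_grid, grid_spacing = 1 / 64)$J$value
  }, numeric(26))
  avg <- rowMeans(jvals, na.rm = TRUE)[-1]
  se <- apply(jvals, 1, sd, na.rm = TRUE)[-1] / sqrt(20)
  expect_true(all(abs(avg - 1) < 3 * pmax(se, 0.02)))
})

test_that("statistics are invariant to rigid motions of pattern and window", {
  pp <- gen_point_process("poisson", unit_sq, list(lambda = 60), seed = 5)
  r_grid <- seq(0, 0.25, length.out = 16)
  base_k <- k_function(pp, r_grid, correction = "translation")$value
  base_ce <- clark_evans(pp)

  shifted <- point_pattern(pp$x + 7, pp$y - 3, pp_window(7, 8, -3, -2))
  expect_equal(k_function(shifted, r_grid, "translation")$value, base_k)
  expect_equal(clark_evans(shifted), base_ce)

  rotated <- point_pattern(pp$y, 1 - pp$x, unit_sq)  # 90 deg in square
  expect_equal(k_function(rotated, r_grid, "translation")$value, base_k)
  expect_equal(clark_evans(rotated), base_ce)
})

test_that("pointwise envelope bands follow the rank construction", {
  pp <- gen_point_process("poisson", unit_sq, list(lambda = 50), seed = 1)
  r_grid <- seq(0, 0.2, length.out = 11)
  env <- csr_envelope(pp, "K", n_sim = 99, kind = "pointwise",
                      rng_seed = 7, r_grid = r_grid)
  # reproduce the simulations and check the 3rd-extreme construction
  set.seed(7L)
  sims <- vapply(1:99, function(i) {
    histoscape:::.eval_summary_fn(
      histoscape:::.runif_pattern(pp$n, pp$window), "K", r_grid, NULL)
  }, numeric(length(r_grid)))
  expect_equal(env$lo, apply(sims, 1, function(v) sort(v)[3]))
  expect_equal(env$hi, apply(sims, 1, function(v) sort(v, TRUE)[3]))
})

test_that("global envelopes catch clustering and respect CSR", {
  clus <- gen_point_process("matern_cluster", unit_sq,
                            list(kappa = 10, mu = 10, R = 0.03), seed = 2)
  env <- csr_envelope(clus, "L", n_sim = 99, kind = "global", rng_seed = 3)
  expect_true(any(env$obs > env$hi, na.rm = TRUE))

  # coverage calibration: CSR inside the 95% global band most of the time
  hits <- vapply(1:40, function(t) {
    pp <- gen_point_process("poisson", unit_sq, list(lambda = 40),
                            seed = 1000 + t)
    e <- csr_envelope(pp, "L", n_sim = 39, kind = "global",
                      rng_seed = t, r_grid = seq(0, 0.25, length.out = 33))
    all(e$obs >= e$lo & e$obs <= e$hi, na.rm = TRUE)
  }, logical(1))
  # nominal 95%, binomial slack for 40 trials
  expect_gte(mean(hits), 0.8)
})

test_that("Voronoi cells tile the window and Stienen circles touch", {
  pp <- gen_point_process("poisson", unit_sq, list(lambda = 40), seed = 6)
  vs <- voronoi_stienen(pp)
  expect_equal(sum(vs$cell_areas), 1, tolerance = 1e-6)

  sym <- point_pattern(c(0.25, 0.75), c(0.5, 0.5), unit_sq)
  vsym <- voronoi_stienen(sym)
  expect_equal(vsym$cell_areas, c(0.5, 0.5))
  expect_equal(vsym$stienen$radius, c(0.25, 0.25))
  expect_false(any(vsym$stienen$crosses_boundary))
  expect_error(voronoi_stienen(point_pattern(0.5, 0.5, unit_sq)),
               "at least 2")
})

test_that("grouped permutation test handles identity and separation", {
  pp <- gen_point_process("poisson", unit_sq, list(lambda = 60), seed = 1)
  same <- list(list(pp, pp, pp), list(pp, pp, pp))
  res <- studentized_permutation_test(same, "L", n_permutations = 99,
                                      rng_seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  mk <- function(kind, params, seeds) {
    lapply(seeds, function(s) gen_point_process(kind, unit_sq, params, s))
  }
  csr <- mk("poisson", list(lambda = 100), 1:8)
  clus <- mk("matern_cluster", list(kappa = 12, mu = 9, R = 0.04), 1:8)
  res2 <- studentized_permutation_test(list(a = csr, b = clus), "L",
                                       n_permutations = 199, rng_seed = 2)
  expect_lte(res2$p_value, 0.01)
  expect_error(studentized_permutation_test(list(csr, clus[1]), "L"),
               "at least 2 patterns")
})

test_that("the combined multi-function test aggregates per-function statistics", {
  mk <- function(kind, params, seeds) {
    lapply(seeds, function(s) gen_point_process(kind, unit_sq, params, s))
  }
  # 5 patterns per group: enough distinct label permutations for p to
  # resolve below 0.05
  csr <- mk("poisson", list(lambda = 80), 1:5)
  clus <- mk("matern_cluster", list(kappa = 10, mu = 8, R = 0.04), 1:5)
  res <- combined_permutation_test(list(csr, clus), which = c("L", "G"),
                                   n_permutations = 199, rng_seed = 1)
  expect_equal(res$statistic, sum(res$per_function))
  expect_equal(res$which, "L+G")
  expect_lt(res$p_value, 0.05)
  # consistency: each per-function statistic matches the single test
  single <- studentized_permutation_test(list(csr, clus), "L",
                                         n_permutations = 9, rng_seed = 1)
  expect_equal(unname(res$per_function["L"]), single$statistic)
})
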