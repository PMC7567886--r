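big_w <- pp_window(-10, 10, -10, 10)

test_that("cross-kNN distances enumerate the k smallest correctly", {
  hexx <- cos(seq(0, 300, by = 60) * pi / 180)
  hexy <- sin(seq(0, 300, by = 60) * pi / 180)
  central <- point_pattern(0, 0, big_w)
  portals <- point_pattern(hexx, hexy, big_w)
  expect_equal(as.numeric(cross_knn_distances(central, portals, 6)),
               rep(1, 6))

  targets <- point_pattern(c(1, 2, 3), c(0, 0, 0), big_w)
  expect_equal(as.numeric(cross_knn_distances(central, targets, 2)),
               c(1, 2))
  expect_equal(as.numeric(cross_knn_distances(central, targets, 1)), 1)
  expect_error(cross_knn_distances(central, targets, 5), "deficit")
})

test_that("lobule areas follow the hexagon formula and scale as expected", {
  hexx <- cos(seq(0, 300, by = 60) * pi / 180)
  hexy <- sin(seq(0, 300, by = 60) * pi / 180)
  centrals <- point_pattern(0, 0, big_w)
  portals <- point_pattern(hexx, hexy, big_w)
  la <- lobule_areas(centrals, portals)
  expect_equal(la$r, 1)
  expect_equal(la$area, 3 * sqrt(3) / 2, tolerance = 1e-12)

  # doubling all coordinates quadruples the area
  c2 <- point_pattern(0, 0, big_w)
  p2 <- point_pattern(2 * hexx, 2 * hexy, big_w)
  expect_equal(lobule_areas(c2, p2)$area, 4 * la$area)

  expect_error(lobule_areas(centrals, point_pattern(1:5, 1:5, big_w)),
               "at least 6")
})

test_that("lattice estimates recover the constructed hexagon area", {
  win <- pp_window(0, 900, 0, 700)
  lat <- gen_lobular_lattice(win, spacing = 100, jitter_sd = 0, seed = 1)
  la <- lobule_areas(lat$centrals, lat$portals)
  expect_gt(nrow(la), 10)
  expect_lt(max(abs(la$area - lat$true_area) / lat$true_area), 1e-9)
  # identity: true area equals (sqrt(3)/2) s^2
  expect_equal(lat$true_area, sqrt(3) / 2 * 100^2, tolerance = 1e-12)
})

test_that("point-to-ring distance handles segments, vertices, endpoints", {
  ring <- list(x = c(-1, 1, 0), y = c(0, 0, 2))
  expect_equal(point_to_ring_distance(list(x = 0, y = -1), ring), 1)
  expect_equal(point_to_ring_distance(list(x = -1, y = 0), ring), 0)
  expect_equal(point_to_ring_distance(list(x = 2, y = 0), ring), 1)
  expect_error(point_to_ring_distance(list(x = 0, y = 0),
                                      list(x = c(1, 1, 1), y = c(2, 2, 2))),
               "degenerate")
  # interior points get a positive distance to the boundary
  sq <- list(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4))
  expect_equal(point_to_ring_distance(list(x = 2, y = 2), sq), 2)
})

test_that("ring centroid matches polygon closed forms and translates", {
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(ring_centroid(sq), c(x = 0.5, y = 0.5))
  tri <- list(x = c(0, 1, 0), y = c(0, 0, 1))
  expect_equal(ring_centroid(tri), c(x = 1 / 3, y = 1 / 3))
  tri2 <- list(x = tri$x + 5, y = tri$y - 2)
  expect_equal(ring_centroid(tri2), c(x = 1 / 3 + 5, y = 1 / 3 - 2))
  expect_warning(cz <- ring_centroid(list(x = c(0, 1, 2), y = c(0, 1, 2))),
                 "zero area")
  expect_equal(unname(cz), c(1, 1))
})

test_that("polar angles follow the image-orientation convention", {
  ctr <- c(0, 0)
  expect_equal(polar_angles(list(x = 1, y = 0), ctr), 0)
  # due north on screen = smaller y in raster coords = 90 deg
  expect_equal(polar_angles(list(x = 0, y = -1), ctr), 90)
  expect_equal(polar_angles(list(x = 0, y = 1), ctr, flip_y = FALSE), 90)
  expect_error(polar_angles(list(x = c(1, 0), y = c(1, 0)), ctr), "index 2")

  # rotating points rotates every angle equally
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  a0 <- polar_angles(list(x = x, y = y), ctr, flip_y = FALSE)
  th <- 30 * pi / 180
  a1 <- polar_angles(list(x = x * cos(th) - y * sin(th),
                          y = x * sin(th) + y * cos(th)),
                     ctr, flip_y = FALSE)
  expect_equal((a1 - a0) %% 360, rep(30, 20), tolerance = 1e-9)
})

test_that("angular density is circular, normalised, and peak-seeking", {
  ad <- angular_density(rep(30, 50), bandwidth = 5)
  expect_equal(ad$phi_peak, 30)
  expect_equal(sum(ad$density), 1, tolerance = 1e-6)

  # antipodal clusters with unequal weight: peak at the heavier mode
  set.seed(2)
  a <- c(rnorm(70, 10, 4) %% 360, rnorm(30, 190, 4) %% 360)
  ad2 <- angular_density(a, bandwidth = 6)
  expect_lt(min(abs(ad2$phi_peak - 10), abs(ad2$phi_peak - 370)), 10)
  expect_error(angular_density(5), "at least 2")

  # wrapping: mass near 0/360 is not split by the boundary
  near0 <- c(rnorm(50, 0, 3)) %% 360
  ad3 <- angular_density(near0, bandwidth = 3)
  expect_lt(min(ad3$phi_peak, 360 - ad3$phi_peak), 6)
})

test_that("alignment rotates the peak to 90 deg preserving structure", {
  sf <- gen_scar_field(n_cells = 300, axis_deg = 30,
                       bipolar_concentration = 25, seed = 3)
  al <- align_to_peak(sf)
  expect_equal(al$phi_peak, 90)
  expect_equal(al$d, sf$d)
  # pairwise angular differences preserved (mod 360)
  d0 <- (sf$phi[-1] - sf$phi[1]) %% 360
  d1 <- (al$phi[-1] - al$phi[1]) %% 360
  expect_equal(d1, d0, tolerance = 1e-9)
  # aligning an aligned field is the identity shift
  al2 <- align_to_peak(al)
  expect_equal(al2$shift_applied, 0)
})

test_that("sine fit recovers planted periodicities", {
  phi <- 0:359
  y <- 2 - cos(2 * phi * pi / 180)  # = 2 + sin(2 pi phi / 180 - pi/2)
  fit <- fit_axial_sine(phi, y)
  expect_equal(fit$period, 180, tolerance = 1e-3)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$period_identifiable)

  flat <- fit_axial_sine(phi, rep(1 / 360, 360))
  expect_lt(flat$amplitude, 1e-6)
  expect_false(flat$period_identifiable)

  # unipolar (von-Mises-like) density: 360-degree periodicity
  set.seed(4)
  uni <- angular_density(rnorm(400, 200, 30) %% 360, bandwidth = 15)
  fu <- fit_axial_sine(uni$phi, uni$density)
  expect_equal(fu$period, 360, tolerance = 36)
})

test_that("radial density is normalised with sensible modes", {
  set.seed(5)
  d <- rexp(400, rate = 4)
  rd <- radial_density(d)
  expect_equal(sum(rd$density) * (rd$x[2] - rd$x[1]), 1, tolerance = 1e-6)
  expect_lt(rd$mode, quantile(d, 0.25))

  spike <- radial_density(rep(2, 10))
  expect_equal(spike$mode, 2)
  expect_error(radial_density(1), "at least 2")
})

test_that("bootstrap KS behaves at the identity and separation extremes", {
  a <- c(1, 2, 3, 4, 5)
  res <- ks_boot(a, a, n_boot = 99, rng_seed = 1)
  expect_equal(res$D, 0)
  expect_equal(res$p_value, 1)

  b <- a + 100
  res2 <- ks_boot(rep(a, 3), rep(b, 3), n_boot = 999, rng_seed = 1)
  expect_equal(res2$D, 1)
  expect_lte(res2$p_value, 0.01)

  # D agrees with the standard two-sample statistic
  set.seed(6)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(ks_boot(x, y, n_boot = 9, rng_seed = 1)$D,
               unname(suppressWarnings(ks.test(x, y)$statistic)))
})

test_that("Welch test matches its closed form", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shifted <- welch_t_test(c(1, 2, 3), c(1001, 1002, 1003))
  expect_lt(shifted$p_value, 1e-6)

  # hand computation: a = {0, 1}, b = {10, 11}
  # means 0.5, 10.5; variances 0.5; t = -10 / sqrt(0.5); df = 2
  res <- welch_t_test(c(0, 1), c(10, 11))
  expect_equal(res$t, -10 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$df, 2, tolerance = 1e-12)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("lobule areas are rigid-motion equivariant and scale squared", {
  win <- pp_window(0, 600, 0, 500)
  lat <- gen_lobular_lattice(win, spacing = 80, jitter_sd = 4, seed = 2)
  la0 <- lobule_areas(lat$centrals, lat$portals)
  wshift <- pp_window(50, 650, -20, 480)
  cs <- point_pattern(lat$centrals$x + 50, lat$centrals$y - 20, wshift)
  ps <- point_pattern(lat$portals$x + 50, lat$portals$y - 20, wshift)
  expect_equal(lobule_areas(cs, ps)$area, la0$area)

  wbig <- pp_window(0, 1800, 0, 1500)
  cb <- point_pattern(3 * lat$centrals$x, 3 * lat$centrals$y, wbig)
  pb <- point_pattern(3 * lat$portals$x, 3 * lat$portals$y, wbig)
  expect_equal(lobule_areas(cb, pb)$area, 9 * la0$area)
})
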