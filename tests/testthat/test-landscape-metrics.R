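test_that("patch metrics match hand counts on minimal patches", {
  # single 2x2 patch
  r <- categorical_raster(matrix(1L, 2, 2))
  pm <- patch_metrics(label_patches(r), r)
  expect_equal(pm$area, 4)
  expect_equal(pm$perimeter, 8)
  expect_equal(pm$shape_index, 1.0)
  expect_true(is.na(pm$enn))

  # single pixel
  r1 <- categorical_raster(matrix(1L, 1, 1))
  pm1 <- patch_metrics(label_patches(r1), r1)
  expect_equal(pm1$area, 1)
  expect_equal(pm1$perimeter, 4)
  expect_equal(pm1$shape_index, 1.0)
})

test_that("ENN is the edge-to-edge pixel-centre distance", {
  # two same-class pixels separated by one column of another class
  r <- categorical_raster(matrix(c(1, 2, 1), 1, 3))
  pm <- patch_metrics(label_patches(r, 4), r)
  same <- pm[pm$class == 1, ]
  expect_equal(same$enn, c(2, 2))
  # the lone class-2 patch has no same-class neighbour
  expect_true(is.na(pm$enn[pm$class == 2]))
})

test_that("patch area and perimeter match the pixel-loop oracle", {
  for (seed in 1:6) {
    r <- random_raster(6, 6, 3, seed)
    lab <- label_patches(r, 8)
    pm <- patch_metrics(lab, r)
    oracle <- oracle_patch_table(r$values, 8)
    # align oracle ids to package ids through pixel overlap
    map <- integer(max(oracle$ids))
    for (id in seq_len(max(oracle$ids))) {
      map[id] <- lab$patch_ids[which(oracle$ids == id)[1]]
    }
    expect_equal(pm$area[map], as.numeric(oracle$area))
    expect_equal(pm$perimeter[map], as.numeric(oracle$perimeter))
  }
})

test_that("class metrics recover closed-form values on small rasters", {
  uni <- categorical_raster(matrix(7L, 4, 4))
  cm <- class_metrics(label_patches(uni), uni)
  expect_equal(cm$pland, 100)
  expect_equal(cm$np, 1)
  expect_equal(cm$lpi, 100)
  expect_equal(cm$ai, 100)

  chk <- categorical_raster(matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE))
  cmc <- class_metrics(label_patches(chk, 4), chk)
  expect_equal(cmc$ai, c(0, 0))

  r <- categorical_raster(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE))
  cm2 <- class_metrics(label_patches(r), r)
  expect_equal(cm2$pland, c(75, 25))
  expect_equal(cm2$np, c(1, 1))
})

test_that("resolution scales areas and lengths correctly", {
  v <- matrix(c(1, 1, 1, 2), 2, 2)
  r1 <- categorical_raster(v, resolution = 1)
  r2 <- categorical_raster(v, resolution = 2.5)
  pm1 <- patch_metrics(label_patches(r1), r1)
  pm2 <- patch_metrics(label_patches(r2), r2)
  expect_equal(pm2$area, pm1$area * 2.5^2)
  expect_equal(pm2$perimeter, pm1$perimeter * 2.5)
  expect_equal(pm2$shape_index, pm1$shape_index)
})

test_that("landscape metrics recover diversity closed forms", {
  uni <- categorical_raster(matrix(1L, 4, 4))
  lm_uni <- landscape_level_metrics(label_patches(uni), uni)
  expect_equal(lm_uni$shdi, 0)
  expect_equal(lm_uni$sidi, 0)
  expect_true(is.na(lm_uni$shei))
  expect_true(is.na(lm_uni$contag))

  half <- categorical_raster(matrix(rep(c(1L, 2L), each = 8), 4, 4))
  lm_half <- landscape_level_metrics(label_patches(half), half)
  expect_equal(lm_half$shdi, log(2), tolerance = 1e-12)
  expect_equal(lm_half$shei, 1)

  # large 4-class iid raster: SHDI approaches ln 4
  big <- random_raster(128, 128, 4, seed = 1)
  lm_big <- landscape_level_metrics(label_patches(big), big)
  expect_equal(lm_big$shdi, log(4), tolerance = 0.01)
})

test_that("complexity metrics match hand-derived distributions", {
  chk <- categorical_raster(matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE))
  cx <- complexity_metrics(adjacency_counts(chk))
  expect_equal(cx$marginal, 1)
  expect_equal(cx$conditional, 0)
  expect_equal(cx$joint, 1)
  expect_equal(cx$mutual_information, 1)
  expect_equal(cx$relative_mutual_information, 1)

  uni <- categorical_raster(matrix(1L, 3, 3))
  cxu <- complexity_metrics(adjacency_counts(uni))
  expect_equal(cxu$marginal, 0)
  expect_equal(cxu$joint, 0)
  expect_true(is.na(cxu$relative_mutual_information))

  expect_error(complexity_metrics(adjacency_counts(
    categorical_raster(matrix(1L, 1, 1)))), "degenerate")
})

test_that("iid random labels give near-zero mutual information", {
  big <- random_raster(256, 256, 2, seed = 7)
  cx <- complexity_metrics(adjacency_counts(big))
  expect_lt(abs(cx$mutual_information), 0.02)
  ocx <- oracle_complexity(big$values)
  expect_equal(cx$mutual_information, ocx$mutual_information,
               tolerance = 1e-12)
})

test_that("entropy identities hold and relabelling is invariant", {
  for (seed in 1:5) {
    r <- random_raster(10, 10, 3, seed)
    cx <- complexity_metrics(adjacency_counts(r))
    expect_equal(cx$joint, cx$marginal + cx$conditional, tolerance = 1e-9)
    expect_gte(cx$mutual_information, -1e-9)
    expect_lte(cx$mutual_information, cx$marginal + 1e-9)

    # permute class codes: diversity and complexity metrics unchanged
    perm <- c(2L, 3L, 1L)
    rp <- categorical_raster(matrix(perm[r$values], 10, 10))
    lmo <- landscape_level_metrics(label_patches(r), r)
    lmp <- landscape_level_metrics(label_patches(rp), rp)
    for (nm in c("shdi", "shei", "sidi", "contag", "np", "te"))
      expect_equal(lmp[[nm]], lmo[[nm]])
    cxp <- complexity_metrics(adjacency_counts(rp))
    expect_equal(cxp, cx)
  }
})

test_that("all metrics match naive oracles exactly on tiny rasters", {
  for (seed in 1:8) {
    r <- random_raster(sample(3:6, 1), sample(3:6, 1), 3, seed)
    lab <- label_patches(r, 8)
    expect_equal(unclass(adjacency_counts(r)), oracle_adjacency(r$values),
                 ignore_attr = TRUE)
    ocx <- oracle_complexity(r$values)
    cx <- complexity_metrics(adjacency_counts(r))
    expect_equal(cx$marginal, ocx$marginal, tolerance = 1e-12)
    expect_equal(cx$joint, ocx$joint, tolerance = 1e-12)
    ot <- oracle_patch_table(r$values, 8)
    pm <- patch_metrics(lab, r)
    expect_equal(sort(pm$area), sort(as.numeric(ot$area)))
    expect_equal(sort(pm$perimeter), sort(as.numeric(ot$perimeter)))
    # class pland from raw counts
    cm <- class_metrics(lab, r)
    counts <- table(factor(r$values, levels = cm$class))
    expect_equal(cm$pland, 100 * as.numeric(counts) / sum(counts))
  }
})

test_that("clumpier generators give lower edge density and higher AI", {
  lo <- vapply(1:5, function(s) {
    r <- gen_clumpy_raster(c(96, 96), 3, clumpiness = 0.1, seed = s)
    lm <- landscape_level_metrics(label_patches(r), r)
    c(lm$ed, lm$ai)
  }, numeric(2))
  hi <- vapply(1:5, function(s) {
    r <- gen_clumpy_raster(c(96, 96), 3, clumpiness = 0.9, seed = s)
    lm <- landscape_level_metrics(label_patches(r), r)
    c(lm$ed, lm$ai)
  }, numeric(2))
  expect_true(all(hi[1, ] < lo[1, ]))  # edge density falls
  expect_true(all(hi[2, ] > lo[2, ]))  # aggregation rises
})

test_that("metric tables serialise to tidy long CSV", {
  r <- random_raster(6, 6, 2, seed = 3)
  lab <- label_patches(r)
  path <- withr::local_tempfile(fileext = ".csv")
  long <- write_metrics_csv(class_metrics(lab, r), "class", "caseA", path)
  back <- read.csv(path)
  expect_equal(names(back), c("case_id", "level", "id", "metric", "value"))
  expect_equal(nrow(back), nrow(long))
  expect_true(all(back$level == "class"))
})
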