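# Feature operators against brute-force references and their documented
# invariances.

test_that("bright-detail image matches the naive min-then-max scan and its
           degenerate contracts", {
  expect_equal(bright_detail_image(matrix(7, 15, 15)), matrix(0, 15, 15))

  x <- matrix(0, 15, 15); x[8, 8] <- 42
  expect_equal(bright_detail_image(x), x)

  for (seed in 1:8) {
    g <- random_cell_grid(seed = seed)
    expect_equal(bright_detail_image(g, 3), oracle_bright_detail(g, 3),
                 tolerance = 1e-12)
    expect_true(all(bright_detail_image(g, 2) >= 0))
  }
})

test_that("BDI sums bright detail over the mask, is additive over disjoint
           puncta, and is invariant to constant offsets", {
  m <- default_disk_mask()
  expect_equal(bright_detail_intensity(matrix(5, 31, 31), m), 0)

  side <- 31
  punc <- function(cx, cy, a) {
    d2 <- outer((seq_len(side) - cx)^2, (seq_len(side) - cy)^2, "+")
    a * exp(-d2 / (2 * 0.5^2))
  }
  p1 <- punc(12, 12, 200); p2 <- punc(20, 20, 150)
  b1 <- bright_detail_intensity(p1, m)
  b2 <- bright_detail_intensity(p2, m)
  b12 <- bright_detail_intensity(p1 + p2, m)
  expect_equal(b12, b1 + b2, tolerance = 1e-9)
  # a radius-0.5 punctum passes the radius-3 top-hat almost unchanged
  expect_equal(b1, sum(oracle_bright_detail(p1)[m]), tolerance = 1e-12)
  expect_gt(b1, 0.9 * sum(p1[m]))

  g <- random_cell_grid(seed = 99)
  expect_equal(bright_detail_intensity(g + 13.7, m),
               bright_detail_intensity(g, m), tolerance = 1e-9)
  expect_equal(bright_detail_intensity(3 * g, m),
               3 * bright_detail_intensity(g, m), tolerance = 1e-9)
  expect_warning(b0 <- bright_detail_intensity(g, matrix(FALSE, 31, 31)),
                 "empty mask")
  expect_identical(b0, 0)
})

test_that("max pixel subtracts the out-of-mask background and matches a
           direct scan", {
  m <- default_disk_mask()
  expect_equal(max_pixel(matrix(3, 31, 31), m), 0)

  x <- matrix(10, 31, 31); x[16, 16] <- 250
  expect_equal(max_pixel(x, m), 240)

  for (seed in 1:5) {
    g <- random_cell_grid(seed = seed)
    bg <- estimate_background(g, m)
    expect_equal(max_pixel(g, m), max(max(g[m]) - bg, 0), tolerance = 1e-12)
    # shift invariance under the constant-background policy
    expect_equal(max_pixel(g + 11.3, m), max_pixel(g, m), tolerance = 1e-9)
    expect_equal(max_pixel(2.5 * g, m), 2.5 * max_pixel(g, m),
                 tolerance = 1e-9)
  }
})

test_that("MCP matches the distance-transform binning oracle and honors its
           geometric contracts", {
  m <- default_disk_mask(31, 12)
  center <- matrix(0, 31, 31); center[16, 16] <- 100
  expect_lte(max_contour_position(center, m), 1 / 8)

  ctr <- 16
  d2 <- outer((seq_len(31) - ctr)^2, (seq_len(31) - ctr)^2, "+")
  rim <- ifelse(d2 <= 12^2 & d2 > 11^2, 100, 0)
  expect_gte(max_contour_position(rim, m), 1 - 1 / 8)

  for (seed in 1:5) {
    g <- random_cell_grid(seed = seed)
    expect_equal(max_contour_position(g, m), oracle_mcp(g, m),
                 tolerance = 1e-12)
    # scale invariance and 90-degree rotation invariance
    expect_equal(max_contour_position(5 * g, m), max_contour_position(g, m))
    rot <- t(g)[, rev(seq_len(31))]
    mrot <- t(m)[, rev(seq_len(31))]
    expect_equal(max_contour_position(rot, mrot), max_contour_position(g, m))
  }
  expect_warning(v <- max_contour_position(center, matrix(FALSE, 31, 31)),
                 "empty mask")
  expect_true(is.na(v))
})

test_that("BDS is the Fisher-z of the bright-detail correlation, symmetric,
           and invariant to affine rescaling", {
  m <- default_disk_mask()
  set.seed(11)
  a <- random_cell_grid(seed = 21)
  b <- random_cell_grid(seed = 22)
  expect_equal(bright_detail_similarity(a, b, m), oracle_bds(a, b, m),
               tolerance = 1e-12)
  expect_equal(bright_detail_similarity(a, b, m),
               bright_detail_similarity(b, a, m))
  expect_equal(bright_detail_similarity(2 * a + 7, b, m),
               bright_detail_similarity(a, b, m), tolerance = 1e-9)
  # identical non-constant input: r = 1 clipped at 0.999 -> z ~ 3.8
  expect_equal(bright_detail_similarity(a, a, m), atanh(0.999),
               tolerance = 1e-12)
  # a hand-sized fixed case against the closed formula
  small_a <- matrix(c(1, 5, 2, 8, 3, 9, 4, 7, 6, 2, 8, 1, 5, 3, 7, 4,
                      2, 6, 9, 1, 3, 8, 5, 2, 7), 5, 5)
  small_b <- matrix(c(2, 4, 1, 9, 2, 8, 5, 6, 7, 3, 9, 2, 4, 2, 8, 5,
                      1, 7, 8, 2, 4, 7, 6, 3, 6), 5, 5)
  m5 <- matrix(TRUE, 5, 5)
  ta <- oracle_bright_detail(small_a, 1)[m5]
  tb <- oracle_bright_detail(small_b, 1)[m5]
  r <- stats::cor(ta, tb)
  expect_equal(bright_detail_similarity(small_a, small_b, m5, radius = 1),
               0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  # zero variance flags 0; tiny masks are missing
  expect_equal(bright_detail_similarity(matrix(1, 31, 31), b, m), 0)
  tiny <- matrix(FALSE, 31, 31); tiny[1, 1:2] <- TRUE
  expect_warning(v <- bright_detail_similarity(a, b, tiny), "< 3 pixels")
  expect_true(is.na(v))
})

test_that("morphology mask keeps everything inside the outermost contour", {
  expect_warning(m0 <- morphology_mask(matrix(0, 15, 15)), "all-zero")
  expect_false(any(m0))

  side <- 31; ctr <- 16
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+")
  annulus <- ifelse(d2 <= 12^2 & d2 > 9^2, 100, 0)
  m <- morphology_mask(annulus, method = "fixed", threshold = 50)
  expect_true(all(m[d2 <= 12^2])) # hole filled
  expect_false(any(m[d2 > 12.6^2]))

  for (seed in 1:5) {
    g <- random_cell_grid(seed = seed)
    thr <- EBImage::otsu(g / max(g), range = c(0, 1)) * max(g)
    got <- morphology_mask(g)
    expect_identical(which(got), which(oracle_morphology_mask(g, thr)))
  }
})

test_that("adaptive erosion retains the requested area fraction and nests by
           percent", {
  disk <- default_disk_mask(41, 15)
  full <- adaptive_erode_mask(disk, 100)
  expect_identical(which(full), which(disk))

  m78 <- adaptive_erode_mask(disk, 78)
  ratio <- sum(m78) / sum(disk)
  expect_gte(ratio, 0.78)
  one_more <- oracle_binary_erode(m78)
  expect_lt(sum(one_more) / sum(disk), 0.78)
  expect_identical(which(m78), which(oracle_adaptive_erode(disk, 78)))

  core <- adaptive_erode_mask(disk, 0)
  expect_gt(sum(core), 0)
  expect_identical(which(core), which(oracle_adaptive_erode(disk, 0)))

  # nesting in percent, and subset of base
  prev <- disk
  for (p in c(90, 60, 30, 0)) {
    mp <- adaptive_erode_mask(disk, p)
    expect_true(all(!mp | prev)) # mp subset of previous (larger percent)
    prev <- mp
  }
  expect_warning(e <- adaptive_erode_mask(matrix(FALSE, 9, 9), 50),
                 "empty base")
  expect_false(any(e))
})

test_that("staining area isolates compact bright staining and saturates for
           diffuse signal", {
  m <- default_disk_mask(31, 12)
  side <- 31
  # subpixel punctum center, as acquisition produces
  d2 <- outer((seq_len(side) - 14.4)^2, (seq_len(side) - 14.6)^2, "+")
  punc <- 300 * exp(-d2 / (2 * 0.75^2))
  a <- staining_area(punc, m)
  expect_gte(a, 2)
  expect_lte(a, 12)
  diffuse <- ifelse(default_disk_mask(31, 12), 80, 0) +
    matrix(abs(rnorm(31^2, 0, 2)), 31, 31)
  expect_gt(staining_area(diffuse, m), 0.9 * sum(m))
  expect_identical(staining_area(matrix(0, 31, 31), m), 0L)
})

test_that("features computed singly and in batch are identical", {
  p <- scene_params(noise_sd = 4)
  s <- simulate_sample(12, mix = population_mix(0.5, 0.1, 0.1),
                       params = p, seed = 5)
  cfg <- gating_config("tec")
  batch <- compute_features(s, cfg)
  single <- dplyr::bind_rows(lapply(seq_len(12), function(i) {
    compute_features(s$cells[[i]], cfg)
  }))
  single$cell_id <- batch$cell_id
  expect_equal(as.data.frame(batch), as.data.frame(single), tolerance = 1e-12)
})

test_that("batched features equal their single-operator oracle calls", {
  p <- scene_params(noise_sd = 4)
  s <- simulate_sample(20, mix = population_mix(0.4, 0.15, 0.15),
                       params = p, seed = 31)
  cfg <- gating_config("tec")
  f <- compute_features(s, cfg)
  for (i in c(1, 7, 13, 20)) {
    img <- s$cells[[i]]
    morph <- morphology_mask(img$channels$BF)
    er <- adaptive_erode_mask(morph, 78)
    bg <- estimate_background(img$channels$PLA, morph)
    expect_equal(f$morph_area[i], sum(morph))
    expect_equal(f$erode_area[i], sum(er))
    expect_equal(f$PLA_bdi[i], bright_detail_intensity(img$channels$PLA, morph),
                 tolerance = 1e-12)
    expect_equal(f$PLA_max_pixel[i],
                 max_pixel(img$channels$PLA, morph, background = bg),
                 tolerance = 1e-12)
    expect_equal(f$PLA_mcp[i], max_contour_position(img$channels$PLA, morph),
                 tolerance = 1e-12)
    expect_equal(f$PLA_area[i],
                 staining_area(img$channels$PLA, morph, background = bg))
    expect_equal(f$PLA_bdi_erode[i],
                 bright_detail_intensity(img$channels$PLA, er),
                 tolerance = 1e-12)
    expect_equal(f$PLA_max_pixel_erode[i],
                 max_pixel(img$channels$PLA, er, background = bg),
                 tolerance = 1e-12)
    expect_equal(f$bds_PLA_CD80[i],
                 bright_detail_similarity(img$channels$PLA,
                                          img$channels$CD80, er),
                 tolerance = 1e-12)
    expect_equal(f$CD80_total[i],
                 total_intensity(img$channels$CD80, morph), tolerance = 1e-12)
  }
})
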