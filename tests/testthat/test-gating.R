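# The gating cascade: population assignment, the probes-only PLA gate, the
# localization and BDS false-positive filters, and the audit trail.

fixture_cfg <- gating_config("tec")

test_that("population gating follows the marker intensities", {
  f <- tibble::tibble(cell_id = 1:4,
                      morph_area = 400L,
                      CD45_total = c(2e5, 100, 50, 0),
                      CD80_total = c(1e3, 2e5, 1e4, 0))
  g <- gate_population(f, fixture_cfg)
  expect_identical(g$population,
                   c("CONTROL_POP", "TARGET_HI", "TARGET_LO", "UNASSIGNED"))
})

test_that("bimodal marker intensities are split into hi/lo matching the
           planted populations", {
  p <- scene_params()
  s <- simulate_sample(400, mix = population_mix(f_pos = 0.2), params = p,
                       seed = 41)
  cfg <- gating_config("tec")
  cfg$population$hi_policy <- list(method = "split2")
  f <- gate_population(compute_features(s, cfg), cfg)
  agree <- mean(f$population == s$truth$population)
  expect_gte(agree, 0.99)
})

test_that("the PLA threshold reproduces the sorted-array percentile and is
           monotone in the percentile", {
  vals <- tibble::tibble(PLA_bdi = as.numeric(1:100),
                         PLA_max_pixel = as.numeric(100:1),
                         PLA_bdi_erode = 0, PLA_max_pixel_erode = 0)
  th <- set_pla_threshold(vals, percentile = 95, pla_channel = "PLA")
  expect_equal(th$bdi_cut, oracle_percentile(1:100, 0.95))
  expect_equal(th$max_pixel_cut, oracle_percentile(100:1, 0.95))

  cuts <- vapply(c(50, 80, 95, 99.5),
                 function(p) set_pla_threshold(vals, percentile = p,
                                               pla_channel = "PLA")$bdi_cut,
                 numeric(1))
  expect_true(all(diff(cuts) >= 0))

  zero <- tibble::tibble(PLA_bdi = rep(0, 50), PLA_max_pixel = rep(0, 50),
                         PLA_bdi_erode = 0, PLA_max_pixel_erode = 0)
  th0 <- set_pla_threshold(zero, percentile = 99.5, pla_channel = "PLA")
  expect_identical(th0$bdi_cut, 0)
  expect_error(set_pla_threshold(vals[0, ], percentile = 99.5,
                                 pla_channel = "PLA"), "empty")
})

test_that("the localization filter separates the planted signal classes", {
  p <- scene_params()
  cfg <- gating_config("tec")
  one_class <- function(class, n, seed) {
    mix <- tibble::tibble(population = "TARGET_HI", class = class, prop = 1)
    simulate_sample(n, mix = mix, params = p, seed = seed)
  }
  po <- simulate_probes_only(150, params = p, seed = 50)
  th <- set_pla_threshold(compute_features(po, cfg), cfg)

  nuc <- one_class("NUCLEAR_PLA_POS", 40, 51)
  f_nuc <- compute_features(nuc, cfg)
  loc_nuc <- localization_filter(f_nuc, cfg, th)
  expect_gte(mean(loc_nuc$localization_pass), 0.9)

  mem <- one_class("MEMBRANAL_FP", 40, 52)
  f_mem <- compute_features(mem, cfg)
  loc_mem <- localization_filter(f_mem, cfg, th)
  expect_lte(mean(loc_mem$localization_pass), 0.05)
  # membranal signal sits outside the eroded interior and at high MCP
  expect_lte(mean(loc_mem$interior_pass & loc_mem$mcp_pass), 0.05)

  dif <- one_class("DIFFUSE_AF", 40, 53)
  f_dif <- compute_features(dif, cfg)
  loc_dif <- localization_filter(f_dif, cfg, th)
  # diffuse autofluorescence fails on the staining-area range
  expect_lte(mean(loc_dif$area_pass), 0.05)
})

test_that("the BDS filter excludes channel-bleed cells and keeps independent
           patterns", {
  cfg <- gating_config("tec")
  p_copy <- scene_params(neighbor_mode = "copy")
  p_ind <- scene_params(neighbor_mode = "independent")
  mix <- tibble::tibble(population = "TARGET_HI", class = "NUCLEAR_PLA_POS",
                        prop = 1)
  bleed <- simulate_sample(40, mix = mix, params = p_copy, seed = 61)
  f_bleed <- compute_features(bleed, cfg)
  expect_true(all(f_bleed$bds_PLA_CD80 > 1.5))
  expect_false(any(bds_filter(f_bleed, cfg)))

  ind <- simulate_sample(40, mix = mix, params = p_ind, seed = 62)
  f_ind <- compute_features(ind, cfg)
  expect_gte(mean(bds_filter(f_ind, cfg)), 0.95)

  # cutoff +Inf disables the filter
  expect_true(all(bds_filter(f_bleed, cfg, cutoff = Inf)))
})

test_that("the pipeline recovers a planted positive fraction and keeps a
           complete audit trail", {
  p <- scene_params()
  s <- simulate_sample(500, mix = population_mix(f_pos = 0.25), params = p,
                       seed = 71)
  po <- simulate_probes_only(200, params = p, seed = 72)
  res <- run_pipeline(list(rep1 = s), po, fixture_cfg)
  calls <- tidy(res)

  # final = conjunction of the enabled gates
  expect_identical(
    calls$final_pla_pos[calls$population != "UNASSIGNED"],
    (calls$pla_raw_pos & calls$localization_pass &
       calls$bds_pass)[calls$population != "UNASSIGNED"])

  # monotone cascade: each filter only shrinks the positive set
  expect_true(all(calls$final_pla_pos <= calls$pla_raw_pos,
                  na.rm = TRUE))

  # every excluded cell carries at least one failure reason, and counts
  # reconcile
  excluded <- !calls$final_pla_pos | is.na(calls$final_pla_pos)
  expect_true(all(nzchar(calls$reasons[excluded])))
  expect_true(all(calls$reasons[!excluded] == ""))
  expect_identical(sum(calls$final_pla_pos, na.rm = TRUE) + sum(excluded),
                   nrow(calls))

  # recovery: estimate near the planted fraction in TARGET_HI
  hi <- dplyr::filter(glance(res), .data$population == "TARGET_HI")
  truth_f <- mean(s$truth$class[s$truth$population == "TARGET_HI"] ==
                    "NUCLEAR_PLA_POS")
  expect_lt(abs(hi$pct_pla_pos / 100 - truth_f), 0.05)
})

test_that("the final positive set is invariant to filter order", {
  p <- scene_params()
  s <- simulate_sample(150, mix = population_mix(0.3, 0.1, 0.1), params = p,
                       seed = 81)
  po <- simulate_probes_only(120, params = p, seed = 82)
  cfg_a <- gating_config("tec", filters = c("localization", "bds"))
  cfg_b <- gating_config("tec", filters = c("bds", "localization"))
  res_a <- run_pipeline(s, po, cfg_a)
  res_b <- run_pipeline(s, po, cfg_b)
  expect_identical(tidy(res_a)$final_pla_pos, tidy(res_b)$final_pla_pos)
})

test_that("the reduced cascade applies only the raw PLA gate", {
  p <- scene_params()
  s <- simulate_sample(120, mix = population_mix(0, 0.4, 0.2), params = p,
                       seed = 91)
  po <- simulate_probes_only(120, params = p, seed = 92)
  res <- run_pipeline(s, po, gating_config("bmdm"))
  calls <- tidy(res)
  expect_identical(calls$final_pla_pos[calls$population != "UNASSIGNED"],
                   calls$pla_raw_pos[calls$population != "UNASSIGNED"])
})

test_that("a knockout-like scenario is cleaned up by the filters", {
  p <- scene_params()
  ko_mix <- dplyr::bind_rows(
    tibble::tibble(population = "TARGET_HI",
                   class = c("MEMBRANAL_FP", "DIFFUSE_AF", "NEGATIVE"),
                   prop = c(0.4, 0.2, 0.1)),
    tibble::tibble(population = "CONTROL_POP", class = "NEGATIVE",
                   prop = 0.3))
  s <- simulate_sample(400, mix = ko_mix, params = p, seed = 101)
  po <- simulate_probes_only(200, params = p, seed = 102)
  res <- run_pipeline(s, po, fixture_cfg)
  calls <- tidy(res)
  hi <- calls$population == "TARGET_HI"
  raw_rate <- mean(calls$pla_raw_pos[hi])
  post_rate <- mean(calls$final_pla_pos[hi])
  expect_gt(raw_rate, 0.10)
  expect_lt(post_rate, 0.02)
})

test_that("gating config validation and YAML round trip", {
  expect_error(gating_config(control_percentile = 100), "control_percentile")
  expect_error(gating_config(adaptive_erode_percent = 101), "adaptive_erode")
  cfg <- gating_config("tec", mcp_max = 0.5, bds_cutoff = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_config(cfg, path)
  back <- read_gating_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
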