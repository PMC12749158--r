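test_that("count simulation is a pure function of config and seed", {
  cfg <- sim_config(n_genes = 200, n_animals = 3, seed = 5)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_counts(sim_config(n_genes = 200, n_animals = 3, seed = 6))
  expect_false(identical(a$counts, c$counts))
})

test_that("simulated design is strictly paired and class fractions hold", {
  cfg <- sim_config(n_genes = 1000, n_animals = 4, frac_met = 0.15,
                    frac_hum = 0.1, frac_synergy = 0.2, seed = 2)
  sim <- simulate_counts(cfg)
  expect_equal(ncol(sim$counts), 16L)
  sets <- build_paired_sets(sim$sheet)
  expect_equal(nrow(sets), 4L)
  expect_equal(unname(table(sim$truth$class)[c("metabolic", "humoral",
                                               "synergistic")]),
               c(150L, 100L, 200L), ignore_attr = TRUE)
  # truth table log2 fold changes are consistent with the coefficients
  expect_equal(sim$truth$log2fc_all,
               sim$truth$beta_met + sim$truth$beta_hum + sim$truth$gamma)
})

test_that("KO/EC profiles carry no humoral effect and no interaction", {
  for (prof in c("KO_VSMC", "EC")) {
    cfg <- sim_config(n_genes = 500, cell_profile = prof,
                      frac_hum = 0.3, frac_synergy = 0.3, seed = 3)
    expect_equal(cfg$frac_hum, 0)
    expect_equal(cfg$frac_synergy, 0)
    sim <- simulate_counts(cfg)
    expect_true(all(sim$truth$beta_hum == 0))
    expect_true(all(sim$truth$gamma == 0))
  }
  expect_error(sim_config(frac_met = 0.7, frac_hum = 0.4), "fractions")
})

test_that("null simulation gives nominal CI coverage of 1", {
  cfg <- sim_config(n_genes = 3000, n_animals = 4, frac_met = 0,
                    frac_hum = 0, frac_synergy = 0, seed = 8)
  sim <- simulate_counts(cfg)
  fpm <- compute_fpm(sim$counts)
  sets <- build_paired_sets(sim$sheet)
  eff <- paired_effect_table(fpm, sets, "ALL", level = 0.95)
  keep <- rowMeans(fpm[, sets$CTRL]) > 5  # stay clear of zero-dropouts
  rate <- mean(eff$excludes_one[keep])
  # 3 Monte-Carlo standard errors around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / sum(keep)) + 0.01)
})

test_that("synergy-index recovery matches the generative interaction", {
  cfg <- sim_config(n_genes = 4000, n_animals = 4, frac_synergy = 0.2,
                    interaction_log2 = 1.0, seed = 12)
  sim <- simulate_counts(cfg)
  fpm <- compute_fpm(sim$counts)
  sets <- build_paired_sets(sim$sheet)
  fc <- function(cond) paired_de_test(fpm, sets, cond)$log2fc
  si <- synergy_index(fc("ALL"), additive_prediction(fc("MET"), fc("HUM")))
  syn <- sim$truth$class == "synergistic" &
    rowMeans(fpm[, sets$CTRL]) > 5
  # orient by the sign of the true interaction
  oriented <- si[syn] * sign(sim$truth$gamma[syn])
  expect_equal(mean(oriented, na.rm = TRUE), 1.0, tolerance = 0.1)
  nul <- sim$truth$class == "null" & rowMeans(fpm[, sets$CTRL]) > 5
  expect_equal(mean(si[nul], na.rm = TRUE), 0, tolerance = 0.05)
})

test_that("cell-object simulation exercises the filter and contracts", {
  sim <- simulate_cell_objects(500, contraction_factor = 0.2, seed = 4)
  expect_identical(simulate_cell_objects(500, contraction_factor = 0.2,
                                         seed = 4)$before, sim$before)
  # some objects must fall outside the analysis window
  expect_lt(nrow(filter_cells(sim$before)), nrow(sim$before))
  expect_gt(nrow(filter_cells(sim$before)), 0)
  mb <- median(circularity(sim$before$area_um2, sim$before$perimeter_um))
  ma <- median(circularity(sim$after$area_um2, sim$after$perimeter_um))
  expect_gt(ma, mb)
  none <- simulate_cell_objects(100, contraction_factor = 0, seed = 4)
  expect_identical(none$before, none$after)
})

test_that("DAPI simulation produces the stated mixture geometry", {
  uni <- simulate_dapi(500, fractions = c(1, 0, 0), cv = 0.05, seed = 1)
  expect_true(all(uni$phase == "G1"))
  expect_equal(median(uni$dapi_integral), 1e5, tolerance = 0.02)
  spikes <- simulate_dapi(1000, fractions = c(0.5, 0, 0.5), cv = 0,
                          seed = 1)
  expect_equal(sort(unique(spikes$dapi_integral)), c(1e5, 2e5),
               tolerance = 1e-9)
  expect_error(simulate_dapi(10, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("noiseless OCR traces invert exactly through ocr_params", {
  trace <- simulate_ocr_trace(br = 80, pl = 20, nmoc = 20, max_ocr = 160,
                              noise_sd = 0, seed = 1)
  p <- ocr_params(trace)
  expect_equal(p$br, 80)
  expect_equal(p$pl, 20)
  expect_equal(p$nmoc, 20)
  expect_equal(p$max_ocr, 160)
  # noisy recovery stays near the inputs
  noisy <- ocr_params(simulate_ocr_trace(80, 20, 20, 160, noise_sd = 2,
                                         seed = 2))
  expect_equal(noisy$br, 80, tolerance = 0.1)
  # pathological configuration propagates to the flag
  odd <- ocr_params(simulate_ocr_trace(br = 10, pl = 40, nmoc = 20,
                                       max_ocr = 100, seed = 3))
  expect_true("proton_leak_exceeds_basal" %in% odd$flags)
  expect_error(simulate_ocr_trace(-1, 0, 0, 0), "non-negative")
})

test_that("track simulation matches its speed parameterization", {
  still <- simulate_tracks(20, speed_um_h = 0, n_frames = 3, dt_h = 2,
                           seed = 5)
  tr <- link_tracks(still, max_step = 1)
  for (id in unique(tr$track_id)) {
    expect_equal(displacement_rate(tr[tr$track_id == id, ], 0, 4), 0)
  }
  # straight-line motion at v gives displacement_rate exactly v
  directed <- simulate_tracks(10, speed_um_h = 7, n_frames = 3, dt_h = 2,
                              mode = "directed", seed = 6)
  trd <- link_tracks(directed, max_step = 50)
  rates <- vapply(unique(trd$track_id), function(id) {
    displacement_rate(trd[trd$track_id == id, ], 0, 4)
  }, numeric(1))
  expect_equal(unname(rates), rep(7, 10), tolerance = 1e-9)
  # random walk: mean per-frame step speed near the target
  rw <- simulate_tracks(300, speed_um_h = 10, n_frames = 2, dt_h = 2,
                        seed = 7)
  trw <- link_tracks(rw, max_step = 1e4)
  step <- vapply(unique(trw$track_id), function(id) {
    displacement_rate(trw[trw$track_id == id, ], 0, 2)
  }, numeric(1))
  expect_equal(mean(step), 10, tolerance = 0.6)
})
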