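test_that("circularity follows the shape formula and clips at 1", {
  expect_equal(circularity(pi, 2 * pi), 1)           # unit circle
  expect_equal(circularity(1, 4), pi / 4)            # unit square
  expect_warning(c_over <- circularity(pi * 1.01, 2 * pi), "clipped")
  expect_equal(c_over, 1)
  expect_error(circularity(-1, 4), "positive")
  expect_error(circularity(1, 0), "positive")
})

test_that("ellipse circularity is scale-invariant and near 0.26 at ratio 9.1", {
  # numeric oracle: Ramanujan perimeter evaluated directly
  r <- 9.1
  a <- r; b <- 1
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_equal(ellipse_circularity(9.1), 4 * pi * (pi * a * b) / p^2)
  expect_equal(ellipse_circularity(9.1), 0.26, tolerance = 0.01)
  # scaling both axes leaves circularity unchanged
  for (k in c(0.5, 2, 10)) {
    area <- pi * (k * a) * (k * b)
    perim <- pi * (3 * (k * a + k * b) -
                     sqrt((3 * k * a + k * b) * (k * a + 3 * k * b)))
    expect_equal(circularity(area, perim), ellipse_circularity(r))
  }
})

test_that("ellipse circularity strictly decreases with aspect ratio", {
  ratios <- seq(1, 20, by = 0.25)
  vals <- ellipse_circularity(ratios)
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("object filter keeps single-nucleus cells within the area window", {
  obj <- data.frame(area_um2 = c(1000, 300, 1000, 4200, 400, 4000),
                    n_nuclei = c(1L, 1L, 2L, 1L, 1L, 1L))
  kept <- filter_cells(obj)
  expect_equal(kept$area_um2, c(1000, 400, 4000))
})

test_that("contraction index is the relative change of median circularity", {
  mk <- function(circ) {
    # squares scaled to hit a target circularity are impossible; use
    # ellipses: perimeter from area and target circularity
    area <- rep(1000, 5)
    per <- sqrt(4 * pi * area / circ)
    data.frame(area_um2 = area, perimeter_um = per, n_nuclei = 1L)
  }
  res <- contractility_assay(mk(0.26), mk(0.37))
  expect_equal(res$median_before, 0.26)
  expect_equal(res$median_after, 0.37)
  expect_equal(res$contraction_index, (0.37 - 0.26) / 0.26)

  same <- contractility_assay(mk(0.3), mk(0.3))
  expect_equal(same$contraction_index, 0)
  relaxed <- contractility_assay(mk(0.4), mk(0.3))
  expect_lt(relaxed$contraction_index, 0)
  expect_error(contractility_assay(mk(0.3)[0, ], mk(0.3)), "empty")
})

test_that("contraction model raises circularity under shortening", {
  r <- calibrate_aspect_ratio(0.26)
  expect_equal(ellipse_circularity(r), 0.26, tolerance = 1e-9)

  no_short <- contraction_model(r, 0)
  expect_equal(no_short$circ_after, no_short$circ_before)

  for (mode in c("volume_conserving_3d", "area_conserving_2d",
                 "width_constant")) {
    m <- contraction_model(r, 0.2, mode)
    expect_gt(m$circ_after, m$circ_before)
  }
  vol <- contraction_model(r, 0.2, "volume_conserving_3d")
  expect_gt(vol$circ_after, 0.33)
  expect_lt(vol$circ_after, 0.41)

  # a circle stays round under symmetric widening (axis-swap handling)
  circ_area <- contraction_model(1, 0.2, "area_conserving_2d")
  expect_equal(circ_area$aspect_ratio_after,
               (1 / 0.8) / 0.8, tolerance = 1e-12)
  width <- contraction_model(1, 0.2, "width_constant")
  expect_lt(width$circ_after, 1)
  expect_error(contraction_model(0.5, 0.2), "aspect_ratio")
})

test_that("cell-cycle gating recovers a known mixture", {
  sim <- simulate_dapi(5000, fractions = c(0.6, 0.2, 0.2), cv = 0.05,
                       seed = 99)
  gates <- gate_cell_cycle(sim$dapi_integral)
  expect_equal(sum(gates$fractions), 1)
  expect_equal(unname(gates$fractions["G1"]), 0.6, tolerance = 0.03)
  expect_equal(unname(gates$fractions["S"]), 0.2, tolerance = 0.03)
  expect_equal(unname(gates$fractions["G2"]), 0.2, tolerance = 0.03)
  expect_equal(gates$g1_mode, 1e5, tolerance = 0.05)

  # degenerate: every nucleus exactly at the mode
  suppressWarnings(spike <- gate_cell_cycle(rep(7, 10)))
  expect_equal(unname(spike$fractions), c(1, 0, 0))
  expect_error(gate_cell_cycle(numeric(0)), "no usable")
  expect_warning(gate_cell_cycle(rlnorm(50, log(10), 0.05)), "fewer than 100")
})

test_that("BrdU threshold derives from the negative control", {
  set.seed(41)
  neg <- rnorm(5000, 100, 10)
  # sample identical to the control: positivity ~ 1 - quantile
  same <- brdu_call(neg, neg, quantile = 0.99)
  expect_equal(same$positive_fraction, 0.01, tolerance = 0.003)
  # everything above the control maximum
  expect_equal(brdu_call(neg + 200, neg)$positive_fraction, 1)
  # 30% of nuclei shifted +10 sd
  lab <- c(rnorm(3500, 100, 10), rnorm(1500, 200, 10))
  mix <- brdu_call(lab, neg)
  expect_equal(mix$positive_fraction, 0.3 + 0.7 * 0.01, tolerance = 0.02)
  expect_error(brdu_call(numeric(0), neg), "empty")
})

test_that("lipid score is the printed product over nuclei", {
  obj <- data.frame(mean_intensity = rep(10, 5), area_um2 = rep(100, 5))
  expect_equal(lipid_score(obj, 50), 100)
  expect_equal(lipid_score(obj[0, ], 50), 0)
  expect_equal(lipid_score(rbind(obj, obj), 50), 2 * lipid_score(obj, 50))
  expect_error(lipid_score(obj, 0), "positive")
})

test_that("lipid compartments split by distance to the nucleus boundary", {
  nuclei <- data.frame(x_um = c(0, 100), y_um = c(0, 0),
                       area_um2 = pi * 5^2)  # equivalent radius 5
  at_centroids <- data.frame(mean_intensity = 10, area_um2 = 20,
                             x_um = c(0, 100), y_um = c(0, 0))
  res <- lipid_compartments(at_centroids, nuclei)
  expect_equal(res$peripheral_score, 0)
  expect_gt(res$perinuclear_score, 0)

  far <- data.frame(mean_intensity = 10, area_um2 = 20,
                    x_um = c(50, 50), y_um = c(40, -40))
  res2 <- lipid_compartments(far, nuclei)
  expect_equal(res2$perinuclear_score, 0)
  expect_gt(res2$peripheral_score, 0)

  half <- rbind(at_centroids, far)
  res3 <- lipid_compartments(half, nuclei)
  expect_equal(res3$n_perinuclear, 2L)
  expect_equal(res3$n_peripheral, 2L)
  expect_error(lipid_compartments(far, nuclei[0, ]), "empty nuclei")
})

test_that("OCR parameters reproduce the hand-evaluated example", {
  trace <- data.frame(
    time_min = 1:8,
    ocr = c(100, 100, 40, 45, 180, 170, 20, 25),
    phase = rep(c("baseline", "oligomycin", "fccp", "rot_aa"), each = 2))
  p <- ocr_params(trace)
  expect_equal(p$nmoc, 20)
  expect_equal(p$br, 80)
  expect_equal(p$pl, 20)
  expect_equal(p$atp_ocr, 60)
  expect_equal(p$max_ocr, 160)
  expect_equal(p$coupling_methods, 0.6)
  expect_equal(p$coupling_results, 0.75)
  expect_equal(p$utilization, 0.5)
  expect_length(p$flags, 0)
})

test_that("OCR algebra identities hold and degeneracies are flagged", {
  set.seed(6)
  for (i in 1:10) {
    lv <- sort(runif(4, 10, 200))  # rotaa < oligo < baseline < fccp
    trace <- data.frame(time_min = 1:4,
                        ocr = c(lv[3], lv[2], lv[4], lv[1]),
                        phase = c("baseline", "oligomycin", "fccp",
                                  "rot_aa"))
    p <- ocr_params(trace)
    expect_equal(p$br + p$nmoc, p$ocr_baseline)
    expect_equal(p$atp_ocr + p$pl, p$br)
    expect_gte(p$coupling_methods, 0)
    expect_lte(p$coupling_methods, 1)
  }
  # perfect coupling: proton leak zero
  perfect <- ocr_params(data.frame(time_min = 1:4,
                                   ocr = c(100, 20, 180, 20),
                                   phase = c("baseline", "oligomycin",
                                             "fccp", "rot_aa")))
  expect_equal(perfect$atp_ocr, perfect$br)
  expect_equal(perfect$coupling_results, 1)
  # flat trace: no basal respiration
  flat <- ocr_params(data.frame(time_min = 1:4, ocr = rep(50, 4),
                                phase = c("baseline", "oligomycin", "fccp",
                                          "rot_aa")))
  expect_true("non_positive_basal_respiration" %in% flat$flags)
  expect_error(ocr_params(data.frame(time_min = 1, ocr = 1,
                                     phase = "baseline")),
               "missing phase")
})

test_that("track linking preserves identities and handles the 3-4-5 step", {
  frames <- data.frame(time_h = c(0, 1), x_um = c(0, 3), y_um = c(0, 4))
  tr <- link_tracks(frames, max_step = 10)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(displacement_rate(tr, 0, 1), 5)

  # stationary nuclei: zero displacement
  still <- data.frame(time_h = rep(c(0, 2), each = 3),
                      x_um = rep(c(10, 50, 90), 2),
                      y_um = rep(c(5, 5, 5), 2))
  ts <- link_tracks(still, max_step = 10)
  expect_equal(length(unique(ts$track_id)), 3L)
  for (id in unique(ts$track_id)) {
    expect_equal(displacement_rate(ts[ts$track_id == id, ], 0, 2), 0)
  }

  # two nuclei pass each other with separation >> step size
  crossing <- rbind(
    data.frame(time_h = 0, x_um = c(0, 100), y_um = c(0, 0)),
    data.frame(time_h = 1, x_um = c(10, 90), y_um = c(0, 0)),
    data.frame(time_h = 2, x_um = c(20, 80), y_um = c(0, 0)))
  tc <- link_tracks(crossing, max_step = 15)
  expect_equal(length(unique(tc$track_id)), 2L)
  t1 <- tc[tc$track_id == 1L, ]
  expect_equal(t1$x_um, c(0, 10, 20))

  # links beyond the cap start new tracks
  jump <- data.frame(time_h = c(0, 1), x_um = c(0, 500), y_um = c(0, 0))
  tj <- link_tracks(jump, max_step = 50)
  expect_equal(length(unique(tj$track_id)), 2L)
  expect_error(link_tracks(frames[frames$time_h == 0, ], 10), "2 frames")
})

test_that("displacement rate is net, rotation- and translation-invariant", {
  loop <- data.frame(time_h = 0:4, x_um = c(0, 5, 5, 0, 0),
                     y_um = c(0, 0, 5, 5, 0))
  expect_equal(displacement_rate(loop, 0, 4), 0)
  straight <- data.frame(time_h = c(0, 2), x_um = c(0, 6), y_um = c(0, 8))
  expect_equal(displacement_rate(straight, 0, 2), 5)
  theta <- 0.7; shift <- c(12, -3)
  rot <- data.frame(time_h = c(0, 2),
                    x_um = cos(theta) * straight$x_um -
                      sin(theta) * straight$y_um + shift[1],
                    y_um = sin(theta) * straight$x_um +
                      cos(theta) * straight$y_um + shift[2])
  expect_equal(displacement_rate(rot, 0, 2), 5)
  expect_error(displacement_rate(straight, 2, 0), "after")
})

test_that("metabolic fluxes and the glycolytic index follow stoichiometry", {
  # fully glycolytic: 2 lactate per glucose
  f <- metabolic_fluxes(20, 18, 1, 5, protein = 1)
  expect_equal(f$consumption, 2)
  expect_equal(f$production, 4)
  expect_equal(f$glycolytic_index, 1)
  expect_equal(metabolic_fluxes(20, 18, 1, 1, 1)$glycolytic_index, 0)
  expect_equal(metabolic_fluxes(20, 18, 1, 3, 1)$glycolytic_index, 0.5)
  # per-protein normalization
  f2 <- metabolic_fluxes(20, 18, 1, 5, protein = 2)
  expect_equal(f2$consumption, 1)
  neg <- metabolic_fluxes(20, 21, 1, 5, 1)
  expect_true(is.na(neg$glycolytic_index))
  expect_true("non_positive_glucose_consumption" %in% neg$flags)
  expect_error(metabolic_fluxes(20, 18, 1, 5, 0), "positive")
})

test_that("normalized rate is the protein-scaled slope", {
  expect_equal(normalized_rate(100, 160, 30, 60, 2), 1)
  expect_equal(normalized_rate(100, 100, 30, 60, 2), 0)
  expect_lt(normalized_rate(160, 100, 30, 60, 2), 0)
  expect_error(normalized_rate(1, 2, 60, 30, 1), "after")
})

test_that("nuclear/perinuclear ratio subtracts background first", {
  expect_equal(nuclear_perinuclear_ratio(30, 20, 10), 2)
  expect_equal(nuclear_perinuclear_ratio(25, 25, 5), 1)
  expect_equal(nuclear_perinuclear_ratio(10, 30, 0), 1 / 3)
  expect_warning(und <- nuclear_perinuclear_ratio(30, 10, 10), "background")
  expect_true(is.na(und))
})
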