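# Formula-defined quantitative assay readouts: cell shape and contraction,
# DAPI-integral cell-cycle gating, BrdU positivity, lipid scores,
# mito-stress-test OCR parameters, random motility, metabolic fluxes,
# caspase rates and nuclear/perinuclear ratios.

#' Cell circularity
#'
#' `C = 4 * pi * A / P^2`: 1 for a perfect circle, approaching 0 for
#' elongated shapes. Values marginally above 1 (impossible shapes from
#' discretized perimeters) are clipped to 1 with a warning.
#'
#' @param area Cell area(s), square micrometres.
#' @param perimeter Cell perimeter(s), micrometres.
#' @return Circularity in (0, 1], vectorized.
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive and finite")
  }
  C <- 4 * pi * area / perimeter^2
  if (any(C > 1 + 1e-9)) {
    warning(sum(C > 1 + 1e-9),
            " circularity value(s) > 1 clipped (segmentation noise)")
  }
  pmin(C, 1)
}

#' Filter segmented cell objects for analysis
#'
#' Keeps objects containing exactly one nucleus with an area between
#' 400 and 4000 square micrometres, removing debris and cell clumps.
#'
#' @param objects Data frame with columns `area_um2` and `n_nuclei`.
#' @param area_min,area_max Area bounds in square micrometres.
#' @return The filtered data frame.
#' @export
filter_cells <- function(objects, area_min = 400, area_max = 4000) {
  keep <- objects$n_nuclei == 1L & objects$area_um2 >= area_min &
    objects$area_um2 <= area_max
  objects[keep, , drop = FALSE]
}

#' Ionomycin contraction readout from before/after circularity
#'
#' Circularity is not normally distributed across cells, so the per-sample
#' median is the summary statistic; the contraction index is the relative
#' acute increase of the median circularity after the calcium ionophore.
#'
#' @param before,after Filtered object tables (see [filter_cells()]) with
#'   `area_um2` and `perimeter_um` columns, imaged before and after
#'   ionomycin addition.
#' @return List `median_before`, `median_after`, `contraction_index`
#'   (= (after - before) / before).
#' @export
contractility_assay <- function(before, after) {
  if (nrow(before) == 0L || nrow(after) == 0L) {
    stop("empty object table")
  }
  mb <- stats::median(circularity(before$area_um2, before$perimeter_um))
  ma <- stats::median(circularity(after$area_um2, after$perimeter_um))
  list(median_before = mb, median_after = ma,
       contraction_index = (ma - mb) / mb)
}

# Ramanujan's (first) approximation of the ellipse perimeter with
# semi-axes a, b.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Circularity of an ellipse with given aspect ratio
#'
#' Uses Ramanujan's perimeter approximation; scale-invariant, so only the
#' ratio of major to minor axis matters.
#'
#' @param aspect_ratio Major/minor axis ratio (>= 1), vectorized.
#' @return Circularity in (0, 1].
#' @export
ellipse_circularity <- function(aspect_ratio) {
  if (any(aspect_ratio < 1)) stop("aspect_ratio must be >= 1")
  a <- aspect_ratio
  b <- 1
  area <- pi * a * b
  circularity(area, ellipse_perimeter(a, b))
}

#' Aspect ratio of an ellipse with a given circularity
#'
#' Numeric inverse of [ellipse_circularity()], used to calibrate the
#' contraction model to an observed baseline circularity.
#'
#' @param circ Target circularity in (0, 1].
#' @param upper Search upper bound for the ratio.
#' @return Aspect ratio >= 1.
#' @export
calibrate_aspect_ratio <- function(circ, upper = 200) {
  if (circ <= 0 || circ > 1) stop("circ must be in (0, 1]")
  if (circ == 1) return(1)
  stats::uniroot(function(r) ellipse_circularity(r) - circ,
                 lower = 1, upper = upper, tol = 1e-12)$root
}

#' Ellipsoid model of circularity change under acute shortening
#'
#' Models the cell as an ellipse with major semi-axis `a` and minor
#' semi-axis `b`; contraction shortens `a` by `shortening_fraction` while
#' the width responds per `mode`: `area_conserving_2d` keeps the ellipse
#' area constant (`b' = b / (1 - s)`), `volume_conserving_3d` treats the
#' cell as a prolate ellipsoid of revolution with conserved volume and
#' isotropic widening (`b' = b / sqrt(1 - s)`), `width_constant` leaves
#' `b` unchanged. If shortening pushes the ratio below 1 the axes swap
#' (the former width becomes the long axis). Circularity uses Ramanujan's
#' perimeter approximation.
#'
#' @param aspect_ratio Resting major/minor axis ratio (>= 1).
#' @param shortening_fraction Fractional shortening of the long axis,
#'   in (0, 1).
#' @param mode One of `"volume_conserving_3d"` (default),
#'   `"area_conserving_2d"`, `"width_constant"`.
#' @return List `circ_before`, `circ_after`, `aspect_ratio_after`.
#' @export
contraction_model <- function(aspect_ratio, shortening_fraction,
                              mode = c("volume_conserving_3d",
                                       "area_conserving_2d",
                                       "width_constant")) {
  mode <- match.arg(mode)
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (shortening_fraction < 0 || shortening_fraction >= 1) {
    stop("shortening_fraction must lie in [0, 1)")
  }
  s <- shortening_fraction
  a <- aspect_ratio
  b <- 1
  a2 <- a * (1 - s)
  b2 <- switch(mode,
               area_conserving_2d = b / (1 - s),
               volume_conserving_3d = b / sqrt(1 - s),
               width_constant = b)
  ratio_after <- max(a2, b2) / min(a2, b2)
  list(circ_before = ellipse_circularity(a),
       circ_after = ellipse_circularity(ratio_after),
       aspect_ratio_after = ratio_after)
}

#' Gate nuclei into cell-cycle phases from DAPI integrals
#'
#' The nuclear DAPI integral (area x mean fluorescence) is a relative DNA
#' content: G1 nuclei cluster at a mode `m`, G2 nuclei at `2 m`, S-phase
#' nuclei bridge the two. The G1 mode is located as the kernel-density
#' maximum over the lower half of the distribution; gates are symmetric
#' windows of relative width `window` around `m` (G1) and `2 m` (G2) with
#' S in between. Nuclei below the G1 gate or above the G2 gate are
#' excluded as debris/aggregates; phase fractions are taken over the gated
#' nuclei and sum to 1.
#'
#' @param dapi_integrals Positive numeric vector of per-nucleus DAPI
#'   integrals.
#' @param window Full relative gate width (default 0.3, i.e. +/- 15%).
#' @return List of class `cycle_gates`: `g1_mode`, `boundaries` (b1 < b2 <
#'   b3 < b4), `fractions` (named G1/S/G2), `n_gated`, `n_excluded`.
#' @export
gate_cell_cycle <- function(dapi_integrals, window = 0.3) {
  x <- dapi_integrals[is.finite(dapi_integrals) & dapi_integrals > 0]
  if (length(x) == 0L) stop("no usable DAPI integrals")
  if (length(x) < 100L) {
    warning("fewer than 100 nuclei; phase fractions will be unstable")
  }
  lower <- x[x <= stats::median(x)]
  if (stats::sd(lower) == 0 || length(lower) < 2L) {
    m <- lower[1L]
  } else {
    d <- stats::density(lower)
    m <- d$x[which.max(d$y)]
  }
  h <- window / 2
  b <- c(m * (1 - h), m * (1 + h), 2 * m * (1 - h), 2 * m * (1 + h))
  g1 <- x >= b[1L] & x <= b[2L]
  s <- x > b[2L] & x < b[3L]
  g2 <- x >= b[3L] & x <= b[4L]
  n_gated <- sum(g1) + sum(s) + sum(g2)
  if (n_gated == 0L) stop("no nuclei fall inside the cell-cycle gates")
  structure(list(g1_mode = m, boundaries = b,
                 fractions = c(G1 = sum(g1), S = sum(s), G2 = sum(g2)) /
                   n_gated,
                 n_gated = n_gated, n_excluded = length(x) - n_gated),
            class = "cycle_gates")
}

#' @export
print.cycle_gates <- function(x, ...) {
  cat(sprintf(
    "Cell cycle: G1 mode %.3g; fractions G1 %.1f%% / S %.1f%% / G2 %.1f%% (%d gated, %d excluded)\n",
    x$g1_mode, 100 * x$fractions[["G1"]], 100 * x$fractions[["S"]],
    100 * x$fractions[["G2"]], x$n_gated, x$n_excluded))
  invisible(x)
}

#' Call BrdU-positive nuclei against a negative control
#'
#' The positivity threshold is derived from the antibody-free negative
#' control: by default its `quantile`-th quantile (0.99), alternatively
#' mean + 3 SD.
#'
#' @param nuclear_red_integrals Per-nucleus red-fluorescence integrals of
#'   the sample.
#' @param negative_control_integrals Same quantity from the negative
#'   control wells.
#' @param quantile Quantile of the negative control used as threshold.
#' @param method `"quantile"` (default) or `"mean_sd"` (mean + 3 SD).
#' @return List `threshold`, `positive_fraction`, `n_positive`, `n_total`.
#' @export
brdu_call <- function(nuclear_red_integrals, negative_control_integrals,
                      quantile = 0.99, method = c("quantile", "mean_sd")) {
  method <- match.arg(method)
  if (length(negative_control_integrals) == 0L ||
      length(nuclear_red_integrals) == 0L) {
    stop("empty input")
  }
  thr <- switch(method,
                quantile = stats::quantile(negative_control_integrals,
                                           quantile, names = FALSE),
                mean_sd = mean(negative_control_integrals) +
                  3 * stats::sd(negative_control_integrals))
  pos <- nuclear_red_integrals > thr
  list(threshold = thr, positive_fraction = mean(pos),
       n_positive = sum(pos), n_total = length(pos))
}

#' Per-well lipid accumulation score
#'
#' `(mean red intensity of red objects) x (mean red-object area) x
#' (number of red objects) / (number of nuclei)`. Zero red objects give a
#' score of 0.
#'
#' @param red_objects Data frame of lipid (red) objects with columns
#'   `mean_intensity` and `area_um2`.
#' @param n_nuclei Number of (blue) nuclei in the well, > 0.
#' @return Non-negative lipid score.
#' @export
lipid_score <- function(red_objects, n_nuclei) {
  if (n_nuclei <= 0) stop("n_nuclei must be positive")
  if (is.null(red_objects) || nrow(red_objects) == 0L) return(0)
  mean(red_objects$mean_intensity) * mean(red_objects$area_um2) *
    nrow(red_objects) / n_nuclei
}

#' Split the lipid score into perinuclear and peripheral compartments
#'
#' A red object is perinuclear when its centroid lies within
#' `perinuclear_radius` of the nearest nucleus boundary, proxied by the
#' nucleus centroid plus its equivalent circular radius; otherwise it is
#' peripheral. The lipid score is computed per compartment with the same
#' nucleus count.
#'
#' @param red_objects Data frame with `mean_intensity`, `area_um2`,
#'   `x_um`, `y_um`.
#' @param nuclei Data frame of nuclei with `x_um`, `y_um` and `area_um2`.
#' @param perinuclear_radius Ring width around the nucleus boundary,
#'   micrometres.
#' @return List `perinuclear_score`, `peripheral_score`,
#'   `n_perinuclear`, `n_peripheral`.
#' @export
lipid_compartments <- function(red_objects, nuclei, perinuclear_radius = 5) {
  if (is.null(nuclei) || nrow(nuclei) == 0L) stop("empty nuclei table")
  n_nuclei <- nrow(nuclei)
  if (is.null(red_objects) || nrow(red_objects) == 0L) {
    return(list(perinuclear_score = 0, peripheral_score = 0,
                n_perinuclear = 0L, n_peripheral = 0L))
  }
  r_eq <- sqrt(nuclei$area_um2 / pi)
  peri <- vapply(seq_len(nrow(red_objects)), function(i) {
    d <- sqrt((red_objects$x_um[i] - nuclei$x_um)^2 +
              (red_objects$y_um[i] - nuclei$y_um)^2)
    any(d <= r_eq + perinuclear_radius)
  }, logical(1L))
  list(perinuclear_score = lipid_score(red_objects[peri, , drop = FALSE],
                                       n_nuclei),
       peripheral_score = lipid_score(red_objects[!peri, , drop = FALSE],
                                      n_nuclei),
       n_perinuclear = sum(peri), n_peripheral = sum(!peri))
}

#' Mito-stress-test parameters from an OCR trace
#'
#' Derives the standard quantities from a four-phase oxygen-consumption
#' trace (baseline, oligomycin, FCCP, rotenone/antimycin A):
#' non-mitochondrial OCR `nmoc` (rot/AA minimum), basal respiration
#' `br` (baseline - nmoc), proton leak `pl` (oligomycin minimum - nmoc),
#' ATP-linked OCR `atp_ocr` (br - pl), maximal respiration `max_ocr`
#' (FCCP maximum - nmoc, also reported uncorrected as `ocr_fccp_max`),
#' and the two coupling-efficiency variants reported side by side:
#' `coupling_methods` = (baseline - oligomycin minimum)/baseline and
#' `coupling_results` = atp_ocr/br. `utilization` = br/max_ocr.
#'
#' @param trace Data frame with columns `time_min`, `ocr` and `phase` in
#'   `baseline`, `oligomycin`, `fccp`, `rot_aa`.
#' @return List of class `ocr_params` with the raw phase summaries, the
#'   derived rates (pmol O2/min) and the dimensionless ratios; `flags`
#'   collects degeneracies (non-positive basal respiration, proton leak
#'   exceeding basal respiration).
#' @export
ocr_params <- function(trace) {
  phases <- c("baseline", "oligomycin", "fccp", "rot_aa")
  missing <- setdiff(phases, unique(trace$phase))
  if (length(missing)) {
    stop("OCR trace is missing phase(s): ", paste(missing, collapse = ", "))
  }
  val <- function(ph) trace$ocr[trace$phase == ph]
  baseline <- mean(val("baseline"))
  oligo_min <- min(val("oligomycin"))
  fccp_max <- max(val("fccp"))
  rotaa_min <- min(val("rot_aa"))
  nmoc <- rotaa_min
  br <- baseline - nmoc
  pl <- oligo_min - nmoc
  atp_ocr <- br - pl
  max_ocr <- fccp_max - nmoc
  flags <- character(0)
  if (br <= 0) flags <- c(flags, "non_positive_basal_respiration")
  if (pl > br) flags <- c(flags, "proton_leak_exceeds_basal")
  coupling_methods <- if (baseline > 0) (baseline - oligo_min) / baseline
                      else NA_real_
  coupling_results <- if (br > 0) atp_ocr / br else NA_real_
  utilization <- if (max_ocr > 0) br / max_ocr else NA_real_
  structure(list(ocr_baseline = baseline, ocr_oligo_min = oligo_min,
                 ocr_fccp_max = fccp_max, ocr_rotaa_min = rotaa_min,
                 nmoc = nmoc, br = br, pl = pl, atp_ocr = atp_ocr,
                 max_ocr = max_ocr,
                 coupling_methods = coupling_methods,
                 coupling_results = coupling_results,
                 utilization = utilization, flags = flags),
            class = "ocr_params")
}

#' @export
print.ocr_params <- function(x, ...) {
  cat(sprintf(
    "OCR: BR %.1f, PL %.1f, ATP-OCR %.1f, maxOCR %.1f, NMOC %.1f; coupling %.2f/%.2f, utilization %.2f\n",
    x$br, x$pl, x$atp_ocr, x$max_ocr, x$nmoc, x$coupling_methods,
    x$coupling_results, x$utilization))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Link nucleus positions across frames into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' candidate links are sorted by distance and accepted when both endpoints
#' are still free and the step is at most `max_step`. Unlinked nuclei
#' terminate or start tracks. Adequate for sparse nuclei at hour-scale
#' sampling.
#'
#' @param frames Data frame with columns `time_h`, `x_um`, `y_um` (one row
#'   per nucleus per frame).
#' @param max_step Maximum allowed displacement between consecutive
#'   frames, micrometres.
#' @return Data frame `track_id`, `time_h`, `x_um`, `y_um`, ordered by
#'   track then time.
#' @export
link_tracks <- function(frames, max_step) {
  times <- sort(unique(frames$time_h))
  if (length(times) < 2L) stop("at least 2 frames are required")
  frame_list <- lapply(times, function(t) {
    f <- frames[frames$time_h == t, , drop = FALSE]
    if (nrow(f) == 0L) stop("empty frame at time ", t)
    f
  })
  f1 <- frame_list[[1L]]
  tracks <- data.frame(track_id = seq_len(nrow(f1)), time_h = f1$time_h,
                       x_um = f1$x_um, y_um = f1$y_um)
  active <- data.frame(track_id = seq_len(nrow(f1)),
                       x = f1$x_um, y = f1$y_um)
  next_id <- nrow(f1) + 1L
  for (k in 2L:length(times)) {
    f <- frame_list[[k]]
    d <- outer(active$x, f$x_um, "-")^2 + outer(active$y, f$y_um, "-")^2
    d <- sqrt(d)
    cand <- which(d <= max_step, arr.ind = TRUE)
    new_active <- data.frame(track_id = integer(0), x = numeric(0),
                             y = numeric(0))
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_prev <- rep(FALSE, nrow(active))
      used_new <- rep(FALSE, nrow(f))
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1L]; q <- cand[i, 2L]
        if (used_prev[p] || used_new[q]) next
        used_prev[p] <- used_new[q] <- TRUE
        id <- active$track_id[p]
        tracks <- rbind(tracks, data.frame(track_id = id,
                                           time_h = times[k],
                                           x_um = f$x_um[q],
                                           y_um = f$y_um[q]))
        new_active <- rbind(new_active,
                            data.frame(track_id = id, x = f$x_um[q],
                                       y = f$y_um[q]))
      }
      unmatched <- which(!used_new)
    } else {
      unmatched <- seq_len(nrow(f))
    }
    for (q in unmatched) {
      tracks <- rbind(tracks, data.frame(track_id = next_id,
                                         time_h = times[k],
                                         x_um = f$x_um[q],
                                         y_um = f$y_um[q]))
      new_active <- rbind(new_active,
                          data.frame(track_id = next_id, x = f$x_um[q],
                                     y = f$y_um[q]))
      next_id <- next_id + 1L
    }
    active <- new_active
  }
  tracks <- tracks[order(tracks$track_id, tracks$time_h), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}

#' Net displacement rate of a track
#'
#' Euclidean net displacement `sqrt(dx^2 + dy^2)` between two timepoints
#' divided by the elapsed time: micrometres per hour. Net, not path
#' length, so a closed loop scores 0.
#'
#' @param track Data frame with `time_h`, `x_um`, `y_um` for one nucleus.
#' @param t_start,t_end Timepoints present in the track, `t_end > t_start`.
#' @return Displacement rate in um/h.
#' @export
displacement_rate <- function(track, t_start, t_end) {
  if (t_end <= t_start) stop("t_end must be after t_start")
  i0 <- match(t_start, track$time_h)
  i1 <- match(t_end, track$time_h)
  if (is.na(i0) || is.na(i1)) stop("track has no position at a requested time")
  sqrt((track$x_um[i1] - track$x_um[i0])^2 +
       (track$y_um[i1] - track$y_um[i0])^2) / (t_end - t_start)
}

#' Glucose consumption, lactate production and glycolytic index
#'
#' Protein-normalized fluxes over the incubation:
#' consumption = ([Glu]_no cells - [Glu]_treated)/protein, production =
#' ([Lac]_treated - [Lac]_no cells)/protein, and the glycolytic index
#' produced lactate / (2 x consumed glucose): 1 when all consumed glucose
#' leaves as lactate.
#'
#' @param glu_no_cells,glu_treated Glucose concentrations (mmol/l) of
#'   cell-free and treated media.
#' @param lac_no_cells,lac_treated Lactate concentrations (mmol/l).
#' @param protein Protein amount (mg), > 0.
#' @return List `consumption`, `production`, `glycolytic_index`, `flags`.
#' @export
metabolic_fluxes <- function(glu_no_cells, glu_treated, lac_no_cells,
                             lac_treated, protein) {
  if (protein <= 0) stop("protein must be positive")
  consumption <- (glu_no_cells - glu_treated) / protein
  production <- (lac_treated - lac_no_cells) / protein
  flags <- character(0)
  if (consumption <= 0) {
    flags <- c(flags, "non_positive_glucose_consumption")
    index <- NA_real_
  } else {
    index <- production / (2 * consumption)
  }
  list(consumption = consumption, production = production,
       glycolytic_index = index, flags = flags)
}

#' Protein-normalized signal development rate
#'
#' Slope of a plate-reader signal between two timepoints divided by the
#' protein content of the well, e.g. caspase-3 activity development
#' between 30 and 60 min.
#'
#' @param f_t1,f_t2 Fluorescence at the two timepoints.
#' @param t1,t2 Timepoints in minutes, `t2 > t1`.
#' @param protein Protein amount (mg), > 0.
#' @return Rate in signal units per minute per mg protein (may be
#'   negative for decaying signals).
#' @export
normalized_rate <- function(f_t1, f_t2, t1, t2, protein) {
  if (t2 <= t1) stop("t2 must be after t1")
  if (protein <= 0) stop("protein must be positive")
  (f_t2 - f_t1) / (t2 - t1) / protein
}

#' Nuclear-to-perinuclear fluorescence ratio
#'
#' Ratio of background-subtracted mean nuclear fluorescence to the mean
#' fluorescence of a perinuclear ring, the compartmentalization readout of
#' the in-cell fluorescence immunoassay.
#'
#' @param nuclear_mean,ring_mean Mean fluorescence of nucleus and
#'   perinuclear ring.
#' @param background Background fluorescence to subtract from both.
#' @return Ratio, or `NA` (with a warning) when the ring signal does not
#'   exceed background.
#' @export
nuclear_perinuclear_ratio <- function(nuclear_mean, ring_mean, background) {
  denom <- ring_mean - background
  if (any(denom <= 0)) {
    warning("ring signal at or below background; ratio undefined")
  }
  out <- (nuclear_mean - background) / denom
  out[denom <= 0] <- NA_real_
  out
}
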