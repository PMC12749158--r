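# Seeded synthetic-data generators emulating the study design: paired
# four-condition negative-binomial counts with animal effects and an
# EGFR-profile-dependent interaction term, plus cell-object, DAPI, OCR and
# motility fixtures. Every generator is a pure function of its
# configuration and seed.

#' Simulation configuration for paired stressor counts
#'
#' Defaults describe the wildtype-VSMC profile of the study design: four
#' animals with strictly paired CTRL/MET/HUM/ALL samples, sparse metabolic
#' and humoral main effects, and a synergistic interaction acting only
#' under the combined condition. The `KO_VSMC` and `EC` profiles encode
#' the contrasting biology (no humoral main effect, no interaction) as
#' generative truth. Negative-binomial dispersion and the animal random
#' effect are set so that control-sample variability resembles the bulk
#' RNA-seq data the pipeline targets (average control CV near 0.21).
#'
#' @param n_genes Number of genes.
#' @param n_animals Number of animals (paired sets).
#' @param cell_profile `"WT_VSMC"`, `"KO_VSMC"` or `"EC"`.
#' @param frac_met,frac_hum,frac_synergy Fractions of genes carrying a
#'   metabolic main effect, humoral main effect, or interaction term
#'   (disjoint classes; must sum to at most 1). For `KO_VSMC`/`EC`
#'   profiles `frac_hum` and `frac_synergy` are forced to 0.
#' @param effect_size_log2 Magnitude of main effects (log2), random sign.
#' @param interaction_log2 Magnitude of the interaction (log2), random
#'   sign.
#' @param animal_sd_log2 SD of the per-gene, per-animal baseline shift
#'   (log2); cancels within pairs but contributes to control variability.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_mean Mean library size per sample.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 abundance weights.
#' @param sex Sex recorded in the sample sheet.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000, n_animals = 4,
                       cell_profile = c("WT_VSMC", "KO_VSMC", "EC"),
                       frac_met = 0.15, frac_hum = 0.10,
                       frac_synergy = 0.20,
                       effect_size_log2 = 1.0, interaction_log2 = 1.0,
                       animal_sd_log2 = 0.1, dispersion = 0.03,
                       lib_size_mean = 5e6,
                       baseline_log2_mean = 4, baseline_log2_sd = 2,
                       sex = "male", seed = 1L) {
  cell_profile <- match.arg(cell_profile)
  if (cell_profile %in% c("KO_VSMC", "EC")) {
    frac_hum <- 0
    frac_synergy <- 0
  }
  fr <- c(frac_met, frac_hum, frac_synergy)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("effect fractions must be in [0, 1] and sum to at most 1")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_genes < 1 || n_animals < 2) {
    stop("need at least 1 gene and 2 animals")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_animals = as.integer(n_animals),
                 cell_profile = cell_profile,
                 frac_met = frac_met, frac_hum = frac_hum,
                 frac_synergy = frac_synergy,
                 effect_size_log2 = effect_size_log2,
                 interaction_log2 = interaction_log2,
                 animal_sd_log2 = animal_sd_log2,
                 dispersion = dispersion,
                 lib_size_mean = lib_size_mean,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 sex = sex, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate paired stressor-condition counts with known truth
#'
#' Counts are negative binomial with mean
#' `2^(baseline_g + animal_ag + x_met * beta_met_g + x_hum * beta_hum_g +
#' x_met * x_hum * gamma_g)` scaled to the library size, where `x_met` and
#' `x_hum` indicate the metabolic and humoral stressor exposures of the
#' condition (both on under `ALL`) and the interaction `gamma` is nonzero
#' only for genes of the `synergistic` truth class (wildtype profile
#' only). Fully reproducible from the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List with `counts` (integer matrix), `sheet` (sample sheet data
#'   frame) and `truth` (per-gene class and true per-condition log2 fold
#'   changes).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  na <- config$n_animals
  classes <- rep("null", ng)
  n_met <- round(config$frac_met * ng)
  n_hum <- round(config$frac_hum * ng)
  n_syn <- round(config$frac_synergy * ng)
  idx <- sample.int(ng, n_met + n_hum + n_syn)
  classes[idx[seq_len(n_met)]] <- "metabolic"
  if (n_hum > 0) classes[idx[n_met + seq_len(n_hum)]] <- "humoral"
  if (n_syn > 0) classes[idx[n_met + n_hum + seq_len(n_syn)]] <- "synergistic"
  sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
  beta_met <- ifelse(classes == "metabolic",
                     config$effect_size_log2 * sgn(ng), 0)
  beta_hum <- ifelse(classes == "humoral",
                     config$effect_size_log2 * sgn(ng), 0)
  gamma <- ifelse(classes == "synergistic",
                  config$interaction_log2 * sgn(ng), 0)
  baseline <- stats::rnorm(ng, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  animal_ids <- sprintf("animal%02d", seq_len(na))
  animal_eff <- matrix(stats::rnorm(ng * na, 0, config$animal_sd_log2),
                       ng, na)
  conditions <- c("CTRL", "MET", "HUM", "ALL")
  x_met <- c(CTRL = 0, MET = 1, HUM = 0, ALL = 1)
  x_hum <- c(CTRL = 0, MET = 0, HUM = 1, ALL = 1)
  w0 <- 2^baseline
  counts <- matrix(0L, ng, na * 4L)
  sample_ids <- character(na * 4L)
  col <- 0L
  for (a in seq_len(na)) {
    for (cond in conditions) {
      col <- col + 1L
      sample_ids[col] <- paste0(animal_ids[a], "_", cond)
      lmu <- baseline + animal_eff[, a] +
        x_met[[cond]] * beta_met + x_hum[[cond]] * beta_hum +
        x_met[[cond]] * x_hum[[cond]] * gamma
      mu <- 2^lmu
      mu <- mu * config$lib_size_mean / sum(w0)
      counts[, col] <- stats::rnbinom(ng, mu = mu,
                                      size = 1 / config$dispersion)
    }
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  sheet <- data.frame(
    sample_id = sample_ids,
    animal_id = rep(animal_ids, each = 4L),
    cell_type = config$cell_profile,
    sex = config$sex,
    passage = 3L,
    condition = rep(conditions, na),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_ids, class = classes,
    beta_met = beta_met, beta_hum = beta_hum, gamma = gamma,
    log2fc_met = beta_met,
    log2fc_hum = beta_hum,
    log2fc_all = beta_met + beta_hum + gamma,
    stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet, truth = truth)
}

#' Simulate segmented cell objects before and after contraction
#'
#' Cells are parameterized as ellipses with lognormal aspect ratios and
#' areas spanning beyond the 400-4000 um^2 analysis window, with a share
#' of binucleated objects, so that the object filter is exercised. The
#' "after" table applies the forward [contraction_model()] operator to
#' each cell.
#'
#' @param n_cells Number of objects.
#' @param aspect_meanlog,aspect_sdlog Lognormal parameters of the
#'   (aspect ratio - 1) distribution.
#' @param contraction_factor Fractional shortening applied in the "after"
#'   image (0 for none).
#' @param mode Contraction mode, see [contraction_model()].
#' @param frac_binucleated Share of two-nucleus objects.
#' @param seed Integer seed.
#' @return List `before`, `after`: data frames with `object_id`,
#'   `area_um2`, `perimeter_um`, `n_nuclei`, `x_um`, `y_um`.
#' @export
simulate_cell_objects <- function(n_cells, aspect_meanlog = log(8),
                                  aspect_sdlog = 0.35,
                                  contraction_factor = 0.2,
                                  mode = "volume_conserving_3d",
                                  frac_binucleated = 0.1, seed = 1L) {
  if (n_cells <= 0) stop("n_cells must be positive")
  set.seed(seed)
  ratio <- 1 + stats::rlnorm(n_cells, aspect_meanlog, aspect_sdlog)
  area <- stats::runif(n_cells, 300, 4500)
  n_nuclei <- 1L + stats::rbinom(n_cells, 1L, frac_binucleated)
  pos <- matrix(stats::runif(2 * n_cells, 0, 1000), ncol = 2)
  geom <- function(ratio, area) {
    # semi-axes from area and ratio: area = pi a b, a = ratio * b
    b <- sqrt(area / (pi * ratio))
    a <- ratio * b
    perim <- ellipse_perimeter(a, b)
    list(a = a, b = b, perimeter = perim)
  }
  g0 <- geom(ratio, area)
  before <- data.frame(object_id = sprintf("cell%05d", seq_len(n_cells)),
                       area_um2 = area, perimeter_um = g0$perimeter,
                       n_nuclei = n_nuclei,
                       x_um = pos[, 1], y_um = pos[, 2],
                       stringsAsFactors = FALSE)
  s <- contraction_factor
  if (s > 0) {
    a2 <- g0$a * (1 - s)
    b2 <- switch(mode,
                 area_conserving_2d = g0$b / (1 - s),
                 volume_conserving_3d = g0$b / sqrt(1 - s),
                 width_constant = g0$b)
    hi <- pmax(a2, b2); lo <- pmin(a2, b2)
    after <- before
    after$area_um2 <- pi * hi * lo
    after$perimeter_um <- ellipse_perimeter(hi, lo)
  } else {
    after <- before
  }
  list(before = before, after = after)
}

#' Simulate per-nucleus DAPI integrals with known phase truth
#'
#' G1 nuclei are lognormal around the G1 mode, G2 nuclei lognormal around
#' twice the mode, and S-phase nuclei bridge the two clusters uniformly
#' over `s_range` times the mode (mid-S DNA content; real S phase spans
#' the full 1-2x range).
#'
#' @param n_nuclei Number of nuclei.
#' @param fractions Numeric (G1, S, G2) fractions summing to 1.
#' @param g1_mode G1 DAPI-integral mode (arbitrary units).
#' @param cv Coefficient of variation of the G1/G2 clusters.
#' @param s_range S-phase bridge, as multiples of the G1 mode.
#' @param seed Integer seed.
#' @return Data frame `dapi_integral`, `phase` (truth labels).
#' @export
simulate_dapi <- function(n_nuclei, fractions = c(0.6, 0.2, 0.2),
                          g1_mode = 1e5, cv = 0.05,
                          s_range = c(1.2, 1.7), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three non-negative values summing to 1")
  }
  set.seed(seed)
  phase <- sample(c("G1", "S", "G2"), n_nuclei, replace = TRUE,
                  prob = fractions)
  sdlog <- sqrt(log(1 + cv^2))
  x <- numeric(n_nuclei)
  n_g1 <- sum(phase == "G1"); n_s <- sum(phase == "S")
  n_g2 <- sum(phase == "G2")
  x[phase == "G1"] <- stats::rlnorm(n_g1, log(g1_mode), sdlog)
  x[phase == "S"] <- stats::runif(n_s, s_range[1] * g1_mode,
                                  s_range[2] * g1_mode)
  x[phase == "G2"] <- stats::rlnorm(n_g2, log(2 * g1_mode), sdlog)
  data.frame(dapi_integral = x, phase = phase, stringsAsFactors = FALSE)
}

#' Simulate a four-phase mito-stress-test OCR trace
#'
#' Phase plateau levels are chosen so that [ocr_params()] inverts the
#' inputs exactly in the noiseless case: baseline at `br + nmoc`,
#' oligomycin at `pl + nmoc`, FCCP at `max_ocr + nmoc`, rotenone/antimycin
#' A at `nmoc`.
#'
#' @param br,pl,nmoc,max_ocr Target basal respiration, proton leak,
#'   non-mitochondrial OCR and (NMOC-corrected) maximal respiration,
#'   pmol O2/min.
#' @param noise_sd Gaussian measurement noise SD.
#' @param n_per_phase Measurements per phase.
#' @param seed Integer seed.
#' @return Data frame `time_min`, `ocr`, `phase`.
#' @export
simulate_ocr_trace <- function(br, pl, nmoc, max_ocr, noise_sd = 0,
                               n_per_phase = 3L, seed = 1L) {
  if (any(c(br, pl, nmoc, max_ocr) < 0)) stop("rates must be non-negative")
  set.seed(seed)
  levels <- c(baseline = br + nmoc, oligomycin = pl + nmoc,
              fccp = max_ocr + nmoc, rot_aa = nmoc)
  phase <- rep(names(levels), each = n_per_phase)
  ocr <- rep(unname(levels), each = n_per_phase) +
    stats::rnorm(4L * n_per_phase, 0, noise_sd)
  data.frame(time_min = seq_len(4L * n_per_phase) * 6.5,
             ocr = ocr, phase = phase, stringsAsFactors = FALSE)
}

#' Simulate nucleus positions over time
#'
#' Isotropic random-walk (or straight-line directed) motion. For the
#' random walk the per-frame step lengths are Rayleigh-distributed with
#' the per-axis SD chosen so that the mean step length per unit time
#' equals `speed_um_h`.
#'
#' @param n_nuclei Number of nuclei.
#' @param speed_um_h Target mean step speed, um/h.
#' @param n_frames Number of frames (>= 2).
#' @param dt_h Sampling interval, hours.
#' @param mode `"random"` walk or `"directed"` straight-line motion.
#' @param seed Integer seed.
#' @return Data frame `time_h`, `nucleus_id`, `x_um`, `y_um`.
#' @export
simulate_tracks <- function(n_nuclei, speed_um_h, n_frames = 3L, dt_h = 2,
                            mode = c("random", "directed"), seed = 1L) {
  mode <- match.arg(mode)
  if (n_frames < 2L) stop("n_frames must be at least 2")
  set.seed(seed)
  sigma <- speed_um_h * dt_h / sqrt(pi / 2)
  x <- stats::runif(n_nuclei, 0, 1000)
  y <- stats::runif(n_nuclei, 0, 1000)
  if (mode == "directed") {
    theta <- stats::runif(n_nuclei, 0, 2 * pi)
    vx <- speed_um_h * cos(theta)
    vy <- speed_um_h * sin(theta)
  }
  out <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    if (k > 1L) {
      if (mode == "random") {
        x <- x + stats::rnorm(n_nuclei, 0, sigma)
        y <- y + stats::rnorm(n_nuclei, 0, sigma)
      } else {
        x <- x + vx * dt_h
        y <- y + vy * dt_h
      }
    }
    out[[k]] <- data.frame(time_h = (k - 1L) * dt_h,
                           nucleus_id = sprintf("nuc%04d",
                                                seq_len(n_nuclei)),
                           x_um = x, y_um = y, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
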