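# End-to-end orchestration: FPM -> control-variability threshold -> paired
# effects -> triple DEG filter -> synergy decomposition -> slopes and
# reconciliation, with TSV/JSON outputs for reproducible one-command runs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full transcriptome synergy pipeline
#'
#' Sequences the analysis stages on a count matrix with a paired sample
#' sheet: FPM normalization, control-variability fold-change threshold,
#' per-condition paired effects with exclusion tests, built-in paired
#' log-ratio differential-expression test (Benjamini-Hochberg corrected;
#' external per-method FDR tables can be supplied instead), the triple DEG
#' filter, the synergy table, through-origin scatter slopes of the
#' single-stressor versus combined fold changes over the combined-stressor
#' DEG set, CI-based reconciliation of the metabolic and combined DEG
#' lists, and the mesh surface export.
#'
#' @param counts Integer count matrix (see [read_counts()]).
#' @param sheet Sample sheet for the matrix (see [read_sample_sheet()]);
#'   should describe a single cell type.
#' @param fdr_tables Optional named list with elements `MET`, `HUM`, `ALL`,
#'   each a data frame `gene_id`, `fdr_method1`, `fdr_method2` from
#'   external DE tools. When absent both FDR columns are filled by
#'   [paired_de_test()].
#' @param level Confidence level of the paired effect CIs.
#' @param fdr_cut,fpm_cut Filter cutoffs, see [filter_deg()].
#' @param min_mean_fpm Expression floor for CV averaging, see [gene_cv()].
#' @param outdir Optional output directory; when given, all result tables
#'   are written as TSV plus a `run_metadata.json`.
#' @return List of class `synergy_run`: `threshold` (`cv_stats`),
#'   `paired_sets`, per-condition `de` and `deg` tables, `effects`,
#'   `synergy` table, `slopes`, `reconciliation`, `mesh`, `summary`.
#' @export
run_transcriptome_pipeline <- function(counts, sheet, fdr_tables = NULL,
                                       level = 0.99, fdr_cut = 0.05,
                                       fpm_cut = 3, min_mean_fpm = 1,
                                       outdir = NULL) {
  counts <- validate_counts(counts)
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(counts), sheet$sample_id)
  if (length(missing)) {
    stop("stage data_model_io: sample(s) missing from sheet: ",
         paste(missing, collapse = ", "))
  }
  fpm <- compute_fpm(counts)
  sets <- build_paired_sets(sheet)

  ctrl_samples <- sheet$sample_id[sheet$condition == "CTRL"]
  cv_table <- gene_cv(fpm, ctrl_samples, min_mean_fpm = min_mean_fpm)
  threshold <- fc_threshold(cv_table)

  mean_fpm <- group_mean_fpm(fpm, sheet, "condition")
  conditions <- c("MET", "HUM", "ALL")
  de <- list(); deg <- list(); effects <- list()
  for (cond in conditions) {
    det <- paired_de_test(fpm, sets, cond)
    if (!is.null(fdr_tables) && !is.null(fdr_tables[[cond]])) {
      ext <- fdr_tables[[cond]]
      det$fdr_method1 <- ext$fdr_method1[match(det$gene_id, ext$gene_id)]
      det$fdr_method2 <- ext$fdr_method2[match(det$gene_id, ext$gene_id)]
    } else {
      det$fdr_method1 <- det$fdr
      det$fdr_method2 <- det$fdr
    }
    stats_tab <- data.frame(gene_id = det$gene_id, log2fc = det$log2fc,
                            fdr_method1 = det$fdr_method1,
                            fdr_method2 = det$fdr_method2,
                            stringsAsFactors = FALSE)
    stats_tab[[paste0("mean_fpm_CTRL")]] <- mean_fpm[, "CTRL"]
    stats_tab[[paste0("mean_fpm_", cond)]] <- mean_fpm[, cond]
    de[[cond]] <- det
    deg[[cond]] <- filter_deg(stats_tab, threshold, fdr_cut = fdr_cut,
                              fpm_cut = fpm_cut)
    effects[[cond]] <- paired_effect_table(fpm, sets, cond, level = level)
  }

  syn <- synergy_table(
    gene_id = de$MET$gene_id,
    log2fc_met = de$MET$log2fc, log2fc_hum = de$HUM$log2fc,
    log2fc_all = de$ALL$log2fc,
    deg_met = deg$MET$is_deg, deg_hum = deg$HUM$is_deg,
    deg_all = deg$ALL$is_deg,
    threshold_log2fc = threshold$threshold_log2fc)

  all_deg_ids <- deg$ALL$gene_id[deg$ALL$is_deg]
  slopes <- list()
  if (length(all_deg_ids) >= 2L) {
    i <- match(all_deg_ids, syn$gene_id)
    for (cond in c("MET", "HUM")) {
      slopes[[cond]] <- scatter_slope(
        x = syn$log2fc_all[i], y = syn[[paste0("log2fc_", tolower(cond))]][i],
        gene_set_label = "ALL-DEG", x_condition = "ALL",
        y_condition = cond)
    }
  }
  recon <- reconcile_sets(deg$MET$gene_id[deg$MET$is_deg], all_deg_ids,
                          effects$MET, effects$ALL,
                          label_a = "MET", label_b = "ALL")
  mesh <- export_mesh(syn)

  summary <- list(
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_paired_sets = nrow(sets),
    mean_cv = threshold$mean_cv,
    threshold_log2fc = threshold$threshold_log2fc,
    n_deg = vapply(deg, function(d) sum(d$is_deg), integer(1)),
    slope_met_vs_all = if (!is.null(slopes$MET)) slopes$MET$slope
                       else NA_real_,
    slope_hum_vs_all = if (!is.null(slopes$HUM)) slopes$HUM$slope
                       else NA_real_,
    synergy_detected = !is.null(slopes$MET) && slopes$MET$slope < 0.8,
    n_synergistic = sum(grepl("^synergistic", syn$category)),
    level = level, fdr_cut = fdr_cut, fpm_cut = fpm_cut,
    min_mean_fpm = min_mean_fpm)

  res <- structure(list(threshold = threshold, paired_sets = sets,
                        cv_table = cv_table, de = de, deg = deg,
                        effects = effects, synergy = syn, slopes = slopes,
                        reconciliation = recon, mesh = mesh,
                        summary = summary),
                   class = "synergy_run")
  if (!is.null(outdir)) write_synergy_run(res, outdir)
  res
}

write_synergy_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$cv_table, file.path(outdir, "control_cv.tsv"))
  write_tsv(res$paired_sets, file.path(outdir, "paired_sets.tsv"))
  for (cond in names(res$deg)) {
    write_tsv(res$deg[[cond]],
              file.path(outdir, paste0("deg_", cond, ".tsv")))
    write_tsv(res$effects[[cond]],
              file.path(outdir, paste0("effects_", cond, ".tsv")))
  }
  write_tsv(res$synergy, file.path(outdir, "synergy.tsv"))
  write_tsv(res$reconciliation$table,
            file.path(outdir, "reconciliation.tsv"))
  write_tsv(res$mesh, file.path(outdir, "mesh_surface.tsv"))
  jsonlite::write_json(res$summary,
                       file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.synergy_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Paired stressor-synergy run: %d genes, %d paired sets\n",
              s$n_genes, s$n_paired_sets))
  cat(sprintf("  |log2FC| threshold %.3f (mean control CV %.3f)\n",
              s$threshold_log2fc, s$mean_cv))
  cat(sprintf("  DEG counts: MET %d, HUM %d, ALL %d\n",
              s$n_deg[["MET"]], s$n_deg[["HUM"]], s$n_deg[["ALL"]]))
  cat(sprintf("  slope MET~ALL over ALL-DEG: %.3f (%s)\n",
              s$slope_met_vs_all,
              if (isTRUE(s$synergy_detected)) "synergy: single stressor explains a minority of the combined effect"
              else "no synergy signature"))
  invisible(x)
}

#' Run the phenotype-assay pipeline
#'
#' Computes each formula-defined assay readout present in the input list
#' and, where per-condition paired replicate values are supplied, the
#' paired stressor-effect CIs at the functional-assay level (default
#' 0.95).
#'
#' @param inputs Named list; recognized elements:
#'   `contractility` (list with `before`/`after` object tables),
#'   `dapi` (numeric DAPI integrals),
#'   `brdu` (list `sample`, `negative_control`),
#'   `lipid` (list `red_objects`, `n_nuclei`, optional `nuclei`),
#'   `ocr` (data frame trace or named list of traces),
#'   `tracks` (list `frames`, `max_step`, `t_start`, `t_end`),
#'   `paired_endpoints` (named list of lists with `control`/`stressor`
#'   vectors).
#' @param level Confidence level for paired endpoint effects.
#' @param outdir Optional output directory for TSV/JSON results.
#' @return Named list of assay results.
#' @export
run_phenotype_pipeline <- function(inputs, level = 0.95, outdir = NULL) {
  if (length(inputs) == 0L) stop("no phenotype inputs supplied")
  out <- list()
  if (!is.null(inputs$contractility)) {
    ct <- inputs$contractility
    out$contractility <- contractility_assay(filter_cells(ct$before),
                                             filter_cells(ct$after))
  }
  if (!is.null(inputs$dapi)) {
    out$cell_cycle <- gate_cell_cycle(inputs$dapi)
  }
  if (!is.null(inputs$brdu)) {
    out$brdu <- brdu_call(inputs$brdu$sample,
                          inputs$brdu$negative_control)
  }
  if (!is.null(inputs$lipid)) {
    lp <- inputs$lipid
    out$lipid <- list(total = lipid_score(lp$red_objects, lp$n_nuclei))
    if (!is.null(lp$nuclei)) {
      out$lipid <- c(out$lipid,
                     lipid_compartments(lp$red_objects, lp$nuclei))
    }
  }
  if (!is.null(inputs$ocr)) {
    traces <- if (is.data.frame(inputs$ocr)) list(trace = inputs$ocr)
              else inputs$ocr
    out$ocr <- lapply(traces, ocr_params)
  }
  if (!is.null(inputs$tracks)) {
    tk <- inputs$tracks
    tracks <- link_tracks(tk$frames, tk$max_step)
    ids <- unique(tracks$track_id)
    rates <- vapply(ids, function(id) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      if (!all(c(tk$t_start, tk$t_end) %in% tr$time_h)) return(NA_real_)
      displacement_rate(tr, tk$t_start, tk$t_end)
    }, numeric(1))
    out$motility <- list(tracks = tracks,
                         rates = data.frame(track_id = ids,
                                            rate_um_h = rates),
                         median_rate_um_h = stats::median(rates,
                                                          na.rm = TRUE))
  }
  if (!is.null(inputs$paired_endpoints)) {
    out$paired_effects <- do.call(rbind, lapply(
      names(inputs$paired_endpoints), function(nm) {
        ep <- inputs$paired_endpoints[[nm]]
        rec <- paired_effect(ep$control, ep$stressor, level = level)
        rec$target_id <- nm
        rec
      }))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    flat <- list()
    if (!is.null(out$contractility)) flat$contractility <- out$contractility
    if (!is.null(out$cell_cycle)) {
      flat$cell_cycle <- list(g1_mode = out$cell_cycle$g1_mode,
                              fractions = as.list(out$cell_cycle$fractions))
    }
    if (!is.null(out$brdu)) {
      flat$brdu <- out$brdu[c("threshold", "positive_fraction")]
    }
    if (!is.null(out$lipid)) flat$lipid <- out$lipid
    if (!is.null(out$ocr)) {
      flat$ocr <- lapply(out$ocr, function(p) {
        p <- unclass(p); p$flags <- as.list(p$flags); p
      })
    }
    if (!is.null(out$motility)) {
      write_tsv(out$motility$rates,
                file.path(outdir, "motility_rates.tsv"))
      flat$motility <- list(median_rate_um_h = out$motility$median_rate_um_h)
    }
    if (!is.null(out$paired_effects)) {
      write_tsv(out$paired_effects,
                file.path(outdir, "phenotype_paired_effects.tsv"))
    }
    jsonlite::write_json(flat, file.path(outdir, "phenotype_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
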