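#' Per-gene coefficient of variation of control-sample expression
#'
#' The relative standard deviation sd(FPM)/mean(FPM) of each gene across
#' the control samples, the raw material of the variability-derived
#' fold-change threshold. The sample (n-1) standard deviation is used.
#' Genes whose control mean FPM falls below `min_mean_fpm` are retained in
#' the table but flagged `included = FALSE` and excluded from threshold
#' averaging, avoiding 0/0 instability at unexpressed genes.
#'
#' @param fpm FPM matrix from [compute_fpm()].
#' @param control_samples Character vector of control sample ids (>= 2).
#' @param min_mean_fpm Expression floor for inclusion in CV averaging.
#' @return Data frame `gene_id`, `mean_fpm`, `sd_fpm`, `cv`, `included`.
#' @export
gene_cv <- function(fpm, control_samples, min_mean_fpm = 1) {
  missing <- setdiff(control_samples, colnames(fpm))
  if (length(missing)) {
    stop("control sample(s) absent from FPM matrix: ",
         paste(missing, collapse = ", "))
  }
  if (length(control_samples) < 2L) {
    stop("at least 2 control samples are required to estimate variability")
  }
  x <- fpm[, control_samples, drop = FALSE]
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  data.frame(gene_id = rownames(fpm), mean_fpm = m, sd_fpm = s, cv = cv,
             included = !is.na(cv) & m >= min_mean_fpm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change threshold from control variability
#'
#' The significance threshold for |log2 fold change| is defined as three
#' times the average coefficient of variation of gene expression across
#' control samples.
#'
#' @param cv_table Data frame from [gene_cv()].
#' @return Object of class `cv_stats`: list with `mean_cv`,
#'   `threshold_log2fc` (= 3 * mean_cv), `n_genes_used`.
#' @export
fc_threshold <- function(cv_table) {
  if (!is.data.frame(cv_table) || !all(c("cv", "included") %in%
                                       colnames(cv_table))) {
    stop("cv_table must be the output of gene_cv()")
  }
  used <- cv_table$cv[cv_table$included]
  if (length(used) == 0L) stop("no genes available for CV averaging")
  mean_cv <- mean(used)
  structure(list(mean_cv = mean_cv,
                 threshold_log2fc = 3 * mean_cv,
                 n_genes_used = length(used)),
            class = "cv_stats")
}

#' @export
print.cv_stats <- function(x, ...) {
  cat(sprintf(
    "Control variability: mean CV %.4f over %d genes -> |log2FC| threshold %.4f\n",
    x$mean_cv, x$n_genes_used, x$threshold_log2fc))
  invisible(x)
}

#' Triple differential-expression filter
#'
#' A gene is called differentially expressed when all three criteria hold:
#' FDR below `fdr_cut` in *both* external methods, mean expression of at
#' least `fpm_cut` FPM in at least one sample group, and |log2 fold change|
#' at or above the variability-derived threshold. The returned table keeps
#' a full audit trail of which filter each gene passed.
#'
#' @param stats Data frame with columns `gene_id`, `log2fc`, `fdr_method1`,
#'   `fdr_method2` and one or more `mean_fpm_<group>` columns.
#' @param threshold `cv_stats` object from [fc_threshold()], or a single
#'   non-negative number taken as the |log2FC| threshold directly.
#' @param fdr_cut FDR significance cutoff (strict `<`), default 0.05.
#' @param fpm_cut Expression floor in FPM (`>=` in at least one group),
#'   default 3.
#' @return `stats` with added logical columns `passes_fdr`, `passes_fpm`,
#'   `passes_fc`, `is_deg`.
#' @export
filter_deg <- function(stats, threshold, fdr_cut = 0.05, fpm_cut = 3) {
  required <- c("gene_id", "log2fc", "fdr_method1", "fdr_method2")
  missing <- setdiff(required, colnames(stats))
  if (length(missing)) {
    stop("stats table is missing column(s): ", paste(missing, collapse = ", "))
  }
  fpm_cols <- grep("^mean_fpm_", colnames(stats), value = TRUE)
  if (length(fpm_cols) == 0L) {
    stop("stats table needs at least one mean_fpm_<group> column")
  }
  for (col in c("fdr_method1", "fdr_method2")) {
    bad <- !is.na(stats[[col]]) & (stats[[col]] < 0 | stats[[col]] > 1)
    if (any(bad)) stop("FDR outside [0, 1] in column ", col)
  }
  thr <- if (inherits(threshold, "cv_stats")) threshold$threshold_log2fc
         else as.numeric(threshold)
  if (length(thr) != 1L || is.na(thr) || thr < 0) {
    stop("threshold must be a single non-negative log2FC value")
  }
  fdr_ok <- !is.na(stats$fdr_method1) & !is.na(stats$fdr_method2) &
    stats$fdr_method1 < fdr_cut & stats$fdr_method2 < fdr_cut
  fpm_ok <- apply(as.matrix(stats[fpm_cols]) >= fpm_cut, 1L, any)
  fc_ok <- !is.na(stats$log2fc) & abs(stats$log2fc) >= thr
  stats$passes_fdr <- fdr_ok
  stats$passes_fpm <- fpm_ok
  stats$passes_fc <- fc_ok
  stats$is_deg <- fdr_ok & fpm_ok & fc_ok
  stats
}
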