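# Paired stressor-effect ratios with log-scale confidence intervals.
#
# The study design yields strictly connected sample quadruples per animal,
# so stressor effects are estimated as per-set ratios stressor/control,
# summarized by the geometric mean, with a t-based confidence interval on
# the log2 scale back-transformed to the ratio scale. Significance is the
# exclusion of the value 1 from the interval.

#' Paired effect summaries from a ratio matrix
#'
#' Vectorized core of the paired stressor-effect estimate: one row of
#' `ratios` per target (gene or assay endpoint), one column per paired set.
#' Non-finite or non-positive ratios are treated as missing (that set is
#' dropped for that target). Targets with fewer than 2 usable sets get `NA`
#' estimates.
#'
#' @param ratios Numeric matrix of per-set stressor/control ratios.
#' @param level Confidence level in (0, 1), e.g. 0.99 for gene expression
#'   or 0.95 for functional assays.
#' @return Data frame `target_id`, `n_sets`, `log2fc` (mean log2 ratio),
#'   `effect` (geometric mean ratio), `ci_low`, `ci_high`, `level`,
#'   `excludes_one`.
#' @export
paired_effects_from_ratios <- function(ratios, level = 0.99) {
  if (!is.matrix(ratios)) ratios <- matrix(ratios, nrow = 1L)
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    stop("level must be a single value in (0, 1)")
  }
  lr <- log2(ratios)
  lr[!is.finite(lr)] <- NA_real_
  n <- rowSums(!is.na(lr))
  m <- rowMeans(lr, na.rm = TRUE)
  dev <- lr - m
  ss <- rowSums(dev^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1L, 1L))
  se <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = pmax(n - 1L, 1L))
  lo <- m - tq * se
  hi <- m + tq * se
  bad <- n < 2L
  m[bad] <- lo[bad] <- hi[bad] <- NA_real_
  ids <- rownames(ratios)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ratios)))
  data.frame(target_id = ids, n_sets = n, log2fc = m,
             effect = 2^m, ci_low = 2^lo, ci_high = 2^hi,
             level = level,
             excludes_one = !is.na(lo) & (2^lo > 1 | 2^hi < 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired stressor effect for one endpoint
#'
#' Computes the per-set ratios stressor/control, their geometric mean and a
#' back-transformed log2-scale t confidence interval. Sets with a
#' non-positive control value give an undefined ratio and are dropped with
#' a warning; an optional pseudocount can be added to both members instead.
#'
#' @param control,stressor Positive numeric vectors, one entry per paired
#'   set, in matching order.
#' @param level Confidence level in (0, 1).
#' @param pseudocount Value added to both control and stressor before the
#'   ratio (default 0, i.e. drop-on-zero).
#' @return One-row data frame as in [paired_effects_from_ratios()].
#' @export
paired_effect <- function(control, stressor, level = 0.99, pseudocount = 0) {
  if (length(control) != length(stressor)) {
    stop("control and stressor must have the same length")
  }
  ctrl <- control + pseudocount
  str <- stressor + pseudocount
  usable <- is.finite(ctrl) & is.finite(str) & ctrl > 0 & str > 0
  if (any(!usable)) {
    warning(sum(!usable), " paired set(s) dropped (non-positive value)")
  }
  if (sum(usable) < 2L) stop("fewer than 2 usable paired sets")
  ratios <- matrix(str[usable] / ctrl[usable], nrow = 1L,
                   dimnames = list("endpoint", NULL))
  paired_effects_from_ratios(ratios, level = level)
}

#' Confidence-interval exclusion test
#'
#' Significance verdict of a paired effect: `TRUE` when the confidence
#' interval excludes the no-effect value 1, equivalent to a two-sided
#' one-sample t-test of the log-ratios at alpha = 1 - level.
#'
#' @param record Data frame row(s) with `ci_low` and `ci_high` columns.
#' @return Logical vector.
#' @export
exclusion_test <- function(record) {
  if (!all(c("ci_low", "ci_high") %in% colnames(record))) {
    stop("record must have ci_low and ci_high columns")
  }
  !is.na(record$ci_low) & (record$ci_low > 1 | record$ci_high < 1)
}

ratio_matrix <- function(fpm, sets, condition, pseudocount = 0) {
  condition <- match.arg(condition, c("MET", "HUM", "ALL"))
  missing <- setdiff(c(sets$CTRL, sets[[condition]]), colnames(fpm))
  if (length(missing)) {
    stop("paired-set sample(s) absent from FPM matrix: ",
         paste(missing, collapse = ", "))
  }
  num <- fpm[, sets[[condition]], drop = FALSE] + pseudocount
  den <- fpm[, sets$CTRL, drop = FALSE] + pseudocount
  r <- num / den
  r[den <= 0 | num <= 0] <- NA_real_
  colnames(r) <- paste0("set", seq_len(nrow(sets)))
  r
}

#' Per-gene paired stressor effects for one condition
#'
#' Applies [paired_effects_from_ratios()] to every gene of an FPM matrix
#' using the paired sets of the study design.
#'
#' @param fpm FPM matrix from [compute_fpm()].
#' @param sets Paired sets from [build_paired_sets()].
#' @param condition One of `"MET"`, `"HUM"`, `"ALL"`.
#' @param level Confidence level.
#' @param genes Optional subset of gene ids.
#' @param pseudocount See [paired_effect()].
#' @return Data frame, one row per gene (see
#'   [paired_effects_from_ratios()]), with `target_id` = gene id.
#' @export
paired_effect_table <- function(fpm, sets, condition, level = 0.99,
                                genes = NULL, pseudocount = 0) {
  if (!is.null(genes)) {
    present <- intersect(genes, rownames(fpm))
    fpm <- fpm[present, , drop = FALSE]
  }
  if (nrow(sets) < 2L) stop("fewer than 2 paired sets")
  r <- ratio_matrix(fpm, sets, condition, pseudocount)
  paired_effects_from_ratios(r, level = level)
}

#' Built-in paired log-ratio differential-expression test
#'
#' A self-contained alternative to external count-model tools: for each
#' gene the per-set log2 ratios stressor/control are tested against zero
#' with a one-sample test, and p-values are Benjamini-Hochberg adjusted.
#' With `moderate = TRUE` (default) the per-gene variances are shrunk by
#' limma's empirical-Bayes moderation, which restores power at the small
#' number of paired sets typical of this design; `moderate = FALSE` gives
#' the ordinary per-gene t-test.
#'
#' @inheritParams paired_effect_table
#' @param moderate Use empirical-Bayes variance moderation (default TRUE).
#' @return Data frame `gene_id`, `log2fc`, `n_sets`, `p_value`, `fdr`.
#' @export
paired_de_test <- function(fpm, sets, condition, moderate = TRUE,
                           pseudocount = 0) {
  r <- ratio_matrix(fpm, sets, condition, pseudocount)
  lr <- log2(r)
  lr[!is.finite(lr)] <- NA_real_
  n <- rowSums(!is.na(lr))
  m <- rowMeans(lr, na.rm = TRUE)
  m[n < 2L] <- NA_real_
  if (moderate) {
    fit <- limma::lmFit(lr, design = matrix(1, ncol(lr), 1,
                                            dimnames = list(NULL, "mean")))
    fit <- limma::eBayes(fit)
    p <- fit$p.value[, 1L]
  } else {
    dev <- lr - rowMeans(lr, na.rm = TRUE)
    s2 <- rowSums(dev^2, na.rm = TRUE) / pmax(n - 1L, 1L)
    tstat <- m / sqrt(s2 / n)
    p <- 2 * stats::pt(abs(tstat), df = pmax(n - 1L, 1L), lower.tail = FALSE)
  }
  p[n < 2L] <- NA_real_
  data.frame(gene_id = rownames(fpm), log2fc = m, n_sets = n,
             p_value = p, fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Biomarker-panel stressor-effect report
#'
#' Paired effects with exclusion-of-1 verdicts for a fixed panel of marker
#' genes (e.g. phenotypic-switching biomarkers), per stressor condition.
#' A gene counts as affected when its confidence interval excludes 1 in at
#' least one condition; the panel is deliberately tested per gene at the
#' nominal level without multiplicity correction.
#'
#' @inheritParams paired_effect_table
#' @param panel Character vector of panel gene ids.
#' @param conditions Stressor conditions to report.
#' @return List of class `panel_report`: `effects` (data frame with a
#'   `condition` column), `missing` (panel genes absent from the matrix),
#'   `n_affected`, `affected_genes`, `level`.
#' @export
biomarker_panel_report <- function(fpm, sets, panel, level = 0.99,
                                   conditions = c("MET", "HUM", "ALL"),
                                   pseudocount = 0) {
  if (length(panel) == 0L) stop("empty biomarker panel")
  missing <- setdiff(panel, rownames(fpm))
  present <- intersect(panel, rownames(fpm))
  if (length(present) == 0L) stop("no panel genes present in matrix")
  effects <- do.call(rbind, lapply(conditions, function(cond) {
    tab <- paired_effect_table(fpm, sets, cond, level = level,
                               genes = present, pseudocount = pseudocount)
    cbind(condition = cond, tab, stringsAsFactors = FALSE)
  }))
  affected <- unique(effects$target_id[effects$excludes_one])
  structure(list(effects = effects, missing = missing,
                 n_affected = length(affected), affected_genes = affected,
                 level = level),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf(
    "Biomarker panel: %d gene(s) affected at level %.2f (%d missing from matrix)\n",
    x$n_affected, x$level, length(x$missing)))
  invisible(x)
}
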