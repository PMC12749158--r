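# Additive-vs-measured synergy decomposition of stressor effects.
#
# Under purely additive action the combined-stressor log2 fold change of a
# gene equals the sum of the single-stressor log2 fold changes; the synergy
# index is the departure of the measured combined effect from that sum.

#' Additive log2 fold-change prediction
#'
#' @param log2fc_met,log2fc_hum Single-stressor log2 fold changes.
#' @return Their sum (the combined effect expected under additivity).
#' @export
additive_prediction <- function(log2fc_met, log2fc_hum) {
  log2fc_met + log2fc_hum
}

#' Synergy index
#'
#' Measured combined-stressor log2 fold change minus the additive
#' prediction. Positive values mean over-additive (synergistic)
#' up-regulation, negative values over-additive down-regulation.
#'
#' @param log2fc_all Measured combined-stressor log2 fold change.
#' @param log2fc_additive Additive prediction from [additive_prediction()].
#' @return Numeric synergy index.
#' @export
synergy_index <- function(log2fc_all, log2fc_additive) {
  log2fc_all - log2fc_additive
}

#' Through-origin scatter slope of two conditions' fold changes
#'
#' Least-squares slope of the regression through the origin `y = b * x`
#' over a stated gene set: `b = sum(x*y) / sum(x^2)`. A slope near 1 means
#' the two conditions act alike on these genes; a slope well below 1 means
#' most of the combined-stressor effect is absent under the single
#' condition.
#'
#' @param x,y Log2 fold changes of the two conditions (same gene order).
#' @param gene_set_label,x_condition,y_condition Optional labels carried
#'   into the result.
#' @return List of class `slope_result` with `slope`, `n_genes` and the
#'   labels.
#' @export
scatter_slope <- function(x, y, gene_set_label = NA_character_,
                          x_condition = NA_character_,
                          y_condition = NA_character_) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("at least 2 finite points are required")
  if (all(x == 0)) stop("all x values are zero; slope undefined")
  structure(list(slope = sum(x * y) / sum(x * x),
                 n_genes = length(x),
                 gene_set_label = gene_set_label,
                 x_condition = x_condition, y_condition = y_condition),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("Through-origin slope %s ~ %s over %s: %.3f (n = %d genes)\n",
              x$y_condition, x$x_condition, x$gene_set_label, x$slope,
              x$n_genes))
  invisible(x)
}

#' Classify genes by stressor response pattern
#'
#' An explicit per-gene formalization of the aggregate synergy comparison:
#' a combined-stressor DEG whose |synergy index| reaches the fold-change
#' threshold is `synergistic_up`/`synergistic_down` (by the index sign);
#' otherwise a gene significant under exactly one single stressor is
#' `metabolic` or `humoral`; a combined-stressor DEG to which both single
#' stressors contribute is `additive`; everything else is `none`.
#'
#' All arguments are vectorized over genes.
#'
#' @param syn_index Synergy index from [synergy_index()].
#' @param deg_met,deg_hum,deg_all Logical DEG flags per condition.
#' @param threshold_log2fc Non-negative threshold (typically the
#'   variability-derived fold-change threshold, for coherence).
#' @return Character vector of categories.
#' @export
classify_gene <- function(syn_index, deg_met, deg_hum, deg_all,
                          threshold_log2fc) {
  stopifnot(length(threshold_log2fc) == 1L, threshold_log2fc >= 0)
  n <- length(syn_index)
  deg_met <- !is.na(deg_met) & deg_met
  deg_hum <- !is.na(deg_hum) & deg_hum
  deg_all <- !is.na(deg_all) & deg_all
  big <- !is.na(syn_index) & abs(syn_index) >= threshold_log2fc
  out <- rep("none", n)
  out[deg_met & !deg_hum & !big] <- "metabolic"
  out[deg_hum & !deg_met & !big] <- "humoral"
  out[deg_all & deg_met & deg_hum & !big] <- "additive"
  out[deg_all & big & syn_index > 0] <- "synergistic_up"
  out[deg_all & big & syn_index < 0] <- "synergistic_down"
  out
}

#' Build the per-gene synergy table
#'
#' Combines per-condition log2 fold changes into additive predictions,
#' synergy indices and response categories.
#'
#' @param gene_id Character vector of gene ids.
#' @param log2fc_met,log2fc_hum,log2fc_all Per-condition log2 fold changes.
#' @param deg_met,deg_hum,deg_all Logical DEG flags.
#' @param threshold_log2fc Threshold passed to [classify_gene()].
#' @return Data frame `gene_id`, `log2fc_met`, `log2fc_hum`, `log2fc_all`,
#'   `log2fc_additive`, `synergy_index`, `category`.
#' @export
synergy_table <- function(gene_id, log2fc_met, log2fc_hum, log2fc_all,
                          deg_met, deg_hum, deg_all, threshold_log2fc) {
  additive <- additive_prediction(log2fc_met, log2fc_hum)
  si <- synergy_index(log2fc_all, additive)
  data.frame(gene_id = gene_id,
             log2fc_met = log2fc_met, log2fc_hum = log2fc_hum,
             log2fc_all = log2fc_all, log2fc_additive = additive,
             synergy_index = si,
             category = classify_gene(si, deg_met, deg_hum, deg_all,
                                      threshold_log2fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reconcile two DEG sets by confidence-interval concordance
#'
#' Genes apparently unique to one DEG list may be missing from the other
#' only because of the stringent triple filter. For each such gene, the
#' other condition's confidence interval is compared with the first
#' condition's point estimate: when the interval covers the estimate the
#' gene is `concordant` (the two conditions act alike on it despite the
#' differing calls), otherwise `discordant`.
#'
#' @param deg_a,deg_b Character vectors of DEG ids for conditions A and B.
#' @param effects_a,effects_b Paired-effect tables (from
#'   [paired_effect_table()]) covering at least the union of the sets.
#' @param label_a,label_b Condition labels for the output.
#' @return List of class `reconciliation`: `table` (gene, membership,
#'   status), `counts` (Venn-style sizes) and per-side concordance
#'   fractions.
#' @export
reconcile_sets <- function(deg_a, deg_b, effects_a, effects_b,
                           label_a = "A", label_b = "B") {
  union_genes <- union(deg_a, deg_b)
  missing <- setdiff(union_genes,
                     intersect(effects_a$target_id, effects_b$target_id))
  if (length(missing)) {
    stop("effects missing for gene(s): ", paste(missing, collapse = ", "))
  }
  a_only <- setdiff(deg_a, deg_b)
  b_only <- setdiff(deg_b, deg_a)
  both <- intersect(deg_a, deg_b)
  status_for <- function(genes, own_effects, other_effects) {
    if (length(genes) == 0L) return(character(0))
    est <- own_effects$effect[match(genes, own_effects$target_id)]
    lo <- other_effects$ci_low[match(genes, other_effects$target_id)]
    hi <- other_effects$ci_high[match(genes, other_effects$target_id)]
    ifelse(!is.na(lo) & lo <= est & est <= hi, "concordant", "discordant")
  }
  st_a <- status_for(a_only, effects_a, effects_b)
  st_b <- status_for(b_only, effects_b, effects_a)
  tab <- data.frame(
    gene_id = c(both, a_only, b_only),
    membership = c(rep("both", length(both)),
                   rep(paste0(label_a, "_only"), length(a_only)),
                   rep(paste0(label_b, "_only"), length(b_only))),
    status = c(rep("shared", length(both)), st_a, st_b),
    row.names = NULL, stringsAsFactors = FALSE)
  frac <- function(st) if (length(st)) mean(st == "concordant") else NA_real_
  structure(list(
    table = tab,
    counts = c(both = length(both),
               a_only = length(a_only), b_only = length(b_only)),
    label_a = label_a, label_b = label_b,
    concordant_frac_a_only = frac(st_a),
    concordant_frac_b_only = frac(st_b)),
    class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf(
    "DEG reconciliation %s vs %s: %d shared, %d %s-only (%.0f%% concordant), %d %s-only (%.0f%% concordant)\n",
    x$label_a, x$label_b, x$counts[["both"]],
    x$counts[["a_only"]], x$label_a, 100 * x$concordant_frac_a_only,
    x$counts[["b_only"]], x$label_b, 100 * x$concordant_frac_b_only))
  invisible(x)
}

#' Gene-ontology enrichment score
#'
#' The fold-enrichment ratio of ratios
#' `E = (intersection/query) / (term/domain)`.
#'
#' @param intersection_size,query_size,term_size,effective_domain_size
#'   Non-negative integers with `intersection <= min(query, term)` and
#'   `term <= domain`.
#' @return Non-negative enrichment score.
#' @export
enrichment_score <- function(intersection_size, query_size, term_size,
                             effective_domain_size) {
  if (query_size <= 0 || term_size <= 0) {
    stop("query_size and term_size must be positive")
  }
  if (effective_domain_size <= 0) stop("domain size must be positive")
  if (intersection_size < 0 ||
      intersection_size > min(query_size, term_size)) {
    stop("intersection size must lie in [0, min(query, term)]")
  }
  if (term_size > effective_domain_size) {
    stop("term size cannot exceed the effective domain size")
  }
  (intersection_size / query_size) / (term_size / effective_domain_size)
}

#' Export the measured/additive/difference fold-change surface
#'
#' Flattens a synergy table into the three-column surface (measured
#' combined log2FC, additive prediction, difference) used for mesh plots,
#' optionally writing it as TSV. The export is lossless for these three
#' quantities.
#'
#' @param records Synergy table from [synergy_table()].
#' @param path Optional output TSV path.
#' @return Data frame `gene_id`, `measured`, `additive`, `difference`.
#' @export
export_mesh <- function(records, path = NULL) {
  if (nrow(records) == 0L) stop("empty synergy table")
  out <- data.frame(gene_id = records$gene_id,
                    measured = records$log2fc_all,
                    additive = records$log2fc_additive,
                    difference = records$synergy_index,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
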