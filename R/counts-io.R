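#' @keywords internal
"_PACKAGE"

# Valid factor levels of the paired study design.
CONDITIONS <- c("CTRL", "MET", "HUM", "ALL")
CELL_TYPES <- c("WT_VSMC", "KO_VSMC", "EC")
SEXES <- c("male", "female")

# featureCounts-style annotation columns silently dropped when reading a
# count matrix.
ANNOTATION_COLS <- c("Chr", "Start", "End", "Strand", "Length", "gene_name",
                     "gene_biotype")

#' Read a gene x sample count matrix from a TSV file
#'
#' Expects a tab-separated file with a header row of sample identifiers and
#' gene identifiers in the first column (featureCounts-like layout; the usual
#' annotation columns `Chr`, `Start`, `End`, `Strand`, `Length` are ignored).
#' All counts must be non-negative integers and identifiers must be unique.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names.
#' @seealso [write_counts()], [compute_fpm()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("count file must contain at least 1 gene and 1 sample: ", path)
  }
  gene_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  df <- df[, !(colnames(df) %in% ANNOTATION_COLS), drop = FALSE]
  if (ncol(df) == 0L) stop("no sample columns found in ", path)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric count value in ", path)
  validate_counts(mat, gene_ids, colnames(df))
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: the written file round-trips exactly.
#'
#' @param counts Integer matrix as returned by [read_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(mat, gene_ids = rownames(mat),
                            sample_ids = colnames(mat)) {
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("count matrix must carry gene and sample identifiers")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(mat)) stop("missing values in count matrix")
  if (any(mat < 0)) stop("negative count value")
  if (any(mat != round(mat))) stop("non-integer count value")
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(gene_ids, sample_ids)
  mat
}

#' Read and validate a sample sheet
#'
#' The sheet describes the paired design: one row per sequenced sample with
#' the animal it came from, its cell type, sex, passage and stressor
#' condition. Comma- or tab-separated files are accepted.
#'
#' @param path Path to a CSV/TSV file with columns `sample_id`, `animal_id`,
#'   `cell_type` (`WT_VSMC`, `KO_VSMC` or `EC`), `sex` (`male`/`female`),
#'   `passage` (integer) and `condition` (`CTRL`, `MET`, `HUM`, `ALL`).
#' @return Validated data frame with character/integer columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "animal_id", "cell_type", "sex", "passage",
                "condition")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id(s) in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_cond <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = "/"), ")")
  }
  bad_ct <- setdiff(unique(df$cell_type), CELL_TYPES)
  if (length(bad_ct)) {
    stop("unknown cell_type label(s): ", paste(bad_ct, collapse = ", "))
  }
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex)) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  }
  df$passage <- as.integer(df$passage)
  if (anyNA(df$passage)) stop("non-integer passage value")
  df[required]
}

#' Build strictly connected paired sample sets
#'
#' The unit of paired inference is one animal's quadruple of samples
#' (control, metabolic, humoral, combined stressors) taken from the same
#' cell type at the same passage. Groups missing any of the four conditions
#' are dropped with a warning rather than an error, so that real-world
#' sheets with failed samples still yield the usable sets.
#'
#' @param sheet Validated sample sheet (see [read_sample_sheet()]).
#' @return Data frame with one row per paired set: `animal_id`, `cell_type`,
#'   `sex`, `passage` and one column per condition (`CTRL`, `MET`, `HUM`,
#'   `ALL`) holding the sample id.
#' @export
build_paired_sets <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  key <- interaction(sheet$animal_id, sheet$cell_type, sheet$passage,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(sheet, key)
  rows <- lapply(groups, function(g) {
    if (!all(CONDITIONS %in% g$condition)) return(NULL)
    ids <- vapply(CONDITIONS,
                  function(cond) g$sample_id[match(cond, g$condition)], "")
    data.frame(animal_id = g$animal_id[1L], cell_type = g$cell_type[1L],
               sex = g$sex[1L], passage = g$passage[1L],
               t(ids), stringsAsFactors = FALSE)
  })
  incomplete <- names(groups)[vapply(rows, is.null, TRUE)]
  if (length(incomplete)) {
    warning("dropping ", length(incomplete),
            " incomplete paired group(s): ",
            paste(incomplete, collapse = ", "))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no complete paired sets in sample sheet")
  sets <- do.call(rbind, rows)
  sets <- sets[order(sets$animal_id, sets$cell_type, sets$passage), ,
               drop = FALSE]
  rownames(sets) <- NULL
  sets
}

#' Fragments-per-million normalization
#'
#' `fpm[g, s] = counts[g, s] * 1e6 / library_size[s]`. By default the
#' library size of a sample is the total of the counts present in the
#' matrix; an explicit per-sample library size (e.g. total mapped reads)
#' may be supplied instead.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param lib_size Optional numeric vector of per-sample library sizes,
#'   in matrix column order. Defaults to column totals.
#' @return Numeric matrix of FPM values with the same dimnames.
#' @export
compute_fpm <- function(counts, lib_size = NULL) {
  counts <- validate_counts(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (length(lib_size) != ncol(counts)) {
    stop("lib_size must have one entry per sample")
  }
  if (any(lib_size <= 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib_size <= 0], collapse = ", "))
  }
  sweep(counts, 2L, lib_size, "/") * 1e6
}

#' Per-gene mean FPM within sample groups
#'
#' Arithmetic mean FPM per gene within each level of a grouping column of
#' the sample sheet (the stressor condition by default). Used by the
#' expression floor of the differential-expression filter ("at least 3 FPM
#' on average in one of the sample groups").
#'
#' @param fpm FPM matrix from [compute_fpm()].
#' @param sheet Sample sheet covering the matrix columns.
#' @param grouping Name of the sheet column to group by.
#' @return Numeric matrix genes x groups of mean FPM.
#' @export
group_mean_fpm <- function(fpm, sheet, grouping = "condition") {
  sheet <- validate_sample_sheet(sheet)
  if (!all(colnames(fpm) %in% sheet$sample_id)) {
    stop("sample(s) in FPM matrix absent from sheet: ",
         paste(setdiff(colnames(fpm), sheet$sample_id), collapse = ", "))
  }
  groups <- split(sheet$sample_id, sheet[[grouping]])
  if (any(lengths(groups) == 0L)) stop("empty sample group")
  out <- vapply(groups, function(ids) {
    ids <- intersect(ids, colnames(fpm))
    if (length(ids) == 0L) stop("empty sample group after matching to matrix")
    rowMeans(fpm[, ids, drop = FALSE])
  }, numeric(nrow(fpm)))
  rownames(out) <- rownames(fpm)
  out
}
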