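# Shared in-code fixtures: tiny paired designs and random matrices.

# A complete paired sheet: n_animals x 4 conditions for one cell type.
make_sheet <- function(n_animals = 2, cell_type = "WT_VSMC", sex = "male",
                       passage = 3L) {
  conditions <- c("CTRL", "MET", "HUM", "ALL")
  animals <- sprintf("animal%02d", seq_len(n_animals))
  data.frame(
    sample_id = paste0(rep(animals, each = 4), "_", conditions),
    animal_id = rep(animals, each = 4),
    cell_type = cell_type, sex = sex, passage = passage,
    condition = rep(conditions, n_animals),
    stringsAsFactors = FALSE)
}

# Random count matrix matching a sheet.
make_counts <- function(sheet, n_genes = 50, lambda = 100) {
  m <- matrix(rpois(n_genes * nrow(sheet), lambda), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sheet$sample_id))
  storage.mode(m) <- "integer"
  m
}

write_counts_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
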