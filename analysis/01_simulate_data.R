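#!/usr/bin/env Rscript
# Generate the seeded synthetic study: paired four-condition count data
# for the three cell profiles (wildtype VSMC with stressor interaction,
# EGFR-KO VSMC and endothelial cells without humoral effect or
# interaction), plus the phenotype-assay fixtures. Everything downstream
# reads from results/simulated/.

library(vascsynergy)

seed <- 1L
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

profiles <- list(
  WT_VSMC = sim_config(cell_profile = "WT_VSMC", seed = seed),
  KO_VSMC = sim_config(cell_profile = "KO_VSMC", seed = seed + 1L),
  EC      = sim_config(cell_profile = "EC", seed = seed + 2L))

for (name in names(profiles)) {
  sim <- simulate_counts(profiles[[name]])
  write_counts(sim$counts, file.path(outdir, paste0(name, "_counts.tsv")))
  write.table(sim$sheet, file.path(outdir, paste0(name, "_samples.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(outdir, paste0(name, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_aff <- table(sim$truth$class)
  message(sprintf(
    "%s: %d genes x %d samples; true classes: %s", name,
    nrow(sim$counts), ncol(sim$counts),
    paste(names(n_aff), n_aff, sep = "=", collapse = ", ")))
}

# Phenotype fixtures: contracting cell objects, a 60/20/20 cell-cycle
# mixture, a noisy mito-stress trace and random-motility frames.
objs <- simulate_cell_objects(2000, contraction_factor = 0.2,
                              seed = seed + 10L)
write.table(objs$before, file.path(outdir, "cells_before.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(objs$after, file.path(outdir, "cells_after.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
dapi <- simulate_dapi(5000, fractions = c(0.6, 0.2, 0.2), cv = 0.05,
                      seed = seed + 11L)
write.table(dapi, file.path(outdir, "dapi_integrals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
trace <- simulate_ocr_trace(br = 80, pl = 20, nmoc = 20, max_ocr = 160,
                            noise_sd = 2, seed = seed + 12L)
write.table(trace, file.path(outdir, "ocr_trace.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
frames <- simulate_tracks(50, speed_um_h = 8, n_frames = 3, dt_h = 2,
                          seed = seed + 13L)
write.table(frames, file.path(outdir, "track_frames.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("phenotype fixtures written to ", outdir)
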