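#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort that every later stage analyzes.
#
# The stated world: ~2,000 CD8 T cells on a stem->exhausted differentiation
# continuum (well-separated preset: no dropout, NB dispersion 10, marker
# amplitude 8x), a clonal repertoire whose expanding clones contain
# multiple stem-like cells 47.7% of the time, and a 2 x 2 mm tissue with
# one planted Quiescent, Stimulated and Lymphoid aggregate each among
# tumor blobs and scattered background immune cells.

suppressPackageStartupMessages(library(stemniche))

SEED <- 2026L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_preset("well_separated", seed = SEED, n_cells = 2000L)
sim <- simulate_cd8_counts(cfg)
clo <- simulate_clonotypes(cfg, sim$truth)
tis <- simulate_tissue(cfg)

write_expression(sim$counts, file.path(out, "expression"))
write.csv(sim$truth, file.path(out, "truth_cells.csv"), row.names = FALSE)
write.csv(clo$assignments, file.path(out, "clonotypes.csv"), row.names = FALSE)
write.csv(clo$clones, file.path(out, "clones_truth.csv"), row.names = FALSE)
write.csv(tis$map, file.path(out, "cell_map.csv"), row.names = FALSE)
write_expression(tis$expr, file.path(out, "tissue_expression"))
write.csv(tis$truth$cell, file.path(out, "truth_tissue_cells.csv"),
          row.names = FALSE)
write.csv(tis$truth$aggregates, file.path(out, "truth_aggregates.csv"),
          row.names = FALSE)
write_gmt(cd8_signatures(), file.path(out, "signatures.gmt"))

cat(sprintf("CD8 cells: %d (%s)\n", ncol(sim$counts),
            paste(names(table(sim$truth$state)),
                  table(sim$truth$state), collapse = ", ", sep = "=")))
cat(sprintf("clones: %d (%d expanding)\n", nrow(clo$clones),
            sum(clo$clones$expanding)))
cat(sprintf("tissue cells: %d over %d planted aggregates\n",
            nrow(tis$map), nrow(tis$truth$aggregates)))
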