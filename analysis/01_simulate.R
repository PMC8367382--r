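#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw data.
#
# Generates (a) a synthetic 3-round, 12-gene mFISH dataset of a 500x500 um
# claustrum field with 300 excitatory cells arranged as core / shell /
# deep-L6 / cortex, per-round rigid drift (up to 8 px) and elastic warping
# (up to 3 px), plus RSC/LEC retrograde-label channels; and (b) a
# 1112-cell scRNA-seq-like count matrix with the planted Snap25-low (27)
# and Slc17a7-low (74) contaminant classes. Ground truth is written next
# to the images so downstream stages can be scored.

suppressPackageStartupMessages(library(coreshell))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 7L
outdir <- file.path("results", "simulated")

cfg <- default_config(seed = seed)
gt <- generate_ground_truth(
  field_size_um = cfg$field_um, n_cells = cfg$n_cells,
  geometry = cfg$geometry, seed = seed)
rendered <- render_rounds(gt, do.call(optics_model, cfg$optics),
                          seed = seed + 1000L)

write_rounds(rendered, outdir)
write_ground_truth(gt, outdir)
message(sprintf("simulated %d cells over %d rounds -> %s",
                nrow(gt$cells), length(rendered$rounds), outdir))
print(gt)

sim <- generate_count_matrix(n_cells = 1112, seed = seed)
write_counts_mtx(sim, file.path("results", "scrnaseq"))
message(sprintf("simulated %d-cell count matrix (%s planted classes) -> results/scrnaseq",
                ncol(sim$counts), length(unique(sim$truth$class))))
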