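#!/usr/bin/env Rscript
# Stage 5 — overlay retrograde projections on the typed cells.
#
# RSC/LEC tracer channels are binarized with the same histogram-tail rule
# as the probes; a cell is called labeled at one label PAC. Dual-projecting
# cells are excluded (the study found 1.9%), then the core/shell x RSC/LEC
# contingency and the Synpr/Nnat projection differential expression are
# computed.

suppressPackageStartupMessages(library(coreshell))

registered <- read_rounds(file.path("results", "registered"))
qdir <- file.path("results", "quantified")
outdir <- file.path("results", "projections")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rois <- read_label_mask(file.path(qdir, "rois.tif"), 0.5)
calls <- detect_labels(registered$labels, rois)
dual <- exclude_dual(calls)
message(sprintf("labeled cells: %d (%d RSC-only, %d LEC-only, %d dual = %.1f%%, excluded)",
                dual$n_labeled, sum(dual$retained$RSC), sum(dual$retained$LEC),
                dual$n_dual, dual$dual_fraction))
write.csv(calls, file.path(outdir, "projection_calls.csv"), row.names = FALSE)

cell_table <- read.csv(file.path("results", "typed", "cell_table.csv"))
ct <- build_contingency(cell_table, dual$retained)
print(ct)
write.csv(cbind(phenotype = rownames(ct$counts), as.data.frame(ct$counts)),
          file.path(outdir, "contingency.csv"), row.names = FALSE)

pac_df <- read.csv(file.path(qdir, "pac_gated.csv"))
genes <- setdiff(names(pac_df), c("label", "x_px", "y_px", "x_um", "y_um",
                                  "area_px", "area_um2", "animal", "section"))
gated <- structure(list(pac = `rownames<-`(as.matrix(pac_df[, genes]),
                                           pac_df$label),
                        cells = pac_df[, "label", drop = FALSE],
                        genes = data.frame(gene = genes), normalized = FALSE),
                   class = "pac_matrix")
pde <- projection_de(gated, dual$retained)
print(pde$de)
write.csv(pde$de, file.path(outdir, "projection_de.csv"), row.names = FALSE)
write.csv(pde$boxes, file.path(outdir, "projection_boxes.csv"),
          row.names = FALSE)
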