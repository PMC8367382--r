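#!/usr/bin/env Rscript
# Stage 4 — embed, cluster and phenotype the gated cells.
#
# UMAP (15 neighbours) on within-cell normalized PAC, Leiden clustering on
# a 15-NN graph with the resolution scanned until exactly five clusters
# appear, then marker-based phenotyping: highest mean Synpr -> core,
# Nnat -> shell, Ctgf -> deep_L6, leftover clusters ordered by Pcp4. Per-
# cluster one-vs-rest differential expression closes the stage.

suppressPackageStartupMessages(library(coreshell))

qdir <- file.path("results", "quantified")
outdir <- file.path("results", "typed")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 7L

read_pac <- function(path, normalized) {
  df <- read.csv(path)
  meta_cols <- c("label", "x_px", "y_px", "x_um", "y_um", "area_px",
                 "area_um2", "animal", "section", "all_zero")
  genes <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[, genes])
  rownames(m) <- df$label
  structure(list(pac = m, cells = df[, intersect(meta_cols, names(df))],
                 genes = data.frame(gene = genes), normalized = normalized),
            class = "pac_matrix")
}
gated <- read_pac(file.path(qdir, "pac_gated.csv"), FALSE)
norm <- read_pac(file.path(qdir, "pac_norm.csv"), TRUE)

clusters <- cluster_cells(norm, target_k = 5, seed = seed + 2000L)
clusters <- assign_phenotypes(clusters, gated)
emb <- embed_umap(norm, seed = seed + 3000L)
message(sprintf("Leiden: %d clusters at resolution %.2f; phenotypes: %s",
                clusters$k, clusters$resolution,
                paste(sprintf("%s=%s", names(clusters$phenotype),
                              clusters$phenotype), collapse = ", ")))

cell_table <- data.frame(
  cell_id = gated$cells$label, x_um = gated$cells$x_um,
  y_um = gated$cells$y_um, animal = gated$cells$animal,
  cluster = unname(clusters$cluster),
  phenotype = unname(clusters$cell_phenotype),
  UMAP1 = emb[, 1], UMAP2 = emb[, 2])
write.csv(cell_table, file.path(outdir, "cell_table.csv"), row.names = FALSE)

# one-vs-rest DE per cluster over all retained genes
de <- do.call(rbind, lapply(sort(unique(clusters$cluster)), function(k) {
  inside <- names(clusters$cluster)[clusters$cluster == k]
  outside <- setdiff(rownames(gated$pac), inside)
  out <- differential_expression(gated, inside, outside)
  out$cluster <- k
  out$phenotype <- clusters$phenotype[[as.character(k)]]
  out
}))
write.csv(de, file.path(outdir, "de_results.csv"), row.names = FALSE)
top <- de[de$stars != "ns" & de$median_1 > de$median_2, ]
message(sprintf("%d significant cluster-enriched gene hits (Bonferroni)",
                nrow(top)))
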