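# Readers/writers for the pipeline's on-disk artifacts: multi-page 16-bit
# TIFF round stacks, label-mask TIFFs, ground-truth CSV, transform/panel
# JSON, and MatrixMarket count triplets.

#' Write a rendered dataset to a directory
#'
#' Per round: a multi-page 16-bit TIFF (page order DAPI, probe 1..4), named
#' `round_k.tif`; label channels as `label_RSC.tif` / `label_LEC.tif`;
#' `panel.json` with the gene/round/channel map.
#'
#' @param rendered Output of [render_rounds()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rounds <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top <- 2^rendered$optics$bit_depth - 1
  for (st in rendered$rounds) {
    pages <- c(list(st$dapi), unname(st$probes))
    pages <- lapply(pages, function(m) m / top)
    tiff::writeTIFF(pages, file.path(dir, sprintf("round_%d.tif", st$round)),
                    bits.per.sample = 16L)
  }
  for (ch in names(rendered$labels)) {
    tiff::writeTIFF(rendered$labels[[ch]] / top,
                    file.path(dir, sprintf("label_%s.tif", ch)),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(rendered$panel, file.path(dir, "panel.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Read a rendered dataset written by [write_rounds()]
#'
#' @param dir Directory containing `round_*.tif`, `label_*.tif`,
#'   `panel.json`.
#' @param bit_depth Bit depth the images were written at.
#' @return A list shaped like [render_rounds()] output (without `optics`).
#' @export
read_rounds <- function(dir, bit_depth = 16) {
  panel <- jsonlite::read_json(file.path(dir, "panel.json"),
                               simplifyVector = TRUE)
  top <- 2^bit_depth - 1
  round_files <- sort(list.files(dir, pattern = "^round_\\d+\\.tif$",
                                 full.names = TRUE))
  rounds <- lapply(round_files, function(f) {
    k <- as.integer(sub(".*round_(\\d+)\\.tif$", "\\1", f))
    pages <- tiff::readTIFF(f, all = TRUE)
    pages <- lapply(pages, function(p) round(p * top))
    genes <- panel$gene[panel$round == k]
    probes <- pages[-1]
    names(probes) <- genes
    list(round = k, dapi = pages[[1]], probes = probes)
  })
  labels <- list()
  for (ch in c("RSC", "LEC")) {
    f <- file.path(dir, sprintf("label_%s.tif", ch))
    if (file.exists(f)) labels[[ch]] <- round(tiff::readTIFF(f) * top)
  }
  list(rounds = rounds, labels = labels, panel = panel)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask A `label_mask`.
#' @param path Output file.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"), max(mask$labels) < 65536)
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path TIFF file.
#' @param pixel_size_um Pixel size to attach.
#' @return A `label_mask`.
#' @export
read_label_mask <- function(path, pixel_size_um) {
  label_mask(matrix(as.integer(round(tiff::readTIFF(path) * 65535)),
                    nrow = dim(tiff::readTIFF(path))[1]),
             pixel_size_um)
}

#' Write ground truth tables
#'
#' `ground_truth.csv` (cell table) and `transforms.json` (per-round rigid
#' shift and elastic control grid).
#'
#' @param gt A `ground_truth`.
#' @param dir Output directory.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(gt$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  tr <- lapply(gt$transforms, function(t) {
    list(round = t$round, dx = t$dx, dy = t$dy,
         elastic = list(nodes_x = t$elastic$nodes_x,
                        nodes_y = t$elastic$nodes_y,
                        du = t$elastic$du, dv = t$elastic$dv,
                        amp_px = t$elastic$amp_px))
  })
  jsonlite::write_json(tr, file.path(dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' `counts.mtx`, `genes.tsv` (one gene per line), `cells.tsv` (cell id,
#' planted class, projection).
#'
#' @param sim Output of [generate_count_matrix()].
#' @param dir Output directory.
#' @export
write_counts_mtx <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(sim$counts), file.path(dir, "genes.tsv"))
  utils::write.table(sim$truth, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a MatrixMarket count matrix with sidecars
#'
#' @param dir Directory holding `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A list with `counts` (dense genes x cells matrix) and `truth`.
#' @export
read_counts_mtx <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  truth <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, truth$cell_id)
  list(counts = counts, truth = truth, genes = genes)
}
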