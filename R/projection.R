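# Retrograde projection overlay: automated label calling from the RSC/LEC
# tracer channels (PAC >= 1 at the same histogram-tail binarization used
# for probes), dual-projection exclusion, and the core/shell x RSC/LEC
# contingency arithmetic.

#' Call retrogradely labeled cells from tracer channels
#'
#' Each label channel is binarized at its tail-fraction threshold; a cell is
#' called labeled for that projection when its label PAC meets
#' `min_label_pac`. A channel missing from `label_images` is simply absent
#' from the calls (with a warning). `dual` is `RSC AND LEC`.
#'
#' @param label_images Named list of registered label channel matrices
#'   (names among "RSC", "LEC").
#' @param rois A `label_mask` of expanded ROIs.
#' @param tail_fraction Binarization tail fraction (default 0.005).
#' @param min_label_pac Label-positive threshold in PAC units (default 1).
#' @return A data.frame of class `projection_calls`: cell_id, per-channel
#'   label PAC, RSC/LEC logical flags, dual flag.
#' @export
detect_labels <- function(label_images, rois, tail_fraction = 0.005,
                          min_label_pac = 1) {
  stopifnot(inherits(rois, "label_mask"))
  channels <- c("RSC", "LEC")
  missing <- setdiff(channels, names(label_images))
  if (length(missing)) {
    warning("label channel(s) missing: ", paste(missing, collapse = ", "))
  }
  n <- max(rois$labels, 0L)
  calls <- data.frame(cell_id = seq_len(n))
  for (ch in channels) {
    if (ch %in% names(label_images)) {
      pac <- compute_pac(binarize_probe(label_images[[ch]], tail_fraction), rois)
      calls[[paste0(tolower(ch), "_pac")]] <- unname(pac)
      calls[[ch]] <- unname(pac) >= min_label_pac
    } else {
      calls[[ch]] <- FALSE
    }
  }
  calls$dual <- calls$RSC & calls$LEC
  class(calls) <- c("projection_calls", class(calls))
  calls
}

#' Exclude dual-projecting cells
#'
#' Removes cells labeled for both targets from RSC-vs-LEC comparisons and
#' reports the dual fraction as a percentage of all labeled cells (one
#' decimal place) - e.g. 14 dual of 739 labeled gives 1.9%.
#'
#' @param calls A `projection_calls` data.frame.
#' @return A list: `retained` (single-projection calls), `dual_fraction`
#'   (percent, 1 decimal), `n_labeled`, `n_dual`.
#' @export
exclude_dual <- function(calls) {
  labeled <- calls[calls$RSC | calls$LEC, , drop = FALSE]
  n_dual <- sum(labeled$dual)
  retained <- labeled[!labeled$dual, , drop = FALSE]
  frac <- if (nrow(labeled) == 0) 0 else 100 * n_dual / nrow(labeled)
  list(retained = retained,
       dual_fraction = round_half_up(frac, 1),
       n_labeled = nrow(labeled), n_dual = n_dual)
}

#' Core/shell x RSC/LEC contingency table
#'
#' Counts single-projection cells per phenotype and reports, for each
#' projection, the integer-rounded percentage of its cells falling in the
#' modal claustrum phenotype (core for RSC, shell for LEC): e.g. 216 core
#' of 259 RSC cells gives 83%. A projection with zero cells gets NA.
#'
#' @param cell_table A data.frame with `cell_id` and `phenotype` columns.
#' @param calls Retained `projection_calls` (after [exclude_dual()]).
#' @param phenotypes Phenotype rows of the table (default core and shell).
#' @return A list of class `contingency_table`: `counts` (phenotype x
#'   projection), `column_totals`, `percent` (per projection, percent of
#'   its labeled cells in each phenotype), `modal_percent`.
#' @export
build_contingency <- function(cell_table, calls,
                              phenotypes = c("core", "shell")) {
  stopifnot(all(c("cell_id", "phenotype") %in% names(cell_table)))
  ph <- stats::setNames(cell_table$phenotype, cell_table$cell_id)
  counts <- matrix(0L, length(phenotypes), 2,
                   dimnames = list(phenotypes, c("RSC", "LEC")))
  for (proj in c("RSC", "LEC")) {
    ids <- calls$cell_id[calls[[proj]]]
    p <- ph[as.character(ids)]
    p <- p[!is.na(p)]
    counts[, proj] <- vapply(phenotypes, function(x) sum(p == x, na.rm = TRUE),
                             integer(1))
  }
  totals <- colSums(counts)
  percent <- percent_columns(counts, totals)
  modal <- c(RSC = if ("core" %in% phenotypes) percent["core", "RSC"] else NA,
             LEC = if ("shell" %in% phenotypes) percent["shell", "LEC"] else NA)
  res <- list(counts = counts, column_totals = totals,
              percent = percent, modal_percent = modal)
  class(res) <- "contingency_table"
  validate_contingency(res)
  res
}

# Column-wise integer-rounded percentages; zero-total columns become NA.
percent_columns <- function(counts, totals) {
  percent <- counts * NA_real_
  for (j in seq_along(totals)) {
    if (totals[j] > 0) percent[, j] <- round_half_up(100 * counts[, j] / totals[j])
  }
  percent
}

# Internal consistency: every reported percentage must recompute exactly
# from its own counts.
validate_contingency <- function(ct) {
  for (proj in colnames(ct$counts)) {
    tot <- ct$column_totals[[proj]]
    if (tot == 0) next
    recomputed <- round_half_up(100 * ct$counts[, proj] / tot)
    stopifnot(identical(unname(recomputed), unname(ct$percent[, proj])))
  }
  invisible(ct)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("projection contingency (counts):\n")
  print(x$counts)
  cat("column totals:", paste(sprintf("%s=%d", names(x$column_totals),
                                      x$column_totals), collapse = ", "), "\n")
  cat(sprintf("modal percentages: RSC-in-core %s%%, LEC-in-shell %s%%\n",
              x$modal_percent[["RSC"]], x$modal_percent[["LEC"]]))
  invisible(x)
}

#' Projection-wise differential expression with box-plot summaries
#'
#' Mann-Whitney U with Bonferroni correction per gene between RSC- and
#' LEC-projecting (single-projection) cells, plus per-group box summaries
#' following the figure convention: hinges at the first and third
#' quartiles, whiskers to the furthest point within 1.5 x IQR of the hinge,
#' outliers beyond the whiskers suppressed from the summary.
#'
#' @param pac_raw A raw `pac_matrix`.
#' @param calls Retained `projection_calls` (after [exclude_dual()]).
#' @param genes Genes to test (default Synpr and Nnat).
#' @return A list: `de` (a `de_result`), `boxes` (per gene x group summary
#'   data.frame).
#' @export
projection_de <- function(pac_raw, calls, genes = c("Synpr", "Nnat")) {
  rsc <- intersect(calls$cell_id[calls$RSC], rownames(pac_raw$pac))
  lec <- intersect(calls$cell_id[calls$LEC], rownames(pac_raw$pac))
  if (length(rsc) == 0 || length(lec) == 0) {
    stop("both projection groups must be non-empty")
  }
  de <- differential_expression(pac_raw, rsc, lec, genes = genes)
  names(de)[names(de) == "median_1"] <- "median_RSC"
  names(de)[names(de) == "median_2"] <- "median_LEC"
  boxes <- do.call(rbind, lapply(genes, function(g) {
    rbind(box_summary(pac_raw$pac[rsc, g], g, "RSC"),
          box_summary(pac_raw$pac[lec, g], g, "LEC"))
  }))
  list(de = de, boxes = boxes)
}

box_summary <- function(x, gene, group) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- suppressWarnings(min(x[x >= q[1] - 1.5 * iqr]))
  hi <- suppressWarnings(max(x[x <= q[3] + 1.5 * iqr]))
  data.frame(gene = gene, group = group, lower_whisker = lo, q1 = q[1],
             median = q[2], q3 = q[3], upper_whisker = hi,
             n = length(x), stringsAsFactors = FALSE)
}
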