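# scRNA-seq bookkeeping: CPM normalization, the two sequential exclusion
# filters (Snap25 CPM < 0.001, then Slc17a7 CPM < 1e-10), the retained-cell
# ledger, and the transcriptomic-class x projection contingency arithmetic.

#' Counts-per-million normalization
#'
#' `CPM(g, c) = 1e6 * count(g, c) / total counts of cell c`. Every column
#' of the result sums to 1e6.
#'
#' @param counts Genes x cells numeric matrix (column sums must be > 0).
#' @return The CPM matrix.
#' @export
compute_cpm <- function(counts) {
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("cell(s) with zero total counts: ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Default QC rules
#'
#' Snap25 CPM < 0.001 (putative non-neuronal), then Slc17a7 CPM < 1e-10
#' (putative non-excitatory), applied sequentially in that order.
#'
#' @return A list of rules, each `list(gene, threshold)`.
#' @export
default_qc_rules <- function() {
  list(list(gene = "Snap25", threshold = 0.001),
       list(gene = "Slc17a7", threshold = 1e-10))
}

#' Sequential QC filtering with an exclusion ledger
#'
#' Applies the rules in order: a cell excluded by rule i is attributed to
#' rule i and not re-tested by later rules, so the ledger decomposes the
#' input exactly (`n_input = sum(excluded per rule) + n_retained`).
#' Swapping rule order may change attribution but never the retained count.
#'
#' @param cpm CPM matrix from [compute_cpm()].
#' @param rules List of rules as in [default_qc_rules()].
#' @return A list of class `qc_ledger`: `n_input`, `n_excluded` (named per
#'   rule gene), `n_retained`, `retained` (cell names), `reason` (per-cell
#'   exclusion attribution, "retained" if kept).
#' @export
qc_filter <- function(cpm, rules = default_qc_rules()) {
  genes <- vapply(rules, `[[`, character(1), "gene")
  missing <- setdiff(genes, rownames(cpm))
  if (length(missing)) stop("QC rule gene(s) absent: ",
                            paste(missing, collapse = ", "))
  n <- ncol(cpm)
  cells <- colnames(cpm) %||% as.character(seq_len(n))
  reason <- stats::setNames(rep("retained", n), cells)
  alive <- rep(TRUE, n)
  n_excluded <- stats::setNames(integer(length(rules)), genes)
  for (i in seq_along(rules)) {
    fail <- alive & (cpm[genes[i], ] < rules[[i]]$threshold)
    reason[fail] <- genes[i]
    n_excluded[i] <- sum(fail)
    alive <- alive & !fail
  }
  ledger <- list(n_input = n, n_excluded = n_excluded,
                 n_retained = sum(alive), retained = cells[alive],
                 reason = reason)
  stopifnot(ledger$n_input == sum(ledger$n_excluded) + ledger$n_retained)
  class(ledger) <- "qc_ledger"
  ledger
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat(sprintf("QC ledger: %d cells in", x$n_input))
  for (g in names(x$n_excluded)) cat(sprintf(", -%d %s-low", x$n_excluded[[g]], g))
  cat(sprintf(" -> %d retained\n", x$n_retained))
  invisible(x)
}

#' Marker-max transcriptomic class labels
#'
#' Assigns each cell the class of its highest-CPM marker among
#' Synpr / Nnat / Ctgf (a deliberately simple stand-in for full
#' graph-based clustering of the count data, which is out of scope).
#'
#' @param cpm CPM matrix.
#' @param markers Named map class -> gene.
#' @return Named character vector of class labels per cell.
#' @export
marker_max_classes <- function(cpm, markers = c(synpr_high = "Synpr",
                                                nnat_high = "Nnat",
                                                cortical = "Ctgf")) {
  stopifnot(all(markers %in% rownames(cpm)))
  sub <- cpm[markers, , drop = FALSE]
  cls <- names(markers)[apply(sub, 2, which.max)]
  stats::setNames(cls, colnames(cpm))
}

#' Transcriptomic-class x projection contingency table
#'
#' Same count/percentage contract as [build_contingency()], applied to
#' per-cell class labels and RSC/LEC projection annotations aligned by cell
#' id: e.g. 204 of 241 RSC-projecting cells in the Synpr class gives 85%.
#'
#' @param class_labels Named character vector (cell id -> class).
#' @param projection_labels Named character vector (cell id -> "RSC",
#'   "LEC" or anything else for unlabeled).
#' @param classes Class rows of the table (default Synpr/Nnat classes).
#' @param modal Named map projection -> its modal class.
#' @return A `contingency_table`.
#' @export
class_projection_contingency <- function(class_labels, projection_labels,
                                         classes = c("synpr_high", "nnat_high"),
                                         modal = c(RSC = "synpr_high",
                                                   LEC = "nnat_high")) {
  ids <- intersect(names(class_labels), names(projection_labels))
  counts <- matrix(0L, length(classes), 2,
                   dimnames = list(classes, c("RSC", "LEC")))
  for (proj in c("RSC", "LEC")) {
    sel <- ids[projection_labels[ids] == proj]
    counts[, proj] <- vapply(classes,
                             function(x) sum(class_labels[sel] == x),
                             integer(1))
  }
  totals <- colSums(counts)
  percent <- percent_columns(counts, totals)
  modal_percent <- vapply(c("RSC", "LEC"), function(p) {
    if (totals[[p]] == 0) NA_real_ else percent[modal[[p]], p]
  }, numeric(1))
  res <- list(counts = counts, column_totals = totals, percent = percent,
              modal_percent = modal_percent)
  class(res) <- "contingency_table"
  validate_contingency(res)
  res
}
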