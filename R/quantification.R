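# Percent-area-covered (PAC) quantification: per-gene histogram-tail
# binarization of the registered probe image, then per-cell positive-pixel
# fraction within the expanded ROI, times 100.

#' Default per-gene tail fractions
#'
#' 0.5% (the midpoint of the stated 0.2-1% range) for every probe except
#' the highly abundant excitatory gate gene, which uses the top of the
#' range (1%): Slc17a7 is expressed in every excitatory cell, so its
#' positive-signal budget must be larger for the one-PAC gate to reflect
#' expression rather than the binarization cap.
#'
#' @param genes Gene names (default: the 12-gene panel).
#' @param base Tail fraction for ordinary probes.
#' @param gate_gene,gate Gene and tail fraction for the abundant gate probe.
#' @return Named numeric vector of tail fractions.
#' @export
default_tail_fractions <- function(genes = default_panel()$gene, base = 0.005,
                                   gate_gene = "Slc17a7", gate = 0.01) {
  tf <- stats::setNames(rep(base, length(genes)), genes)
  if (gate_gene %in% genes) tf[gate_gene] <- gate
  tf
}

#' Histogram-tail binarization threshold
#'
#' Returns the smallest intensity `t` such that the fraction of pixels
#' strictly above `t` is at most `tail_fraction` (the "last 0.2-1% of the
#' histogram tail" rule; default midpoint 0.5%). Because the threshold is a
#' quantile of the full image histogram, PAC is invariant to any monotone
#' intensity rescaling applied before thresholding.
#'
#' @param probe_image Numeric matrix.
#' @param tail_fraction Fraction of pixels allowed above threshold,
#'   in (0, 1); the study's stated range is [0.002, 0.01].
#' @return The threshold intensity.
#' @export
compute_threshold <- function(probe_image, tail_fraction = 0.005) {
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  v <- as.vector(probe_image)
  if (length(unique(v)) == 1L) {
    warning("constant image: threshold equals the constant, no positive pixels")
    return(v[1])
  }
  n <- length(v)
  k <- floor(tail_fraction * n)
  if (k == 0) return(max(v))
  sort(v, partial = n - k)[n - k]
}

#' Binarize a probe image at its tail threshold
#'
#' @inheritParams compute_threshold
#' @return A logical matrix (`TRUE` = positive); pixels strictly above the
#'   threshold are positive.
#' @export
binarize_probe <- function(probe_image, tail_fraction = 0.005) {
  t <- suppressWarnings(compute_threshold(probe_image, tail_fraction))
  probe_image > t
}

#' Percent area covered per cell
#'
#' `PAC(cell) = 100 * (positive pixels within the ROI) / (ROI pixel area)`.
#'
#' @param binary_positive Logical matrix of positive pixels.
#' @param rois A `label_mask` of expanded ROIs.
#' @return Named numeric vector of PAC values (names = labels 1..N).
#' @export
compute_pac <- function(binary_positive, rois) {
  stopifnot(inherits(rois, "label_mask"),
            all(dim(binary_positive) == dim(rois$labels)))
  lab <- rois$labels
  n <- max(lab, 0L)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  area <- tabulate(lab[lab > 0L], nbins = n)
  if (any(area == 0)) stop("ROI with zero pixel area")
  pos <- tabulate(lab[lab > 0L & binary_positive], nbins = n)
  stats::setNames(100 * pos / area, as.character(seq_len(n)))
}

#' Build the cells x genes PAC matrix from registered rounds
#'
#' Thresholds every registered probe channel at its per-gene tail fraction
#' (computed over the whole image, per section) and scores every ROI.
#'
#' @param registered Output of [register_rounds()] (or [render_rounds()] if
#'   no registration is needed).
#' @param rois A `label_mask` of expanded ROIs.
#' @param tail_fraction Scalar or per-gene named vector in [0.002, 0.01].
#' @param cells Optional data.frame of per-cell metadata (from
#'   [mask_centroids()]); computed from `rois` when NULL.
#' @param animal_id,section_id Identifiers stored in the row metadata.
#' @return A `pac_matrix` object: list with `pac` (cells x genes matrix,
#'   raw percent units), `cells` (row metadata), `genes` (column metadata:
#'   gene, round, channel, threshold), `normalized = FALSE`.
#' @export
build_pac_matrix <- function(registered, rois,
                             tail_fraction = default_tail_fractions(),
                             cells = NULL, animal_id = "A1", section_id = "S1") {
  panel <- registered$panel
  if (is.null(cells)) cells <- mask_centroids(rois)
  tf <- if (length(tail_fraction) == 1L) {
    stats::setNames(rep(tail_fraction, nrow(panel)), panel$gene)
  } else {
    stopifnot(all(panel$gene %in% names(tail_fraction)))
    tail_fraction[panel$gene]
  }
  out_of_band <- tf < 0.002 | tf > 0.01
  if (any(out_of_band)) {
    warning(sprintf("tail fraction outside [0.002, 0.01] for: %s",
                    paste(names(tf)[out_of_band], collapse = ", ")))
  }
  pac <- matrix(NA_real_, nrow(cells), nrow(panel),
                dimnames = list(cells$label, panel$gene))
  thresholds <- numeric(nrow(panel))
  for (j in seq_len(nrow(panel))) {
    g <- panel$gene[j]
    img <- registered$rounds[[panel$round[j]]]$probes[[g]]
    thresholds[j] <- suppressWarnings(compute_threshold(img, tf[[g]]))
    pac[, j] <- compute_pac(img > thresholds[j], rois)[as.character(cells$label)]
  }
  genes <- cbind(panel, threshold = thresholds, tail_fraction = unname(tf))
  cells$animal <- animal_id
  cells$section <- section_id
  structure(list(pac = pac, cells = cells, genes = genes, normalized = FALSE),
            class = "pac_matrix")
}

#' Gate cells on the excitatory marker
#'
#' Retains cells whose PAC of the gate gene meets the threshold (default:
#' one PAC of Slc17a7, inclusive), then drops the gate gene column: the
#' gate marker is used only for inclusion, never for downstream analysis.
#'
#' @param pac A raw `pac_matrix`.
#' @param gate_gene Gene used for gating (default "Slc17a7").
#' @param min_pac Inclusion threshold (default 1; rule is `>=`).
#' @return The gated `pac_matrix`, with a `gate` element recording
#'   `retained` / `total` counts.
#' @export
gate_excitatory <- function(pac, gate_gene = "Slc17a7", min_pac = 1) {
  stopifnot(inherits(pac, "pac_matrix"))
  if (!gate_gene %in% colnames(pac$pac)) {
    stop(sprintf("gate gene '%s' not present in the PAC matrix", gate_gene))
  }
  keep <- pac$pac[, gate_gene] >= min_pac
  total <- nrow(pac$pac)
  pac$pac <- pac$pac[keep, setdiff(colnames(pac$pac), gate_gene), drop = FALSE]
  pac$cells <- pac$cells[keep, , drop = FALSE]
  pac$genes <- pac$genes[pac$genes$gene != gate_gene, , drop = FALSE]
  pac$gate <- list(gene = gate_gene, min_pac = min_pac,
                   retained = sum(keep), total = total)
  pac
}

#' Within-cell (L1) normalization of PAC profiles
#'
#' Divides every row with a positive sum by its sum, so each cell's profile
#' sums to 1; all-zero rows are left at zero and flagged in
#' `cells$all_zero`.
#'
#' @param pac A raw `pac_matrix` (normalizing twice is an error).
#' @return The normalized `pac_matrix` (`normalized = TRUE`).
#' @export
normalize_within_cell <- function(pac) {
  stopifnot(inherits(pac, "pac_matrix"))
  if (isTRUE(pac$normalized)) stop("PAC matrix is already normalized")
  rs <- rowSums(pac$pac)
  nz <- rs > 0
  pac$pac[nz, ] <- pac$pac[nz, , drop = FALSE] / rs[nz]
  pac$cells$all_zero <- !nz
  pac$normalized <- TRUE
  pac
}

#' @export
print.pac_matrix <- function(x, ...) {
  cat(sprintf("pac_matrix: %d cells x %d genes (%s)\n",
              nrow(x$pac), ncol(x$pac),
              if (isTRUE(x$normalized)) "within-cell normalized" else "raw PAC %"))
  invisible(x)
}
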