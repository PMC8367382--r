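# Nuclei segmentation from the reference-round DAPI and non-overlapping
# somatic ROI expansion ("dilated by 5 um to include the surrounding
# cytosol"). Built on EBImage primitives: Gaussian smoothing, Otsu
# foreground, distance-transform watershed to split touching nuclei, and
# Voronoi-style label propagation for the expansion.

#' Create a label mask object
#'
#' Integer-labelled image (0 = background, 1..N cell ids) with pixel
#' geometry attached.
#'
#' @param labels Integer matrix of labels.
#' @param pixel_size_um Microns per pixel.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' Segment nuclei from a DAPI image
#'
#' Deterministic recipe: Gaussian smoothing (sigma 2 px), Otsu global
#' threshold, distance-transform watershed to split touching nuclei, and
#' removal of objects below `min_area_um2`. Labels are relabelled
#' contiguously 1..N.
#'
#' @param dapi Numeric DAPI matrix.
#' @param pixel_size_um Microns per pixel.
#' @param min_area_um2 Minimum object area kept (default 20 um^2).
#' @param sigma_px Smoothing sigma (default 2 px).
#' @param watershed_tolerance Minimum basin depth (px of the distance map)
#'   for a watershed split; defaults to 0.5 (smoothing shallows the neck
#'   between touching nuclei, so the split threshold must be sub-pixel).
#' @param min_contrast Minimum foreground/background separation, in
#'   background standard deviations of the smoothed image; below it the
#'   image is treated as signal-free and zero labels are returned.
#' @return A `label_mask` of nuclei.
#' @export
segment_nuclei <- function(dapi, pixel_size_um, min_area_um2 = 20,
                           sigma_px = 2, watershed_tolerance = 0.5,
                           min_contrast = 5) {
  rng <- range(dapi)
  if (diff(rng) == 0) stop("cannot segment a constant image")
  x <- (dapi - rng[1]) / diff(rng)
  sm <- blur(x, sigma_px)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > th
  contrast <- (mean(sm[mask]) - mean(sm[!mask])) /
    max(stats::sd(sm[!mask]), 1e-12)
  if (!any(mask) || !any(!mask) || contrast < min_contrast) {
    return(label_mask(matrix(0L, nrow(dapi), ncol(dapi)), pixel_size_um))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::imageData(EBImage::watershed(dm,
                                                  tolerance = watershed_tolerance,
                                                  ext = 1))
  labels <- matrix(as.integer(labels), nrow(dapi), ncol(dapi))
  # drop debris below the area floor and relabel contiguously
  min_px <- min_area_um2 / pixel_size_um^2
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  label_mask(labels, pixel_size_um)
}

#' Expand nuclei into non-overlapping somatic ROIs
#'
#' Grows every nucleus isotropically by `radius_um`; contested pixels go to
#' the nearest nucleus (Voronoi propagation), so expanded ROIs are pairwise
#' disjoint and probe signal is never double-counted. Original nucleus
#' pixels keep their label and no label is created or deleted.
#'
#' @param nuclei A `label_mask` of nuclei.
#' @param radius_um Expansion radius in microns (default 5).
#' @return A `label_mask` of expanded ROIs.
#' @export
expand_rois <- function(nuclei, radius_um = 5) {
  stopifnot(inherits(nuclei, "label_mask"))
  if (radius_um < 0) stop("expansion radius must be non-negative")
  if (radius_um == 0 || !any(nuclei$labels > 0L)) return(nuclei)
  r_px <- radius_um / nuclei$pixel_size_um
  # distance from every background pixel to the nearest nucleus pixel
  bg <- EBImage::Image((nuclei$labels == 0L) * 1)
  d <- as.matrix(EBImage::distmap(bg))
  mask <- d <= r_px
  zero <- EBImage::Image(matrix(0, nrow(nuclei$labels), ncol(nuclei$labels)))
  out <- EBImage::propagate(zero, EBImage::Image(nuclei$labels), mask = mask,
                            lambda = 1e10)
  labels <- matrix(as.integer(EBImage::imageData(out)),
                   nrow(nuclei$labels), ncol(nuclei$labels))
  labels[nuclei$labels > 0L] <- nuclei$labels[nuclei$labels > 0L]
  label_mask(labels, nuclei$pixel_size_um)
}

#' Per-label centroids and areas
#'
#' @param mask A `label_mask`.
#' @return A data.frame with `label`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `area_px`, `area_um2` (one row per label, ordered by label).
#' @export
mask_centroids <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  pos <- which(lab > 0L)
  if (length(pos) == 0) {
    return(data.frame(label = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0)))
  }
  l <- lab[pos]
  r <- ((pos - 1L) %% nrow(lab)) + 1L
  c <- ((pos - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l)
  ids <- which(area > 0)
  # pixel (r, c) is centred at (c - 0.5, r - 0.5) in pixel units
  xs <- (tapply(c, l, sum)[as.character(ids)] / area[ids]) - 0.5
  ys <- (tapply(r, l, sum)[as.character(ids)] / area[ids]) - 0.5
  data.frame(label = ids,
             x_px = as.numeric(xs), y_px = as.numeric(ys),
             x_um = as.numeric(xs) * mask$pixel_size_um,
             y_um = as.numeric(ys) * mask$pixel_size_um,
             area_px = area[ids],
             area_um2 = area[ids] * mask$pixel_size_um^2)
}
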