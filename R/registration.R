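# Two-stage round-to-round registration anchored on DAPI: whole-image rigid
# translation by FFT cross-correlation, then an elastic displacement field
# from normalized-cross-correlation block matching on a regular grid,
# smoothed and bilinearly densified. Convention: a transform (dx, dy) means
# the moving image's content sits at reference position + (dx, dy), i.e.
# moving(r, c) = reference(r - dy, c - dx); aligning resamples the moving
# image at (r + dy + v, c + dx + u).

#' Estimate the rigid shift between two DAPI images
#'
#' Whole-image FFT cross-correlation of mean-subtracted images with 3-point
#' parabolic sub-pixel refinement of the correlation peak. Translation-only:
#' slides are re-imaged in place across rounds, so rotation is second-order
#' and not modelled.
#'
#' @param reference_dapi,moving_dapi Numeric matrices of identical shape.
#' @return A list of class `rigid_transform` with sub-pixel `dx`, `dy` (px).
#' @export
estimate_rigid <- function(reference_dapi, moving_dapi) {
  stopifnot(all(dim(reference_dapi) == dim(moving_dapi)))
  if (stats::sd(reference_dapi) == 0 || stats::sd(moving_dapi) == 0) {
    stop("no registration signal: constant image")
  }
  a <- reference_dapi - mean(reference_dapi)
  b <- moving_dapi - mean(moving_dapi)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  n <- dim(cc)
  wrap <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
  # parabolic refinement along each axis using circular neighbours
  refine <- function(axis) {
    i <- peak[axis]
    nn <- n[axis]
    at <- function(k) {
      idx <- peak
      idx[axis] <- ((i - 1 + k) %% nn) + 1
      cc[idx[1], idx[2]]
    }
    c0 <- at(0); cm <- at(-1); cp <- at(1)
    denom <- cm - 2 * c0 + cp
    offs <- if (denom == 0) 0 else 0.5 * (cm - cp) / denom
    wrap(i, nn) + max(min(offs, 0.5), -0.5)
  }
  structure(list(dx = refine(2), dy = refine(1)), class = "rigid_transform")
}

#' Estimate a smooth elastic displacement field
#'
#' Normalized-cross-correlation block matching of the rigidly pre-aligned
#' DAPI image against the reference on a regular grid, followed by
#' confidence-aware smoothing of the grid displacements and bilinear
#' interpolation to a dense per-pixel field. Low-texture blocks (no nuclei)
#' are dropped and filled from their neighbours, so accuracy is only claimed
#' where registration signal exists.
#'
#' @param reference_dapi Reference-round DAPI image.
#' @param aligned_dapi Moving DAPI after rigid alignment.
#' @param grid_spacing_px Block/grid spacing in px (default 64).
#' @param search_px Maximum displacement searched per block (default 16).
#' @param max_displacement_px Cap on the output field magnitude (default 10).
#' @return A list of class `displacement_field` with dense `u`, `v`
#'   matrices (px, same shape as the image) and the node-level `grid`.
#' @export
estimate_elastic <- function(reference_dapi, aligned_dapi,
                             grid_spacing_px = 64, search_px = 16,
                             max_displacement_px = 10) {
  d <- dim(reference_dapi)
  stopifnot(all(d == dim(aligned_dapi)))
  if (grid_spacing_px > min(d)) {
    stop("grid spacing exceeds image size")
  }
  win <- grid_spacing_px
  half <- floor(win / 2)
  nodes_r <- seq(half + 1, d[1] - half, by = grid_spacing_px)
  nodes_c <- seq(half + 1, d[2] - half, by = grid_spacing_px)
  sd_global <- stats::sd(reference_dapi)
  pad <- 2^ceiling(log2(win + 2 * search_px))

  du <- matrix(NA_real_, length(nodes_r), length(nodes_c))
  dv <- matrix(NA_real_, length(nodes_r), length(nodes_c))
  conf <- matrix(0, length(nodes_r), length(nodes_c))
  for (i in seq_along(nodes_r)) {
    for (j in seq_along(nodes_c)) {
      rr <- (nodes_r[i] - half):(nodes_r[i] + half - 1)
      cc <- (nodes_c[j] - half):(nodes_c[j] + half - 1)
      ra <- reference_dapi[rr, cc]
      rb <- aligned_dapi[rr, cc]
      if (stats::sd(ra) < 0.05 * sd_global || stats::sd(rb) < 0.05 * sd_global) next
      sh <- block_shift(ra, rb, pad, search_px)
      if (is.null(sh)) next
      du[i, j] <- sh["dx"]; dv[i, j] <- sh["dy"]; conf[i, j] <- sh["peak"]
    }
  }
  if (all(is.na(du))) {
    du[] <- 0; dv[] <- 0
  } else {
    du <- fill_and_smooth(du, conf); dv <- fill_and_smooth(dv, conf)
  }
  du <- pmin(pmax(du, -max_displacement_px), max_displacement_px)
  dv <- pmin(pmax(dv, -max_displacement_px), max_displacement_px)

  grid <- list(nodes_x = c(1, nodes_c, d[2]), nodes_y = c(1, nodes_r, d[1]),
               du = pad_edges(du), dv = pad_edges(dv))
  dense <- eval_elastic(grid,
                        x_px = rep(seq_len(d[2]), each = d[1]),
                        y_px = rep(seq_len(d[1]), times = d[2]))
  structure(list(
    u = matrix(dense$u, d[1], d[2]),
    v = matrix(dense$v, d[1], d[2]),
    grid = grid, grid_spacing_px = grid_spacing_px
  ), class = "displacement_field")
}

# Cross-correlate one block pair (zero-padded FFT), restrict the peak to
# |shift| <= search, refine sub-pixel. Returns c(dx, dy, peak) or NULL.
block_shift <- function(ref_block, mov_block, pad, search_px) {
  w <- dim(ref_block)
  a <- matrix(0, pad, pad); b <- matrix(0, pad, pad)
  a[seq_len(w[1]), seq_len(w[2])] <- (ref_block - mean(ref_block)) / stats::sd(ref_block)
  b[seq_len(w[1]), seq_len(w[2])] <- (mov_block - mean(mov_block)) / stats::sd(mov_block)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  sh <- c(0:(pad / 2), (-pad / 2 + 1):(-1))
  ok_r <- abs(sh) <= search_px
  sub <- cc[ok_r, ok_r, drop = FALSE]
  peak <- arrayInd(which.max(sub), dim(sub))
  shifts <- sh[ok_r]
  at <- function(dr, dc) {
    r <- ((which(sh == shifts[peak[1]]) - 1 + dr) %% pad) + 1
    c <- ((which(sh == shifts[peak[2]]) - 1 + dc) %% pad) + 1
    cc[r, c]
  }
  sub_refine <- function(cm, c0, cp) {
    denom <- cm - 2 * c0 + cp
    if (denom == 0) 0 else max(min(0.5 * (cm - cp) / denom, 0.5), -0.5)
  }
  dy <- shifts[peak[1]] + sub_refine(at(-1, 0), at(0, 0), at(1, 0))
  dx <- shifts[peak[2]] + sub_refine(at(0, -1), at(0, 0), at(0, 1))
  c(dx = dx, dy = dy, peak = max(sub) / length(ref_block))
}

# Replace NA nodes by the confidence-weighted mean of all estimated nodes,
# then smooth with a 3x3 kernel.
fill_and_smooth <- function(g, conf) {
  fallback <- sum(g * conf, na.rm = TRUE) / sum(conf[!is.na(g)])
  g[is.na(g)] <- fallback
  k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
  gp <- rbind(g[1, , drop = FALSE], g, g[nrow(g), , drop = FALSE])
  gp <- cbind(gp[, 1, drop = FALSE], gp, gp[, ncol(gp), drop = FALSE])
  out <- g
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      out[i, j] <- sum(gp[i:(i + 2), j:(j + 2)] * k)
    }
  }
  out
}

# Extend the node matrix by replicating edges so the grid covers the image.
pad_edges <- function(g) {
  g <- rbind(g[1, , drop = FALSE], g, g[nrow(g), , drop = FALSE])
  cbind(g[, 1, drop = FALSE], g, g[, ncol(g), drop = FALSE])
}

#' Resample an image through a rigid + elastic transform
#'
#' Bilinear interpolation at source coordinates
#' `(r + dy + v, c + dx + u)`; out-of-field samples are 0. Integer-offset
#' transforms reproduce source pixels exactly.
#'
#' @param img Numeric matrix.
#' @param rigid A `rigid_transform` (or NULL for identity).
#' @param field A `displacement_field` (or NULL for none).
#' @return The aligned matrix.
#' @export
warp_image <- function(img, rigid = NULL, field = NULL) {
  d <- dim(img)
  dx <- if (is.null(rigid)) 0 else rigid$dx
  dy <- if (is.null(rigid)) 0 else rigid$dy
  u <- if (is.null(field)) 0 else field$u
  v <- if (is.null(field)) 0 else field$v
  if (!is.null(field)) stopifnot(all(dim(field$u) == d))
  rq <- matrix(seq_len(d[1]), d[1], d[2]) + dy + v
  cq <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]) + dx + u
  bilinear_sample(img, rq, cq)
}

bilinear_sample <- function(img, rq, cq) {
  d <- dim(img)
  r0 <- floor(rq); c0 <- floor(cq)
  fr <- rq - r0; fc <- cq - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- (1 - frv) * (1 - fcv) * val(r0v, c0v) +
         (1 - frv) * fcv       * val(r0v, c0v + 1) +
         frv       * (1 - fcv) * val(r0v + 1, c0v) +
         frv       * fcv       * val(r0v + 1, c0v + 1)
  matrix(out, d[1], d[2])
}

#' Align every channel of a round into the reference frame
#'
#' Applies the round's DAPI-estimated transforms identically to all channels
#' (DAPI and probes); probe channels never drive their own registration.
#'
#' @param stack A round stack (list with `dapi` and `probes`).
#' @param rigid A `rigid_transform`.
#' @param field A `displacement_field` (optional).
#' @return The stack with all channels resampled.
#' @export
apply_transforms <- function(stack, rigid, field = NULL) {
  stopifnot(is.list(stack), !is.null(stack$dapi))
  if (!is.null(field) && !all(dim(field$u) == dim(stack$dapi))) {
    stop("displacement field shape does not match the image")
  }
  stack$dapi <- warp_image(stack$dapi, rigid, field)
  stack$probes <- lapply(stack$probes, warp_image, rigid = rigid, field = field)
  stack
}

#' Register all rounds of a rendered dataset to round 1
#'
#' Round 1 is the reference; each later round is rigidly registered from its
#' DAPI, the residual elastic field is estimated from the rigidly aligned
#' DAPI, and both transforms are applied to every channel of the round.
#'
#' @param rendered Output of [render_rounds()].
#' @param grid_spacing_px,search_px Elastic block-matching parameters.
#' @return `rendered` with aligned rounds and an added `transforms` element
#'   (per round: `rigid`, `field`).
#' @export
register_rounds <- function(rendered, grid_spacing_px = 64, search_px = 16) {
  ref <- rendered$rounds[[1]]$dapi
  transforms <- vector("list", length(rendered$rounds))
  transforms[[1]] <- list(rigid = structure(list(dx = 0, dy = 0),
                                            class = "rigid_transform"),
                          field = NULL)
  for (k in seq_along(rendered$rounds)[-1]) {
    stack <- rendered$rounds[[k]]
    rigid <- estimate_rigid(ref, stack$dapi)
    aligned_dapi <- warp_image(stack$dapi, rigid)
    field <- estimate_elastic(ref, aligned_dapi,
                              grid_spacing_px = grid_spacing_px,
                              search_px = search_px)
    rendered$rounds[[k]] <- apply_transforms(stack, rigid, field)
    transforms[[k]] <- list(rigid = rigid, field = field)
  }
  rendered$transforms <- transforms
  rendered
}
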