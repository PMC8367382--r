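# Synthetic image rendering: turns a ground_truth object into per-round
# image stacks (DAPI + 4 probe channels) plus a pre-round RSC/LEC label pair.
# Images are matrices indexed [row = y, col = x]; the point (x, y) in pixel
# units falls in img[floor(y) + 1, floor(x) + 1].

#' Render multi-round mFISH images from ground truth
#'
#' Round 1 is rendered in the reference frame; later rounds are rendered
#' with their stored rigid drift and elastic warp applied to every cell and
#' spot position (forward warping, so registration must undo it). DAPI
#' renders every nucleus in every round. Each probe channel renders a
#' Poisson number of diffraction-limited spots per cell, with mean
#' `density x somatic area / 100`, uniformly placed within the somatic
#' footprint (nucleus dilated by `soma_expand_um`). The retrograde label
#' channels fill the somata of flagged cells and are acquired before round 1
#' in the reference frame.
#'
#' @param gt A `ground_truth` object.
#' @param optics An `optics_model`.
#' @param seed Integer seed for spot placement and noise.
#' @param soma_expand_um Somatic footprint = nucleus radius + this (default 5).
#' @param label_expand_um Radius increment for the retrograde-label fill
#'   (default 2.5). The tracer fill is kept perinuclear - tighter than the
#'   probe footprint - so that a planted label never spills past the
#'   Voronoi boundary into a neighbouring cell's ROI.
#' @return A list with elements `rounds` (list of round stacks, each with
#'   `round`, `dapi`, and `probes`, a named list of gene-channel matrices),
#'   `labels` (list with `RSC` and `LEC` matrices), `panel`, and `optics`.
#' @export
render_rounds <- function(gt, optics = optics_model(), seed = 1,
                          soma_expand_um = 5, label_expand_um = 2.5) {
  stopifnot(inherits(gt, "ground_truth"), inherits(optics, "optics_model"))
  px <- optics$pixel_size_um
  dim_px <- c(round(gt$field_size_um[2] / px), round(gt$field_size_um[1] / px))
  cells <- gt$cells
  soma_r_um <- cells$nucleus_radius_um + soma_expand_um
  soma_area_um2 <- pi * soma_r_um^2

  with_seed(seed, {
    rounds <- lapply(gt$transforms, function(tr) {
      # forward-transform a set of reference positions (in px) into round k
      fwd <- function(x_px, y_px) {
        e <- eval_elastic(tr$elastic, x_px, y_px)
        list(x = x_px + tr$dx + e$u, y = y_px + tr$dy + e$v)
      }
      dapi <- matrix(0, dim_px[1], dim_px[2])
      if (nrow(cells) > 0) {
        p <- fwd(cells$x_um / px, cells$y_um / px)
        for (i in seq_len(nrow(cells))) {
          dapi <- fill_disc(dapi, p$x[i], p$y[i],
                            cells$nucleus_radius_um[i] / px,
                            optics$dapi_amplitude)
        }
      }
      dapi <- add_noise(blur(dapi, optics$psf_sigma_px), optics)

      panel_k <- gt$panel[gt$panel$round == tr$round, , drop = FALSE]
      probes <- lapply(seq_len(nrow(panel_k)), function(j) {
        gene <- panel_k$gene[j]
        field <- matrix(0, dim_px[1], dim_px[2])
        if (nrow(cells) > 0) {
          dens <- vapply(cells$phenotype,
                         function(ph) gt$phenotypes[[ph]]$expression[[gene]],
                         numeric(1))
          lambda <- dens * soma_area_um2 / 100
          n_spots <- stats::rpois(nrow(cells), lambda)
          tot <- sum(n_spots)
          if (tot > 0) {
            idx <- rep(seq_len(nrow(cells)), n_spots)
            rr <- (soma_r_um[idx] / px) * sqrt(stats::runif(tot))
            th <- stats::runif(tot, 0, 2 * pi)
            sx <- cells$x_um[idx] / px + rr * cos(th)
            sy <- cells$y_um[idx] / px + rr * sin(th)
            sp <- fwd(sx, sy)
            field <- accumulate_points(field, sp$x, sp$y)
          }
        }
        sig <- blur(field, optics$psf_sigma_px) * optics$spot_amplitude
        add_noise(sig, optics)
      })
      names(probes) <- panel_k$gene
      list(round = tr$round, dapi = dapi, probes = probes)
    })

    labels <- lapply(c(RSC = "rsc", LEC = "lec"), function(flag) {
      img <- matrix(0, dim_px[1], dim_px[2])
      sel <- which(cells[[flag]])
      for (i in sel) {
        img <- fill_disc(img, cells$x_um[i] / px, cells$y_um[i] / px,
                         (cells$nucleus_radius_um[i] + label_expand_um) / px,
                         optics$label_amplitude)
      }
      add_noise(blur(img, optics$psf_sigma_px), optics)
    })

    list(rounds = rounds, labels = labels, panel = gt$panel, optics = optics)
  })
}

# Fill a disc with `value` (overlaps take the max, not the sum).
fill_disc <- function(img, cx, cy, r_px, value) {
  r0 <- max(1L, floor(cy - r_px) + 1L); r1 <- min(nrow(img), ceiling(cy + r_px) + 1L)
  c0 <- max(1L, floor(cx - r_px) + 1L); c1 <- min(ncol(img), ceiling(cx + r_px) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  yy <- rows - 0.5; xx <- cols - 0.5
  mask <- outer(yy, xx, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_px^2)
  patch <- img[rows, cols, drop = FALSE]
  patch[mask] <- pmax(patch[mask], value)
  img[rows, cols] <- patch
  img
}

# Deposit unit counts at the nearest pixel of each point (duplicates add).
accumulate_points <- function(img, x_px, y_px) {
  r <- floor(y_px) + 1L; c <- floor(x_px) + 1L
  keep <- r >= 1L & r <= nrow(img) & c >= 1L & c <= ncol(img)
  if (!any(keep)) return(img)
  lin <- (c[keep] - 1L) * nrow(img) + r[keep]
  img + matrix(tabulate(lin, nbins = length(img)), nrow(img), ncol(img))
}

blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (sigma > 2) return(as.matrix(EBImage::gblur(img, sigma = sigma)))
  # separable shift-and-add convolution; much faster than an FFT filter for
  # the small PSF widths used here
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along_rows) nrow(m) else ncol(m)
    for (i in -r:r) {
      src <- max(1, 1 - i):min(n, n - i)
      dst <- src + i
      if (along_rows) {
        out[dst, ] <- out[dst, ] + k[i + r + 1] * m[src, ]
      } else {
        out[, dst] <- out[, dst] + k[i + r + 1] * m[, src]
      }
    }
    out
  }
  conv1(conv1(img, TRUE), FALSE)
}

add_noise <- function(signal, optics) {
  lambda <- signal + optics$background_level
  img <- if (optics$shot_noise) {
    out <- stats::rpois(length(lambda), lambda)
    if (optics$read_noise_sd > 0) {
      out <- out + stats::rnorm(length(lambda), 0, optics$read_noise_sd)
    }
    matrix(out, nrow(lambda), ncol(lambda))
  } else {
    lambda
  }
  top <- 2^optics$bit_depth - 1
  matrix(pmin(pmax(round(img), 0), top), nrow(lambda), ncol(lambda))
}
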