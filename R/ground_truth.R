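#' Generate a ground-truth synthetic claustrum field
#'
#' Places cells in a core-disc / shell-annulus / deep-L6-ring / cortex
#' arrangement centred on the field, assigns phenotypes by exact
#' largest-remainder apportionment of the phenotype proportions, draws
#' RSC/LEC retrograde-label flags independently per channel from each
#' phenotype's label affinities, and draws per-round acquisition transforms
#' (rigid drift plus a smooth elastic displacement field on a coarse control
#' grid). Round 1 is the reference frame and carries identity transforms.
#'
#' Cell centroids are kept at least two nucleus radii apart by rejection
#' sampling; placement failure names the achievable density.
#'
#' @param field_size_um Field width/height in microns, length-2.
#' @param n_cells Total number of cells.
#' @param phenotypes List of phenotype models (see [default_phenotypes()]).
#' @param geometry List with `core_radius_um`, `shell_outer_um`,
#'   `deep_outer_um` (zone boundaries; must fit inside the field).
#' @param nucleus_radius_um Nucleus radius (all cells; default 4 um).
#' @param n_rounds Number of imaging rounds (default 3).
#' @param rigid_max_px Per-round rigid drift is drawn uniformly in
#'   `[-rigid_max_px, rigid_max_px]` per axis (sub-pixel values).
#' @param elastic_amp_px Maximum elastic control-point displacement (px).
#' @param elastic_grid Control-grid side (default 4, i.e. 4 x 4 points).
#' @param pixel_size_um Pixel size used to express transforms in pixels.
#' @param animal_id,section_id Identifiers carried into downstream tables.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `ground_truth`.
#' @export
generate_ground_truth <- function(field_size_um = c(500, 500), n_cells = 300,
                                  phenotypes = default_phenotypes(),
                                  geometry = list(core_radius_um = 100,
                                                  shell_outer_um = 160,
                                                  deep_outer_um = 200),
                                  nucleus_radius_um = 4, n_rounds = 3,
                                  rigid_max_px = 8, elastic_amp_px = 3,
                                  elastic_grid = 4, pixel_size_um = 0.5,
                                  animal_id = "A1", section_id = "S1",
                                  seed = 1) {
  validate_phenotypes(phenotypes)
  stopifnot(length(field_size_um) == 2, all(field_size_um > 0), n_cells >= 0)
  half <- min(field_size_um) / 2
  if (!(geometry$core_radius_um < geometry$shell_outer_um &&
        geometry$shell_outer_um < geometry$deep_outer_um &&
        geometry$deep_outer_um <= half)) {
    stop("zone radii must be increasing and fit inside the field")
  }

  with_seed(seed, {
    props <- vapply(phenotypes, `[[`, numeric(1), "proportion")
    n_per <- apportion(n_cells, props)
    names(n_per) <- names(phenotypes)

    cx <- field_size_um[1] / 2
    cy <- field_size_um[2] / 2
    min_d <- 2 * nucleus_radius_um
    zone_of <- c(core = "core", shell = "shell", deep_L6 = "deep",
                 cortex_a = "cortex", cortex_b = "cortex")

    sample_in_zone <- function(zone) {
      repeat {
        x <- stats::runif(1, nucleus_radius_um, field_size_um[1] - nucleus_radius_um)
        y <- stats::runif(1, nucleus_radius_um, field_size_um[2] - nucleus_radius_um)
        r <- sqrt((x - cx)^2 + (y - cy)^2)
        ok <- switch(zone,
          core = r < geometry$core_radius_um,
          shell = r >= geometry$core_radius_um & r < geometry$shell_outer_um,
          deep = r >= geometry$shell_outer_um & r < geometry$deep_outer_um,
          cortex = r >= geometry$deep_outer_um
        )
        if (ok) return(c(x, y))
      }
    }

    xs <- numeric(0); ys <- numeric(0); phen <- character(0)
    budget <- max(10L * n_cells, 10L)
    attempts <- 0L
    for (ph in names(phenotypes)) {
      zone <- zone_of[[ph]]
      placed <- 0L
      while (placed < n_per[[ph]]) {
        if (attempts >= budget) {
          stop(sprintf(
            "cell placement failed after %d attempts; achieved density %.4f cells/um^2 (%d of %d cells) - reduce n_cells or enlarge the field",
            attempts, length(xs) / prod(field_size_um), length(xs), n_cells))
        }
        attempts <- attempts + 1L
        p <- sample_in_zone(zone)
        if (length(xs) == 0 || min((xs - p[1])^2 + (ys - p[2])^2) >= min_d^2) {
          xs <- c(xs, p[1]); ys <- c(ys, p[2]); phen <- c(phen, ph)
          placed <- placed + 1L
        }
      }
    }

    n <- length(xs)
    aff <- t(vapply(phen, function(ph) phenotypes[[ph]]$label_affinity,
                    numeric(2)))
    rsc <- if (n > 0) stats::runif(n) < aff[, "RSC"] else logical(0)
    lec <- if (n > 0) stats::runif(n) < aff[, "LEC"] else logical(0)

    cells <- data.frame(
      cell_id = seq_len(n),
      x_um = xs, y_um = ys,
      nucleus_radius_um = rep(nucleus_radius_um, n),
      phenotype = phen,
      rsc = rsc, lec = lec,
      stringsAsFactors = FALSE
    )
    rownames(cells) <- NULL

    field_px <- round(field_size_um / pixel_size_um)
    transforms <- lapply(seq_len(n_rounds), function(k) {
      if (k == 1) {
        list(round = 1L, dx = 0, dy = 0,
             elastic = zero_elastic(field_px, elastic_grid))
      } else {
        el <- random_elastic(field_px, elastic_grid, elastic_amp_px)
        list(round = as.integer(k),
             dx = stats::runif(1, -rigid_max_px, rigid_max_px),
             dy = stats::runif(1, -rigid_max_px, rigid_max_px),
             elastic = el)
      }
    })

    structure(list(
      cells = cells,
      transforms = transforms,
      panel = default_panel(),
      phenotypes = phenotypes,
      field_size_um = field_size_um,
      field_px = field_px,
      geometry = geometry,
      pixel_size_um = pixel_size_um,
      animal_id = animal_id, section_id = section_id,
      seed = as.integer(seed)
    ), class = "ground_truth")
  })
}

# Elastic ground-truth warp: a coarse grid of random control-point
# displacements, bilinearly interpolated to any (x, y) in pixels.
random_elastic <- function(field_px, grid_n, amp_px) {
  du <- matrix(stats::rnorm(grid_n^2, 0, amp_px / 2), grid_n, grid_n)
  dv <- matrix(stats::rnorm(grid_n^2, 0, amp_px / 2), grid_n, grid_n)
  du <- pmin(pmax(du, -amp_px), amp_px)
  dv <- pmin(pmax(dv, -amp_px), amp_px)
  list(nodes_x = seq(0, field_px[1], length.out = grid_n),
       nodes_y = seq(0, field_px[2], length.out = grid_n),
       du = du, dv = dv, amp_px = amp_px)
}

zero_elastic <- function(field_px, grid_n) {
  list(nodes_x = seq(0, field_px[1], length.out = grid_n),
       nodes_y = seq(0, field_px[2], length.out = grid_n),
       du = matrix(0, grid_n, grid_n), dv = matrix(0, grid_n, grid_n),
       amp_px = 0)
}

# Evaluate an elastic control grid at arbitrary pixel coordinates.
# Returns a list(u, v) of displacements in px. Grid rows index y, cols x.
eval_elastic <- function(elastic, x_px, y_px) {
  interp_grid <- function(g) {
    nx <- elastic$nodes_x; ny <- elastic$nodes_y
    xi <- findInterval(x_px, nx, rightmost.closed = TRUE)
    yi <- findInterval(y_px, ny, rightmost.closed = TRUE)
    xi <- pmin(pmax(xi, 1L), length(nx) - 1L)
    yi <- pmin(pmax(yi, 1L), length(ny) - 1L)
    tx <- (x_px - nx[xi]) / (nx[xi + 1L] - nx[xi])
    ty <- (y_px - ny[yi]) / (ny[yi + 1L] - ny[yi])
    tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
    g00 <- g[cbind(yi, xi)];      g01 <- g[cbind(yi, xi + 1L)]
    g10 <- g[cbind(yi + 1L, xi)]; g11 <- g[cbind(yi + 1L, xi + 1L)]
    (1 - ty) * ((1 - tx) * g00 + tx * g01) + ty * ((1 - tx) * g10 + tx * g11)
  }
  list(u = interp_grid(elastic$du), v = interp_grid(elastic$dv))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells, %g x %g um field, %d rounds, seed %d\n",
              nrow(x$cells), x$field_size_um[1], x$field_size_um[2],
              length(x$transforms), x$seed))
  if (nrow(x$cells) > 0) print(table(x$cells$phenotype))
  invisible(x)
}
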