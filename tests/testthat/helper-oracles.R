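# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately brute-force and never call the code paths they
# check.

# Exhaustive integer-shift normalized cross-correlation: returns the (dx,
# dy) maximizing NCC over the overlap region. O(shifts * pixels); use on
# small images only.
ncc_shift_oracle <- function(ref, mov, max_shift = 10) {
  best <- c(dx = 0, dy = 0); best_v <- -Inf
  n <- dim(ref)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      # mov(r, c) ~ ref(r - dy, c - dx): overlap indices
      r_m <- max(1, 1 + dy):min(n[1], n[1] + dy)
      c_m <- max(1, 1 + dx):min(n[2], n[2] + dx)
      a <- ref[r_m - dy, c_m - dx, drop = FALSE]
      b <- mov[r_m, c_m, drop = FALSE]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      v <- stats::cor(as.vector(a), as.vector(b))
      if (v > best_v) { best_v <- v; best <- c(dx = dx, dy = dy) }
    }
  }
  best
}

# Brute-force per-label positive-pixel PAC.
pac_oracle <- function(binary, labels) {
  ids <- sort(unique(labels[labels > 0]))
  vapply(ids, function(i) {
    px <- labels == i
    100 * sum(binary[px]) / sum(px)
  }, numeric(1))
}

# Brute-force nearest-centroid label assignment within a radius of any
# centroid (oracle for ROI expansion geometry with equal-size nuclei).
nearest_centroid_oracle <- function(dim_px, centroids, max_dist_px) {
  out <- matrix(0L, dim_px[1], dim_px[2])
  for (r in seq_len(dim_px[1])) {
    for (c in seq_len(dim_px[2])) {
      d <- sqrt((c - 0.5 - centroids[, 1])^2 + (r - 0.5 - centroids[, 2])^2)
      i <- which.min(d)
      if (d[i] <= max_dist_px) out[r, c] <- i
    }
  }
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of rank
# assignments (no ties assumed).
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Match detected centroids to planted ones greedily by distance; returns
# indices of planted cells (NA where unmatched beyond max_dist).
match_centroids <- function(found_x, found_y, true_x, true_y, max_dist) {
  d <- sqrt(outer(found_x, true_x, "-")^2 + outer(found_y, true_y, "-")^2)
  idx <- apply(d, 1, which.min)
  ok <- d[cbind(seq_along(idx), idx)] <= max_dist
  idx[!ok] <- NA
  idx
}

# Independent largest-remainder apportionment (checks the generator's
# planted composition).
apportion_ref <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Small, fast ground truth: 200 um field, 60 cells, scaled-down zone radii.
tiny_gt <- function(n_cells = 60, seed = 1, ...) {
  generate_ground_truth(
    field_size_um = c(200, 200), n_cells = n_cells,
    geometry = list(core_radius_um = 40, shell_outer_um = 64,
                    deep_outer_um = 80),
    seed = seed, ...)
}

quiet_optics <- function(...) optics_model(shot_noise = FALSE,
                                           background_level = 0,
                                           read_noise_sd = 0, ...)

# Fast small-field pipeline config for orchestration tests.
tiny_config <- function(seed = 11) {
  validate_config(list(
    seed = seed, n_cells = 80L, field_um = c(250, 250),
    geometry = list(core_radius_um = 50, shell_outer_um = 80,
                    deep_outer_um = 100),
    registration = list(grid_spacing_px = 48, search_px = 12)))
}
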