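# Histogram-tail thresholding, PAC arithmetic, gating and normalization.

test_that("tail threshold matches the sort-based quantile definition", {
  img <- matrix(0, 25, 40)           # 1000 px
  img[1:5] <- 10
  t <- compute_threshold(img, 0.005)
  expect_equal(sum(img > t), 5)      # exactly the 5 bright pixels
  expect_equal(t, 0)

  # fraction 0.5: positives can never exceed half the pixels
  set.seed(2)
  any_img <- matrix(stats::rpois(1000, 30), 25, 40)
  t2 <- compute_threshold(any_img, 0.5)
  expect_lte(sum(any_img > t2), 500)

  # the smallest-t property: one step lower admits too many positives
  vals <- sort(unique(as.vector(any_img)))
  below <- max(vals[vals < t2])
  expect_gt(sum(any_img > below), 500)

  expect_warning(t3 <- compute_threshold(matrix(0, 10, 10), 0.005), "constant")
  expect_equal(t3, 0)
  expect_equal(sum(matrix(0, 10, 10) > t3), 0)
})

test_that("positive-pixel count is monotone in the tail fraction", {
  set.seed(3)
  img <- matrix(stats::rpois(5000, 50) + stats::rbinom(5000, 1, 0.01) * 500, 50, 100)
  fractions <- c(0.01, 0.008, 0.005, 0.002)
  counts <- vapply(fractions, function(f) sum(img > compute_threshold(img, f)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("thresholding is invariant to monotone intensity rescaling", {
  set.seed(4)
  img <- matrix(stats::rpois(4000, 20), 50, 80)
  pos1 <- img > compute_threshold(img, 0.005)
  rescaled <- sqrt(img) * 7 + 3
  pos2 <- rescaled > compute_threshold(rescaled, 0.005)
  expect_identical(pos1, pos2)
})

test_that("PAC equals 100 x positive pixels over ROI area, matching the brute-force oracle", {
  labels <- matrix(0L, 20, 20)
  labels[1:10, 1:10] <- 1L           # 100 px ROI
  labels[11:20, 11:20] <- 2L
  rois <- label_mask(labels, 0.5)
  binary <- matrix(FALSE, 20, 20)
  binary[1:7, 1] <- TRUE             # 7 positives in ROI 1
  pac <- compute_pac(binary, rois)
  expect_equal(unname(pac), c(7, 0))
  expect_equal(unname(pac), unname(pac_oracle(binary, labels)))

  # saturation and the all-positive case
  full <- matrix(TRUE, 20, 20)
  expect_equal(unname(compute_pac(full, rois)), c(100, 100))
  none <- matrix(FALSE, 20, 20)
  expect_equal(unname(compute_pac(none, rois)), c(0, 0))

  # random masks agree with the oracle exactly
  set.seed(5)
  for (i in 1:5) {
    b <- matrix(stats::runif(400) < 0.3, 20, 20)
    expect_equal(unname(compute_pac(b, rois)), unname(pac_oracle(b, labels)))
  }
})

make_pac <- function(mat, genes = colnames(mat)) {
  structure(list(
    pac = mat,
    cells = data.frame(label = seq_len(nrow(mat)),
                       x_um = 0, y_um = 0, animal = "A1", section = "S1"),
    genes = data.frame(gene = genes, round = 1L, channel = seq_along(genes)),
    normalized = FALSE), class = "pac_matrix")
}

test_that("excitatory gating retains at the one-PAC boundary and drops the gate gene", {
  m <- rbind(c(0, 5), c(1, 2), c(0.99, 3), c(2, 0))
  colnames(m) <- c("Slc17a7", "Synpr")
  rownames(m) <- 1:4
  pac <- make_pac(m)
  g <- gate_excitatory(pac)
  expect_equal(g$gate$retained, 2)   # PAC exactly 1.0 is retained (>=)
  expect_equal(rownames(g$pac), c("2", "4"))
  expect_false("Slc17a7" %in% colnames(g$pac))
  expect_false("Slc17a7" %in% g$genes$gene)

  zero <- make_pac(matrix(0, 3, 2, dimnames = list(1:3, c("Slc17a7", "Synpr"))))
  gz <- gate_excitatory(zero)
  expect_equal(gz$gate$retained, 0)

  expect_error(gate_excitatory(make_pac(m[, 2, drop = FALSE])), "gate gene")
})

test_that("within-cell normalization is L1 and guards against double application", {
  m <- rbind(c(2, 2, 0, 0), c(0, 0, 0, 0), c(1, 3, 4, 2))
  colnames(m) <- paste0("g", 1:4); rownames(m) <- 1:3
  pac <- make_pac(m)
  norm <- normalize_within_cell(pac)
  expect_equal(norm$pac[1, ], c(g1 = 0.5, g2 = 0.5, g3 = 0, g4 = 0))
  expect_equal(unname(norm$pac[2, ]), rep(0, 4))
  expect_true(norm$cells$all_zero[2])
  rs <- rowSums(norm$pac)[c(1, 3)]
  expect_equal(unname(rs), c(1, 1), tolerance = 1e-9)
  expect_error(normalize_within_cell(norm), "already normalized")
})

test_that("PAC rank-orders cells by planted expression density on clean images", {
  gt <- generate_ground_truth(seed = 21, rigid_max_px = 0, elastic_amp_px = 0)
  rend <- render_rounds(gt, quiet_optics(), seed = 21)
  nuc <- segment_nuclei(rend$rounds[[1]]$dapi, 0.5)
  rois <- expand_rois(nuc, 5)
  pac <- build_pac_matrix(rend, rois)
  cen <- mask_centroids(rois)
  idx <- match_centroids(cen$x_um, cen$y_um, gt$cells$x_um, gt$cells$y_um,
                         max_dist = 3)
  dens_of <- function(g) vapply(gt$cells$phenotype[idx],
                                function(ph) gt$phenotypes[[ph]]$expression[[g]],
                                numeric(1))
  # per-cell rank fidelity for the core/shell markers, whose planted
  # contrasts span the resolvable range
  for (g in c("Synpr", "Nnat")) {
    expect_gt(stats::cor(pac$pac[, g], dens_of(g), method = "spearman"), 0.9)
  }
  # for every probe, phenotype-level mean PAC preserves the planted density
  # ordering among phenotypes above the one-spot-per-100um2 floor
  for (g in setdiff(colnames(pac$pac), "Slc17a6")) {
    dens <- dens_of(g)
    lvl <- tapply(pac$pac[, g], dens, mean)
    lvl <- lvl[as.numeric(names(lvl)) >= 1]
    if (length(lvl) > 1) {
      expect_true(all(diff(lvl[order(as.numeric(names(lvl)))]) > 0),
                  info = g)
    }
  }
})

test_that("per-gene tail fractions outside the stated band warn", {
  gt <- tiny_gt(n_cells = 20, seed = 22)
  rend <- render_rounds(gt, optics_model(), seed = 22)
  nuc <- segment_nuclei(rend$rounds[[1]]$dapi, 0.5)
  rois <- expand_rois(nuc, 5)
  tf <- default_tail_fractions()
  tf["Synpr"] <- 0.05
  expect_warning(build_pac_matrix(rend, rois, tail_fraction = tf), "Synpr")
})
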