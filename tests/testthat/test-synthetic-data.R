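# Ground-truth generator, image renderer and count-matrix simulator.

test_that("ground truth generation is deterministic and handles the empty case", {
  a <- tiny_gt(seed = 42)
  b <- tiny_gt(seed = 42)
  expect_identical(a, b)
  d <- tiny_gt(seed = 43)
  expect_false(identical(a$cells, d$cells))

  empty <- tiny_gt(n_cells = 0, seed = 1)
  expect_equal(nrow(empty$cells), 0)
  expect_length(empty$transforms, 3)
  expect_true(all(is.finite(unlist(lapply(empty$transforms, `[[`, "dx")))))
})

test_that("phenotype zones are spatially nested and centroids respect spacing", {
  for (seed in 1:4) {
    gt <- tiny_gt(n_cells = 80, seed = seed)
    cells <- gt$cells
    r <- sqrt((cells$x_um - 100)^2 + (cells$y_um - 100)^2)
    med <- tapply(r, cells$phenotype, stats::median)
    expect_lt(med[["core"]], med[["shell"]])
    expect_lt(med[["shell"]], min(med[c("deep_L6", "cortex_a", "cortex_b")]))
    d <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
    diag(d) <- Inf
    expect_gte(min(d), 2 * cells$nucleus_radius_um[1] - 1e-9)
  }
})

test_that("placement failure names the achievable density", {
  expect_error(
    generate_ground_truth(field_size_um = c(40, 40), n_cells = 200,
                          geometry = list(core_radius_um = 8,
                                          shell_outer_um = 13,
                                          deep_outer_um = 18),
                          seed = 1),
    "density")
})

test_that("projection flags match affinity-implied expectations", {
  # expectation derived by direct enumeration over the affinity matrix and
  # phenotype proportions: P(core | RSC) = p_core a_core / sum_ph p_ph a_ph
  models <- default_phenotypes()
  p <- vapply(models, `[[`, numeric(1), "proportion")
  a_rsc <- vapply(models, function(m) m$label_affinity[["RSC"]], numeric(1))
  a_lec <- vapply(models, function(m) m$label_affinity[["LEC"]], numeric(1))
  exp_core_given_rsc <- p[["core"]] * a_rsc[["core"]] / sum(p * a_rsc)
  expect_gt(exp_core_given_rsc, 0.80)
  expect_lt(exp_core_given_rsc, 0.90)

  gt <- generate_ground_truth(n_cells = 600, seed = 7)
  frac <- sum(gt$cells$rsc & gt$cells$phenotype == "core") / sum(gt$cells$rsc)
  expect_lt(abs(frac - 0.85), 0.05)

  # realized marginals within 3 binomial SE of the affinity expectations
  n <- nrow(gt$cells)
  p_rsc <- sum(p * a_rsc); p_lec <- sum(p * a_lec)
  p_dual <- sum(p * a_rsc * a_lec)
  for (pair in list(list(sum(gt$cells$rsc), p_rsc),
                    list(sum(gt$cells$lec), p_lec),
                    list(sum(gt$cells$rsc & gt$cells$lec), p_dual))) {
    se <- sqrt(n * pair[[2]] * (1 - pair[[2]]))
    expect_lt(abs(pair[[1]] - n * pair[[2]]), 3 * se + 1e-9)
  }
})

test_that("rendered DAPI conserves all planted cells and probe channels carry signal", {
  gt <- tiny_gt(n_cells = 40, seed = 5, rigid_max_px = 4)
  rend <- render_rounds(gt, quiet_optics(), seed = 5)
  expect_length(rend$rounds, 3)
  for (st in rend$rounds) {
    nuc <- segment_nuclei(st$dapi, pixel_size_um = 0.5)
    expect_equal(max(nuc$labels), nrow(gt$cells))
    expect_length(st$probes, 4)
  }
})

test_that("zero expression renders pure background and identity transforms identical DAPI", {
  gt <- tiny_gt(n_cells = 20, seed = 2, rigid_max_px = 0, elastic_amp_px = 0)
  models0 <- lapply(gt$phenotypes, function(m) { m$expression[] <- 0; m })
  gt0 <- gt
  gt0$phenotypes <- models0
  opt <- optics_model(background_level = 100, read_noise_sd = 0)
  rend <- render_rounds(gt0, opt, seed = 3)
  for (st in rend$rounds) {
    for (img in st$probes) {
      se <- sqrt(100 / length(img))
      expect_lt(abs(mean(img) - 100), 3 * se)
    }
  }
  # identity transforms: per-pixel DAPI differences are noise-scale only
  rendq <- render_rounds(gt0, quiet_optics(), seed = 3)
  expect_equal(rendq$rounds[[1]]$dapi, rendq$rounds[[2]]$dapi)
})

test_that("a planted rigid shift is visible to an exhaustive correlation oracle", {
  gt <- tiny_gt(n_cells = 30, seed = 9, elastic_amp_px = 0)
  gt$transforms[[2]]$dx <- 3
  gt$transforms[[2]]$dy <- -2
  rend <- render_rounds(gt, optics_model(), seed = 9)
  sh <- ncc_shift_oracle(rend$rounds[[1]]$dapi, rend$rounds[[2]]$dapi,
                         max_shift = 5)
  expect_equal(unname(sh), c(3, -2))
})

test_that("count matrix has planted composition, is deterministic, and respects proportions", {
  sim1 <- generate_count_matrix(n_cells = 400, seed = 3)
  sim2 <- generate_count_matrix(n_cells = 400, seed = 3)
  expect_identical(sim1, sim2)
  expect_equal(ncol(sim1$counts), 400)
  expect_equal(nrow(sim1$truth), 400)

  # exact apportionment of the planted composition
  planted <- table(sim1$truth$class)
  expected <- apportion_ref(400, default_count_proportions())
  expect_equal(as.integer(planted[names(expected)]), unname(expected))

  # no contaminants -> QC retains every cell
  clean <- generate_count_matrix(
    n_cells = 100,
    proportions = c(synpr_high = 0.4, nnat_high = 0.4, cortical = 0.2),
    seed = 1)
  ledger <- qc_filter(compute_cpm(clean$counts))
  expect_equal(ledger$n_retained, 100)

  expect_error(generate_count_matrix(100, proportions = c(synpr_high = 0.7)),
               "sum to 1")
})
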