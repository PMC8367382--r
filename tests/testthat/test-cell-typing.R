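# UMAP embedding, Leiden clustering, phenotype assignment and Mann-Whitney
# differential expression.

# feature-space fixture: k well-separated Gaussian blobs over n genes,
# wrapped as a normalized pac_matrix
blob_pac <- function(n_per, centers, sd = 0.02, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * ncol(centers), rep(centers[i, ], each = n_per),
                        sd), n_per)
  }))
  x <- abs(x)
  x <- x / rowSums(x)
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  rownames(x) <- seq_len(nrow(x))
  pac <- structure(list(
    pac = x,
    cells = data.frame(label = seq_len(nrow(x)), x_um = 0, y_um = 0,
                       animal = "A1", section = "S1"),
    genes = data.frame(gene = colnames(x), round = 1L,
                       channel = seq_len(ncol(x))),
    normalized = TRUE), class = "pac_matrix")
  list(pac = pac, truth = rep(seq_len(k), each = n_per))
}

five_centers <- rbind(
  c(10, 1, 1, 1, 1), c(1, 10, 1, 1, 1), c(1, 1, 10, 1, 1),
  c(1, 1, 1, 10, 1), c(1, 1, 1, 1, 10)) / 14

test_that("UMAP separates well-separated blobs and is seed-deterministic", {
  fx <- blob_pac(40, five_centers[1:2, ], seed = 2)
  emb <- embed_umap(fx$pac, seed = 5)
  expect_true(all(is.finite(emb)))
  cen <- apply(emb, 2, function(col) tapply(col, fx$truth, mean))
  between <- sqrt(sum((cen[1, ] - cen[2, ])^2))
  within <- mean(sqrt(rowSums((emb - cen[fx$truth, ])^2)))
  expect_gt(between, 5 * within)

  expect_identical(emb, embed_umap(fx$pac, seed = 5))
  expect_false(identical(emb, embed_umap(fx$pac, seed = 6)))
})

test_that("UMAP refuses fewer cells than neighbours + 1", {
  fx <- blob_pac(15, five_centers[1, , drop = FALSE], seed = 3)
  expect_error(embed_umap(fx$pac, n_neighbors = 15), "at least")
})

test_that("Leiden finds the planted five clusters with high agreement", {
  fx <- blob_pac(40, five_centers, seed = 4)
  cl <- cluster_cells(fx$pac, target_k = 5, seed = 7)
  expect_equal(cl$k, 5)
  expect_gte(adjusted_rand_index(cl$cluster, fx$truth), 0.9)
  # determinism and partition coverage
  cl2 <- cluster_cells(fx$pac, target_k = 5, seed = 7)
  expect_identical(cl$cluster, cl2$cluster)
  expect_equal(length(cl$cluster), 200)
  expect_true(all(cl$cluster >= 1))

  expect_error(cluster_cells(fx$pac, resolution_grid = numeric(0)), "empty")
})

test_that("a homogeneous blob takes the warning path with k = 1", {
  fx <- blob_pac(60, matrix(rep(1 / 5, 5), 1), sd = 0.01, seed = 5)
  expect_warning(cl <- cluster_cells(fx$pac, target_k = 5,
                                     resolution_grid = c(0.1, 0.2)),
                 "no grid resolution")
  expect_lt(cl$k, 5)
})

test_that("agreement with an independent ARI implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

marker_pac <- function(clusters, genes = c("Synpr", "Nnat", "Ctgf", "Pcp4")) {
  # raw-PAC matrix whose cluster means encode the standard marker logic
  profile <- rbind(
    core = c(8, 1, 0.2, 0.3), shell = c(1, 8, 0.2, 0.5),
    deep_L6 = c(0.2, 0.2, 8, 2), cortex_a = c(0.2, 0.2, 0.5, 6),
    cortex_b = c(0.2, 0.2, 0.5, 3))
  colnames(profile) <- genes
  x <- profile[clusters, , drop = FALSE] + 0.01 * seq_along(clusters)
  rownames(x) <- seq_along(clusters)
  structure(list(pac = x,
                 cells = data.frame(label = seq_along(clusters)),
                 genes = data.frame(gene = genes, round = 1L,
                                    channel = seq_along(genes)),
                 normalized = FALSE), class = "pac_matrix")
}

test_that("phenotype assignment follows marker order and is relabeling-invariant", {
  truth <- rep(c("core", "shell", "deep_L6", "cortex_a", "cortex_b"), each = 10)
  pac <- marker_pac(truth)
  cl <- structure(list(cluster = stats::setNames(rep(1:5, each = 10),
                                                 seq_along(truth))),
                  class = "cluster_result")
  out <- assign_phenotypes(cl, pac)
  expect_equal(unname(out$phenotype[as.character(1:5)]),
               c("core", "shell", "deep_L6", "cortex_a", "cortex_b"))

  # permuting cluster ids permutes the map but not the per-cell phenotypes
  perm <- c(3L, 5L, 1L, 2L, 4L)
  cl2 <- structure(list(cluster = stats::setNames(perm[rep(1:5, each = 10)],
                                                  seq_along(truth))),
                   class = "cluster_result")
  out2 <- assign_phenotypes(cl2, pac)
  expect_equal(unname(out2$cell_phenotype), unname(out$cell_phenotype))

  # fewer clusters than markers: partial assignment with warning
  cl3 <- structure(list(cluster = stats::setNames(rep(1:2, each = 10),
                                                  seq_len(20))),
                   class = "cluster_result")
  w <- capture_warnings(out3 <- assign_phenotypes(cl3, marker_pac(truth[1:20])))
  expect_match(w, "fewer clusters", all = FALSE)
  expect_false("cortex_a" %in% out3$phenotype)
})

test_that("tied markers resolve to the lowest cluster id with a warning", {
  x <- matrix(1, 20, 4, dimnames = list(1:20, c("Synpr", "Nnat", "Ctgf", "Pcp4")))
  pac <- structure(list(pac = x, cells = data.frame(label = 1:20),
                        genes = data.frame(gene = colnames(x), round = 1L,
                                           channel = 1:4),
                        normalized = FALSE), class = "pac_matrix")
  cl <- structure(list(cluster = stats::setNames(rep(1:2, each = 10), 1:20)),
                  class = "cluster_result")
  w <- capture_warnings(out <- assign_phenotypes(cl, pac))
  expect_match(w, "tied", all = FALSE)
  expect_equal(unname(out$phenotype[["1"]]), "core")
})

test_that("Mann-Whitney DE matches the rank-enumeration oracle and stars are forced", {
  x <- rbind(matrix(c(1, 2, 3), 3, 1), matrix(c(4, 5, 6), 3, 1))
  colnames(x) <- "g"; rownames(x) <- 1:6
  pac <- structure(list(pac = x, cells = data.frame(label = 1:6),
                        genes = data.frame(gene = "g", round = 1L, channel = 1L),
                        normalized = FALSE), class = "pac_matrix")
  de <- differential_expression(pac, 1:3, 4:6)
  expect_equal(de$U, 0)
  expect_equal(de$p_raw, 0.1)
  expect_equal(de$p_raw, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  # identical groups: p = 1, ns
  de2 <- differential_expression(pac, 1:3, 1:3)
  expect_equal(de2$p_adj, 1)
  expect_equal(de2$stars, "ns")

  expect_error(differential_expression(pac, integer(0), 4:6), "non-empty")

  # Bonferroni arithmetic and stars on adjusted p
  expect_equal(min(1, 0.004 * 11), 0.044)
  expect_equal(significance_stars(c(0.044, 0.2, 0.009, 0.0009)),
               c("*", "ns", "**", "***"))
})

test_that("random small-sample U tests agree with enumeration", {
  set.seed(9)
  for (i in 1:5) {
    a <- sample(100, 4); b <- sample(100, 5) + 0.5
    p_pkg <- suppressWarnings(stats::wilcox.test(a, b))$p.value
    expect_equal(p_pkg, mw_exact_oracle(a, b), tolerance = 1e-12)
  }
})
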