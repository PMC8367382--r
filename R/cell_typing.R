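# Embedding, clustering and differential expression over gated, normalized
# PAC profiles. UMAP (15 neighbours, otherwise defaults) and Leiden
# community detection on a kNN graph built with the same neighbour count;
# the Leiden resolution is scanned until exactly `target_k` clusters appear.

#' UMAP embedding of normalized PAC profiles
#'
#' @param pac_norm A normalized `pac_matrix`.
#' @param n_neighbors Number of nearest neighbours (default 15).
#' @param seed Integer seed; coordinates are deterministic given the seed.
#' @return A numeric matrix (cells x 2) of embedding coordinates.
#' @export
embed_umap <- function(pac_norm, n_neighbors = 15, seed = 1) {
  stopifnot(inherits(pac_norm, "pac_matrix"), isTRUE(pac_norm$normalized))
  x <- pac_norm$pac
  if (nrow(x) < n_neighbors + 1) {
    stop(sprintf("need at least %d cells for %d neighbours, got %d",
                 n_neighbors + 1, n_neighbors, nrow(x)))
  }
  emb <- with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, n_threads = 1,
               n_sgd_threads = 0)
  )
  stopifnot(all(is.finite(emb)))
  dimnames(emb) <- list(rownames(x), c("UMAP1", "UMAP2"))
  emb
}

# Undirected, unweighted symmetrized kNN graph on Euclidean distance.
knn_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  idx <- apply(d, 1, function(row) order(row)[2:(k + 1)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering targeting a fixed number of clusters
#'
#' Builds a kNN graph (same neighbour count as the embedding) and scans the
#' Leiden resolution grid in ascending order, returning the first resolution
#' that yields exactly `target_k` clusters - the study's criterion was a
#' resolution "that produced five clusters". If no grid value hits
#' `target_k`, the resolution minimizing `|k - target_k|` is used (ties go
#' to the lower resolution) with a warning.
#'
#' @param pac_norm A normalized `pac_matrix`.
#' @param target_k Desired number of clusters (default 5).
#' @param resolution_grid Ascending resolutions to scan
#'   (default `seq(0.1, 2, by = 0.05)`).
#' @param n_neighbors kNN graph neighbour count (default 15).
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @return A list of class `cluster_result`: `cluster` (integer per cell),
#'   `resolution`, `k`, `means` (cluster x gene raw means filled by
#'   [assign_phenotypes()]), `phenotype` (NULL until assigned).
#' @export
cluster_cells <- function(pac_norm, target_k = 5,
                          resolution_grid = seq(0.1, 2, by = 0.05),
                          n_neighbors = 15, seed = 1) {
  stopifnot(inherits(pac_norm, "pac_matrix"), isTRUE(pac_norm$normalized))
  if (length(resolution_grid) == 0) stop("empty resolution grid")
  if (is.unsorted(resolution_grid)) stop("resolution grid must be ascending")
  x <- pac_norm$pac
  if (nrow(x) < target_k) stop("fewer cells than target clusters")
  g <- knn_graph(x, n_neighbors)
  with_seed(seed, {
    best <- NULL
    for (res in resolution_grid) {
      memb <- igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = res,
        n_iterations = 3))
      k <- length(unique(memb))
      if (is.null(best) || abs(k - target_k) < abs(best$k - target_k)) {
        best <- list(membership = as.integer(memb), k = k, resolution = res)
      }
      if (k == target_k) break
    }
    if (best$k != target_k) {
      warning(sprintf("no grid resolution yielded %d clusters; using %d at resolution %.2f",
                      target_k, best$k, best$resolution))
    }
    structure(list(cluster = stats::setNames(best$membership, rownames(x)),
                   resolution = best$resolution, k = best$k,
                   n_neighbors = n_neighbors,
                   means = NULL, phenotype = NULL),
              class = "cluster_result")
  })
}

#' Assign core / shell / cortical phenotypes to clusters
#'
#' Marker-based assignment on raw PAC cluster means, in fixed marker order:
#' the unassigned cluster with the highest mean Synpr becomes `core`, then
#' highest Nnat becomes `shell`, then highest Ctgf becomes `deep_L6`;
#' remaining clusters are `cortex_a` / `cortex_b` by descending Pcp4 mean.
#' Marker ties break to the lowest cluster id with a warning.
#'
#' @param clusters A `cluster_result`.
#' @param pac_raw The raw (gated, unnormalized) `pac_matrix` with the same
#'   cells.
#' @param marker_map Named character vector phenotype -> marker gene.
#' @param cortex_gene Marker ordering the leftover cortical clusters.
#' @return `clusters` with `means` (cluster x gene matrix), `phenotype`
#'   (map cluster id -> phenotype) and per-cell `cell_phenotype` filled.
#' @export
assign_phenotypes <- function(clusters, pac_raw,
                              marker_map = c(core = "Synpr", shell = "Nnat",
                                             deep_L6 = "Ctgf"),
                              cortex_gene = "Pcp4") {
  stopifnot(inherits(clusters, "cluster_result"), inherits(pac_raw, "pac_matrix"))
  missing <- setdiff(c(marker_map, cortex_gene), colnames(pac_raw$pac))
  if (length(missing)) stop("marker genes absent: ", paste(missing, collapse = ", "))
  ids <- sort(unique(clusters$cluster))
  means <- t(vapply(ids, function(k) {
    colMeans(pac_raw$pac[clusters$cluster == k, , drop = FALSE])
  }, numeric(ncol(pac_raw$pac))))
  rownames(means) <- ids

  phen <- stats::setNames(rep(NA_character_, length(ids)), ids)
  avail <- as.character(ids)
  for (ph in names(marker_map)) {
    if (length(avail) == 0) {
      warning("fewer clusters than markers: partial phenotype assignment")
      break
    }
    m <- means[avail, marker_map[[ph]]]
    top <- which(m == max(m))
    if (length(top) > 1) {
      warning(sprintf("marker %s tied across clusters; using lowest cluster id",
                      marker_map[[ph]]))
    }
    pick <- avail[min(top)]
    phen[pick] <- ph
    avail <- setdiff(avail, pick)
  }
  if (length(avail) > 0) {
    ord <- avail[order(means[avail, cortex_gene], decreasing = TRUE)]
    lab <- c("cortex_a", "cortex_b")
    for (i in seq_along(ord)) {
      phen[ord[i]] <- if (i <= 2) lab[i] else sprintf("cortex_%d", i)
    }
  } else if (length(ids) < length(marker_map) + 1) {
    warning("no clusters left for cortical phenotypes")
  }
  clusters$means <- means
  clusters$phenotype <- phen
  clusters$cell_phenotype <- stats::setNames(
    phen[as.character(clusters$cluster)], names(clusters$cluster))
  clusters
}

#' Mann-Whitney differential expression with Bonferroni correction
#'
#' Two-sided Mann-Whitney U test per gene between two cell groups on raw
#' PAC values (exact when sample sizes permit and no ties, otherwise the
#' normal approximation), Bonferroni-adjusted over the genes tested in the
#' call. Stars are computed on the adjusted p-value: ns p >= 0.05,
#' * < 0.05, ** < 0.01, *** < 0.001.
#'
#' @param pac_raw A raw `pac_matrix`.
#' @param group1,group2 Cell ids (rownames of the PAC matrix).
#' @param genes Genes to test (default: all columns).
#' @return A data.frame of class `de_result`: gene, U, median per group,
#'   p_raw, p_adj, stars.
#' @export
differential_expression <- function(pac_raw, group1, group2,
                                    genes = colnames(pac_raw$pac)) {
  stopifnot(inherits(pac_raw, "pac_matrix"))
  if (length(group1) == 0 || length(group2) == 0) {
    stop("both groups must be non-empty")
  }
  x1 <- pac_raw$pac[as.character(group1), genes, drop = FALSE]
  x2 <- pac_raw$pac[as.character(group2), genes, drop = FALSE]
  res <- lapply(genes, function(g) {
    wt <- suppressWarnings(stats::wilcox.test(x1[, g], x2[, g]))
    data.frame(gene = g, U = unname(wt$statistic),
               median_1 = stats::median(x1[, g]),
               median_2 = stats::median(x2[, g]),
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_raw * length(genes))
  out$stars <- significance_stars(out$p_adj)
  class(out) <- c("de_result", class(out))
  out
}

#' Significance stars for adjusted p-values
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @return `"ns"` for p >= 0.05, `"*"` < 0.05, `"**"` < 0.01,
#'   `"***"` < 0.001.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
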