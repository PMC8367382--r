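#' Default class proportions for the synthetic count matrix
#'
#' Two contaminant classes at the study's ledger proportions (27/1112
#' Snap25-low putative non-neuronal cells, 74/1112 Slc17a7-low cells) and
#' three excitatory classes splitting the remainder.
#'
#' @return A named numeric vector summing to 1.
#' @export
default_count_proportions <- function() {
  p_snap <- 27 / 1112
  p_slc <- 74 / 1112
  rest <- 1 - p_snap - p_slc
  c(synpr_high = 0.4 * rest, nnat_high = 0.4 * rest, cortical = 0.2 * rest,
    snap25_low = p_snap, slc17a7_low = p_slc)
}

#' Generate an scRNA-seq-like count matrix with planted contaminants
#'
#' Draws negative-binomial counts for a small gene panel over five planted
#' classes: Synpr-high, Nnat-high and cortical excitatory neurons plus two
#' contaminant classes, one with zero Snap25 (putative non-neuronal) and one
#' with zero Slc17a7 (putative non-excitatory). Class sizes are the exact
#' largest-remainder apportionment of `n_cells * proportions`, so the
#' planted composition is deterministic; the counts themselves are random.
#' Cells optionally carry an RSC/LEC projection annotation drawn from
#' per-class probabilities, emulating targeted harvesting of
#' retrogradely-labeled cells.
#'
#' @param n_cells Number of cells.
#' @param proportions Named class proportions summing to 1 (see
#'   [default_count_proportions()]).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial `size` parameter.
#' @return A list with `counts` (genes x cells integer matrix), `truth`
#'   (data.frame: cell_id, class, projection) and `genes`.
#' @export
generate_count_matrix <- function(n_cells = 1112,
                                  proportions = default_count_proportions(),
                                  seed = 1, dispersion = 2) {
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("class proportions must be non-negative and sum to 1")
  }
  classes <- c("synpr_high", "nnat_high", "cortical",
               "snap25_low", "slc17a7_low")
  stopifnot(all(names(proportions) %in% classes))
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(proportions)] <- proportions
  proportions <- full
  mu <- count_means()
  proj_p <- list( # P(RSC), P(LEC) per class; remainder unlabeled
    synpr_high = c(0.45, 0.04), nnat_high = c(0.04, 0.45),
    cortical = c(0.05, 0.05), snap25_low = c(0, 0), slc17a7_low = c(0, 0)
  )

  with_seed(seed, {
    n_per <- stats::setNames(apportion(n_cells, unname(proportions[classes])),
                             classes)
    cls <- sample(rep(classes, n_per))
    genes <- rownames(mu)
    counts <- matrix(0L, length(genes), length(cls),
                     dimnames = list(genes, sprintf("cell_%04d", seq_along(cls))))
    for (k in classes) {
      j <- which(cls == k)
      if (length(j) == 0) next
      m <- mu[, k]
      draw <- stats::rnbinom(length(genes) * length(j), size = dispersion,
                             mu = rep(m, times = length(j)))
      counts[, j] <- matrix(as.integer(draw), length(genes), length(j))
    }
    u <- stats::runif(length(cls))
    pr <- t(vapply(cls, function(k) proj_p[[k]], numeric(2)))
    projection <- ifelse(u < pr[, 1], "RSC",
                  ifelse(u < pr[, 1] + pr[, 2], "LEC", "none"))
    truth <- data.frame(cell_id = colnames(counts), class = cls,
                        projection = projection, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, genes = genes)
  })
}

# Per-class negative-binomial means. Contaminant identity is hard-planted:
# the Snap25-low class has mean-zero Snap25 (CPM < 0.001 requires a strictly
# zero count at these library sizes) and the Slc17a7-low class mean-zero
# Slc17a7, so QC attribution against planted truth is exact.
count_means <- function() {
  g <- c(default_panel()$gene, "Snap25", paste0("Hk", 1:7))
  m <- matrix(20, length(g), 5,
              dimnames = list(g, c("synpr_high", "nnat_high", "cortical",
                                   "snap25_low", "slc17a7_low")))
  m["Snap25", ] <- c(200, 200, 200, 0, 200)
  m["Slc17a7", ] <- c(150, 150, 150, 0, 0)
  m["Slc17a6", ] <- c(10, 10, 10, 2, 10)
  m["Synpr", ] <- c(300, 20, 10, 2, 30)
  m["Nnat", ] <- c(20, 300, 10, 2, 30)
  m["Ctgf", ] <- c(5, 5, 200, 2, 10)
  m["Pcp4", ] <- c(10, 15, 100, 5, 20)
  m["Gnb4", ] <- c(120, 80, 10, 2, 10)
  m["Lxn", ] <- c(80, 120, 10, 2, 10)
  m["Cdh9", ] <- c(60, 10, 5, 2, 5)
  m["Slc30a3", ] <- c(10, 10, 60, 2, 10)
  m["Gfra1", ] <- c(10, 30, 40, 2, 10)
  m["Spon1", ] <- c(15, 60, 20, 2, 10)
  m[paste0("Hk", 1:7), ] <- 50
  m
}
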