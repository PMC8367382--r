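# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Largest-remainder apportionment of n into integer class sizes proportional
# to `p` (sums to n exactly; deterministic).
apportion <- function(n, p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1L
  }
  as.integer(base)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a recovered clustering and a reference
#' labelling, used to score cluster recovery against planted phenotypes.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Round-half-up to `digits`, matching how percentages are printed in figures
# (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

`%||%` <- function(x, y) if (is.null(x)) y else x
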