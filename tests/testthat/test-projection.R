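# Retrograde label calling, dual exclusion and contingency arithmetic.

test_that("blank label channels yield zero labeled cells; planted labels are recalled", {
  # recall/false-positive contract is stated at default study conditions
  gt <- generate_ground_truth(seed = 31)
  rend <- render_rounds(gt, optics_model(), seed = 31)
  nuc <- segment_nuclei(rend$rounds[[1]]$dapi, 0.5)
  rois <- expand_rois(nuc, 5)

  blank <- list(RSC = matrix(0, nrow(nuc$labels), ncol(nuc$labels)),
                LEC = matrix(0, nrow(nuc$labels), ncol(nuc$labels)))
  calls0 <- detect_labels(blank, rois)
  expect_equal(sum(calls0$RSC | calls0$LEC), 0)

  calls <- detect_labels(rend$labels, rois)
  cen <- mask_centroids(rois)
  idx <- match_centroids(cen$x_um, cen$y_um, gt$cells$x_um, gt$cells$y_um,
                         max_dist = 3)
  truth_rsc <- gt$cells$rsc[idx]
  truth_lec <- gt$cells$lec[idx]
  expect_gte(sum(calls$RSC & truth_rsc) / sum(truth_rsc), 0.95)
  expect_gte(sum(calls$LEC & truth_lec) / sum(truth_lec), 0.95)
  expect_lte(sum(calls$RSC & !truth_rsc) / max(sum(!truth_rsc), 1), 0.02)
  # planted dual cells are flagged dual
  planted_dual <- which(truth_rsc & truth_lec)
  if (length(planted_dual) > 0) expect_true(all(calls$dual[planted_dual]))

  w <- capture_warnings(one <- detect_labels(rend$labels["RSC"], rois))
  expect_match(w, "missing", all = FALSE)
  expect_false(any(one$LEC))
})

test_that("dual exclusion reproduces the 14-of-739 worked example and degenerate cases", {
  mk <- function(rsc, lec) {
    n <- length(rsc)
    structure(data.frame(cell_id = seq_len(n), RSC = rsc, LEC = lec,
                         dual = rsc & lec),
              class = c("projection_calls", "data.frame"))
  }
  # 739 labeled cells of which 14 dual -> 725 retained, 1.9%
  rsc <- c(rep(TRUE, 350), rep(FALSE, 375), rep(TRUE, 14))
  lec <- c(rep(FALSE, 350), rep(TRUE, 375), rep(TRUE, 14))
  out <- exclude_dual(mk(rsc, lec))
  expect_equal(out$n_labeled, 739)
  expect_equal(nrow(out$retained), 725)
  expect_equal(out$dual_fraction, 1.9)

  none <- exclude_dual(mk(c(TRUE, FALSE), c(FALSE, TRUE)))
  expect_equal(nrow(none$retained), 2)
  expect_equal(none$dual_fraction, 0)

  all_dual <- exclude_dual(mk(rep(TRUE, 5), rep(TRUE, 5)))
  expect_equal(nrow(all_dual$retained), 0)
  expect_equal(all_dual$dual_fraction, 100)
})

# build a retained-calls table + cell table realizing given counts
counts_fixture <- function(rsc_core, rsc_shell, lec_core, lec_shell) {
  n <- rsc_core + rsc_shell + lec_core + lec_shell
  phen <- c(rep("core", rsc_core), rep("shell", rsc_shell),
            rep("core", lec_core), rep("shell", lec_shell))
  rsc <- c(rep(TRUE, rsc_core + rsc_shell), rep(FALSE, lec_core + lec_shell))
  cell_table <- data.frame(cell_id = seq_len(n), phenotype = phen)
  calls <- data.frame(cell_id = seq_len(n), RSC = rsc, LEC = !rsc,
                      dual = FALSE)
  build_contingency(cell_table, calls)
}

test_that("contingency percentages reproduce the printed worked examples", {
  ct <- counts_fixture(rsc_core = 216, rsc_shell = 43,
                       lec_core = 48, lec_shell = 276)
  expect_equal(unname(ct$counts["core", "RSC"]), 216)
  expect_equal(unname(ct$column_totals[["RSC"]]), 259)
  expect_equal(unname(ct$modal_percent[["RSC"]]), 83)
  expect_equal(unname(ct$column_totals[["LEC"]]), 324)
  expect_equal(unname(ct$modal_percent[["LEC"]]), 85)

  # a projection with zero cells reports NA
  ct0 <- counts_fixture(10, 2, 0, 0)
  expect_true(is.na(ct0$modal_percent[["LEC"]]))
})

test_that("conservation: retained RSC + retained LEC + dual = total labeled", {
  gt <- tiny_gt(n_cells = 60, seed = 33)
  rend <- render_rounds(gt, optics_model(), seed = 33)
  nuc <- segment_nuclei(rend$rounds[[1]]$dapi, 0.5)
  rois <- expand_rois(nuc, 5)
  calls <- detect_labels(rend$labels, rois)
  out <- exclude_dual(calls)
  expect_equal(sum(out$retained$RSC) + sum(out$retained$LEC) + out$n_dual,
               out$n_labeled)
})

test_that("projection DE flags planted marker direction and handles the 1-vs-1 degenerate case", {
  x <- cbind(Synpr = c(8, 9, 7, 8, 1, 0, 1, 0.5),
             Nnat = c(0.5, 1, 0, 0.2, 7, 9, 8, 8))
  rownames(x) <- 1:8
  pac <- structure(list(pac = x, cells = data.frame(label = 1:8),
                        genes = data.frame(gene = colnames(x), round = 1L,
                                           channel = 1:2),
                        normalized = FALSE), class = "pac_matrix")
  calls <- data.frame(cell_id = 1:8, RSC = rep(c(TRUE, FALSE), each = 4),
                      LEC = rep(c(FALSE, TRUE), each = 4), dual = FALSE)
  out <- projection_de(pac, calls)
  synpr <- out$de[out$de$gene == "Synpr", ]
  nnat <- out$de[out$de$gene == "Nnat", ]
  expect_gt(synpr$median_RSC, synpr$median_LEC)
  expect_gt(nnat$median_LEC, nnat$median_RSC)
  expect_lt(synpr$p_adj, 0.06)   # exact test floor at 4 vs 4 is 2/70*2
  expect_equal(nrow(out$boxes), 4)
  expect_true(all(out$boxes$q1 <= out$boxes$median))

  one <- data.frame(cell_id = c(1, 5), RSC = c(TRUE, FALSE),
                    LEC = c(FALSE, TRUE), dual = FALSE)
  out1 <- projection_de(pac, one)
  expect_true(all(out1$de$p_adj == 1))

  expect_error(projection_de(pac, calls[calls$RSC, ]), "non-empty")
})

test_that("box summaries follow the hinge and 1.5 IQR whisker convention", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 100)
  b <- coreshell:::box_summary(x, "g", "RSC")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(b$q1, q[1]); expect_equal(b$q3, q[3])
  expect_equal(b$median, q[2])
  # the outlier at 100 lies beyond the whisker and is suppressed
  expect_lt(b$upper_whisker, 100)
  expect_equal(b$upper_whisker, max(x[x <= q[3] + 1.5 * (q[3] - q[1])]))
})
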