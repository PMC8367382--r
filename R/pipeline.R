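# End-to-end orchestration: simulate -> register -> segment -> quantify ->
# cluster -> project, from one config and one seed, producing a
# machine-readable report whose percentages always recompute from their own
# counts. The global seed fans out to per-stage seeds by fixed offsets so
# stages are independently reproducible.

#' Default pipeline configuration
#'
#' All tunables of a full synthetic run in one JSON-serializable list.
#' Defaults are the study conditions the generator emulates: a 500 x 500 um
#' field of 300 excitatory cells in a core / shell / deep-L6 / cortex
#' arrangement, 12 genes over 3 rounds, per-round drift up to 8 px and
#' elastic warp up to 3 px, 0.5% histogram-tail binarization, a one-PAC
#' Slc17a7 gate, UMAP/Leiden with 15 neighbours targeting 5 clusters.
#'
#' @param seed Global seed.
#' @return A config list (class `run_config`).
#' @export
default_config <- function(seed = 7) {
  structure(list(
    seed = as.integer(seed),
    n_cells = 300L,
    field_um = c(500, 500),
    geometry = list(core_radius_um = 100, shell_outer_um = 160,
                    deep_outer_um = 200),
    optics = list(pixel_size_um = 0.5, psf_sigma_px = 1,
                  background_level = 100, read_noise_sd = 5,
                  shot_noise = TRUE),
    transforms = list(rigid_max_px = 8, elastic_amp_px = 3, elastic_grid = 4),
    registration = list(grid_spacing_px = 64, search_px = 16),
    segmentation = list(min_area_um2 = 20, sigma_px = 2, expand_um = 5),
    thresholds = list(tail_fraction = 0.005, tail_fraction_gate = 0.01,
                      gate_pac = 1, label_pac = 1),
    clustering = list(n_neighbors = 15L, target_k = 5L,
                      resolution_min = 0.1, resolution_max = 2,
                      resolution_step = 0.05),
    animal_id = "A1", section_id = "S1"
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks the config against [default_config()]: unknown keys (top-level or
#' nested) are rejected; missing keys are filled with defaults.
#'
#' @param config A (possibly partial) config list.
#' @return The completed `run_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      bad <- setdiff(names(config[[nm]]), names(ref[[nm]]))
      if (length(bad)) stop(sprintf("unknown config key(s) under %s: %s",
                                    nm, paste(bad, collapse = ", ")))
      ref[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      ref[[nm]] <- config[[nm]]
    }
  }
  ref
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline
#'
#' Generates ground truth and images, registers rounds 2-3 to the round-1
#' DAPI frame, segments and expands nuclei, builds / gates / normalizes the
#' PAC matrix, embeds and clusters (per animal; the default run holds one
#' animal), assigns phenotypes, calls and overlays projections, and runs
#' the projection differential expression. Deterministic for a fixed seed.
#'
#' @param config A `run_config` (see [default_config()]); partial lists are
#'   completed via [validate_config()].
#' @param outdir Optional directory; when given, images, tables and the
#'   report are written there.
#' @return A list of class `run_report`; see Details.
#' @details The report carries per-stage counts (`n_planted`,
#'   `n_segmented`, `n_gated`), the thresholds used, cluster sizes,
#'   resolution and phenotype map, the contingency table, dual fraction,
#'   projection DE table, the recovered transforms, ground truth, and the
#'   md5 hash of the config consumed. Every percentage in the report
#'   recomputes from its own counts (enforced at construction).
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  config <- validate_config(unclass(config))
  seed <- config$seed

  gt <- generate_ground_truth(
    field_size_um = config$field_um, n_cells = config$n_cells,
    geometry = config$geometry,
    rigid_max_px = config$transforms$rigid_max_px,
    elastic_amp_px = config$transforms$elastic_amp_px,
    elastic_grid = config$transforms$elastic_grid,
    pixel_size_um = config$optics$pixel_size_um,
    animal_id = config$animal_id, section_id = config$section_id,
    seed = seed)
  optics <- do.call(optics_model, config$optics)
  rendered <- render_rounds(gt, optics, seed = seed + 1000L)
  registered <- register_rounds(rendered,
                                grid_spacing_px = config$registration$grid_spacing_px,
                                search_px = config$registration$search_px)

  nuclei <- segment_nuclei(registered$rounds[[1]]$dapi,
                           pixel_size_um = optics$pixel_size_um,
                           min_area_um2 = config$segmentation$min_area_um2,
                           sigma_px = config$segmentation$sigma_px)
  rois <- expand_rois(nuclei, radius_um = config$segmentation$expand_um)

  tf <- default_tail_fractions(base = config$thresholds$tail_fraction,
                               gate = config$thresholds$tail_fraction_gate)
  pac_raw <- build_pac_matrix(registered, rois, tail_fraction = tf,
                              animal_id = config$animal_id,
                              section_id = config$section_id)
  gated <- gate_excitatory(pac_raw, min_pac = config$thresholds$gate_pac)
  pac_norm <- normalize_within_cell(gated)

  grid <- seq(config$clustering$resolution_min, config$clustering$resolution_max,
              by = config$clustering$resolution_step)
  clusters <- cluster_cells(pac_norm, target_k = config$clustering$target_k,
                            resolution_grid = grid,
                            n_neighbors = config$clustering$n_neighbors,
                            seed = seed + 2000L)
  clusters <- assign_phenotypes(clusters, gated)
  embedding <- embed_umap(pac_norm, n_neighbors = config$clustering$n_neighbors,
                          seed = seed + 3000L)

  cell_table <- data.frame(
    cell_id = gated$cells$label,
    x_um = gated$cells$x_um, y_um = gated$cells$y_um,
    animal = gated$cells$animal, section = gated$cells$section,
    cluster = unname(clusters$cluster),
    phenotype = unname(clusters$cell_phenotype),
    UMAP1 = embedding[, 1], UMAP2 = embedding[, 2],
    stringsAsFactors = FALSE)

  calls <- detect_labels(registered$labels, rois,
                         tail_fraction = config$thresholds$tail_fraction,
                         min_label_pac = config$thresholds$label_pac)
  dual <- exclude_dual(calls)
  contingency <- build_contingency(cell_table, dual$retained)
  pde <- tryCatch(projection_de(gated, dual$retained),
                  error = function(e) NULL)

  report <- structure(list(
    config = config, config_hash = config_hash(config),
    n_planted = nrow(gt$cells),
    n_segmented = max(nuclei$labels, 0L),
    n_gated = gated$gate$retained,
    thresholds = gated$genes[, c("gene", "threshold", "tail_fraction")],
    cluster_sizes = table(clusters$cluster),
    resolution = clusters$resolution, k = clusters$k,
    phenotype_map = clusters$phenotype,
    cell_table = cell_table,
    contingency = contingency,
    dual_fraction = dual$dual_fraction,
    n_labeled = dual$n_labeled, n_dual = dual$n_dual,
    projection_de = pde,
    transforms = registered$transforms,
    ground_truth = gt,
    pac = list(raw = pac_raw, gated = gated, normalized = pac_norm),
    rois = rois
  ), class = "run_report")
  stopifnot(report$n_gated <= report$n_segmented)

  if (!is.null(outdir)) write_report(report, registered, nuclei, outdir)
  report
}

write_report <- function(report, registered, nuclei, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_rounds(registered, file.path(outdir, "registered"))
  write_ground_truth(report$ground_truth, outdir)
  write_label_mask(nuclei, file.path(outdir, "nuclei.tif"))
  write_label_mask(report$rois, file.path(outdir, "rois.tif"))
  utils::write.csv(report$cell_table, file.path(outdir, "cell_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$projection_de)) {
    utils::write.csv(report$projection_de$de,
                     file.path(outdir, "projection_de.csv"), row.names = FALSE)
  }
  summary <- list(
    config_hash = report$config_hash,
    n_planted = report$n_planted, n_segmented = report$n_segmented,
    n_gated = report$n_gated, k = report$k, resolution = report$resolution,
    phenotype_map = as.list(report$phenotype_map),
    contingency_counts = report$contingency$counts,
    modal_percent = as.list(report$contingency$modal_percent),
    dual_fraction = report$dual_fraction,
    n_labeled = report$n_labeled, n_dual = report$n_dual)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d): %d planted -> %d segmented -> %d gated cells\n",
              x$config$seed, x$n_planted, x$n_segmented, x$n_gated))
  cat(sprintf("clusters: k = %d at resolution %.2f; phenotypes: %s\n",
              x$k, x$resolution,
              paste(sprintf("%s=%s", names(x$phenotype_map), x$phenotype_map),
                    collapse = ", ")))
  print(x$contingency)
  cat(sprintf("dual-projection fraction: %.1f%% (%d/%d)\n",
              x$dual_fraction, x$n_dual, x$n_labeled))
  invisible(x)
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses a 3D stack (rows x cols x z) to a 2D image by the per-pixel
#' maximum over z; single-plane input is returned unchanged.
#'
#' @param zstack 3D numeric array (or a 2D matrix, returned as is).
#' @return A 2D matrix.
#' @export
max_intensity_project <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  stopifnot(length(dim(zstack)) == 3, dim(zstack)[3] >= 1)
  out <- zstack[, , 1]
  for (k in seq_len(dim(zstack)[3])[-1]) out <- pmax(out, zstack[, , k])
  out
}
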