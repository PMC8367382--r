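#' The 12-gene probe panel across three imaging rounds
#'
#' Gene-to-(round, channel) assignment for the iterative mFISH design: probes
#' are visualized four at a time over three rounds, in probe-tail order
#' (Cdh9 .. Slc17a7). Each round additionally carries a DAPI channel used as
#' the registration anchor.
#'
#' @return A data.frame with columns `gene`, `round`, `channel`.
#' @export
default_panel <- function() {
  genes <- c("Cdh9", "Ctgf", "Slc17a6", "Lxn",
             "Slc30a3", "Gfra1", "Spon1", "Gnb4",
             "Nnat", "Synpr", "Pcp4", "Slc17a7")
  data.frame(
    gene = genes,
    round = rep(1:3, each = 4L),
    channel = rep(1:4, times = 3L),
    stringsAsFactors = FALSE
  )
}

#' Phenotype expression and projection-affinity models
#'
#' One model per simulated phenotype: core (Synpr-high), shell (Nnat-high),
#' deep layer-6 cortex (Ctgf-high), and two other cortical classes
#' (Pcp4-expressing). Expression is a mean spot density in spots per 100 um^2
#' of somatic area; every phenotype expresses Slc17a7 (all simulated cells
#' are excitatory). `label_affinity` gives the probability that a cell of the
#' phenotype carries the RSC or LEC retrograde label; the two channels are
#' drawn independently, so a small dual-labeled fraction arises.
#'
#' Default affinities: core RSC 0.95 / LEC 0.02, shell RSC 0.02 / LEC 0.95,
#' all cortical classes 0.10 / 0.10. With the default phenotype proportions
#' these imply P(core | RSC) = P(shell | LEC) ~ 0.86 and a dual fraction of
#' ~2.4% of labeled cells (direct enumeration; see the methods vignette).
#'
#' @param proportions Named numeric vector of phenotype proportions
#'   (must sum to 1).
#' @return A list of phenotype models, each with `name`, `proportion`,
#'   `expression` (named density vector over the panel genes) and
#'   `label_affinity` (named RSC/LEC probabilities).
#' @export
default_phenotypes <- function(proportions = c(core = 0.30, shell = 0.30,
                                               deep_L6 = 0.15, cortex_a = 0.15,
                                               cortex_b = 0.10)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  genes <- default_panel()$gene
  # spots / 100 um^2 of somatic area; rows = genes, cols = phenotypes
  dens <- rbind(
    Cdh9    = c(5,   0.5, 0.2, 0.2, 2),
    Ctgf    = c(0.2, 0.2, 18,  1,   0.2),
    Slc17a6 = c(0.5, 0.5, 0.5, 0.5, 0.5),
    Lxn     = c(6,   8,   0.5, 0.5, 0.5),
    Slc30a3 = c(0.5, 0.5, 1,   6,   1),
    Gfra1   = c(0.5, 2,   0.5, 0.5, 6),
    Spon1   = c(1,   6,   2,   0.5, 0.5),
    Gnb4    = c(8,   6,   0.5, 0.2, 0.2),
    Nnat    = c(2,   20,  0.5, 0.2, 0.2),
    Synpr   = c(20,  2,   0.5, 0.2, 0.2),
    Pcp4    = c(0.3, 0.5, 4,   12,  6),
    Slc17a7 = c(6,   6,   6,   6,   6)
  )
  colnames(dens) <- c("core", "shell", "deep_L6", "cortex_a", "cortex_b")
  affin <- list(
    core     = c(RSC = 0.95, LEC = 0.02),
    shell    = c(RSC = 0.02, LEC = 0.95),
    deep_L6  = c(RSC = 0.10, LEC = 0.10),
    cortex_a = c(RSC = 0.10, LEC = 0.10),
    cortex_b = c(RSC = 0.10, LEC = 0.10)
  )
  models <- lapply(names(proportions), function(ph) {
    m <- list(
      name = ph,
      proportion = unname(proportions[[ph]]),
      expression = stats::setNames(dens[genes, ph], genes),
      label_affinity = affin[[ph]]
    )
    class(m) <- "phenotype_model"
    m
  })
  names(models) <- names(proportions)
  validate_phenotypes(models)
  models
}

# Enforce the marker logic every phenotype set must satisfy.
validate_phenotypes <- function(models) {
  dens <- sapply(models, function(m) m$expression)
  if (any(dens["Slc17a7", ] <= 0)) {
    stop("every phenotype must express Slc17a7 (all simulated cells are excitatory)")
  }
  argmax <- function(g) colnames(dens)[which.max(dens[g, ])]
  if ("core" %in% colnames(dens) && argmax("Synpr") != "core") {
    stop("core must carry the panel-max Synpr density")
  }
  if ("shell" %in% colnames(dens) && argmax("Nnat") != "shell") {
    stop("shell must carry the panel-max Nnat density")
  }
  if ("deep_L6" %in% colnames(dens) && argmax("Ctgf") != "deep_L6") {
    stop("deep_L6 must carry the panel-max Ctgf density")
  }
  aff <- unlist(lapply(models, `[[`, "label_affinity"))
  if (any(aff < 0 | aff > 1)) stop("label affinities must lie in [0, 1]")
  invisible(models)
}

#' Optical model for synthetic image rendering
#'
#' Parameters of the simulated acquisition: pixel size, Gaussian PSF width,
#' constant background level, Poisson shot noise on (signal + background)
#' plus Gaussian read noise, and the integer output range.
#'
#' @param pixel_size_um Microns per pixel (> 0).
#' @param psf_sigma_px Gaussian blur sigma in pixels.
#' @param background_level Mean background counts.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param shot_noise If `FALSE`, Poisson and read noise are disabled
#'   (noiseless rendering for oracle tests).
#' @param bit_depth Output bit depth (images are clipped to 2^bit_depth - 1).
#' @param spot_amplitude Integrated counts contributed by one mRNA spot.
#' @param dapi_amplitude Nucleus fill level in counts.
#' @param label_amplitude Retrograde-label soma fill level in counts.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(pixel_size_um = 0.5, psf_sigma_px = 0.5,
                         background_level = 100, read_noise_sd = 5,
                         shot_noise = TRUE, bit_depth = 16,
                         spot_amplitude = 5000, dapi_amplitude = 3000,
                         label_amplitude = 1500) {
  stopifnot(pixel_size_um > 0, psf_sigma_px >= 0, background_level >= 0,
            read_noise_sd >= 0, bit_depth %in% c(8, 16))
  structure(list(
    pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
    background_level = background_level, read_noise_sd = read_noise_sd,
    shot_noise = shot_noise, bit_depth = bit_depth,
    spot_amplitude = spot_amplitude, dapi_amplitude = dapi_amplitude,
    label_amplitude = label_amplitude
  ), class = "optics_model")
}
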