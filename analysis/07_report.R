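#!/usr/bin/env Rscript
# Stage 7 — collate the headline numbers of all stages into results/report.md.

suppressPackageStartupMessages(library(coreshell))

j <- function(...) jsonlite::read_json(file.path("results", ...),
                                       simplifyVector = TRUE)
qc <- j("quantified", "qc_report.json")
reg <- jsonlite::read_json(file.path("results", "registered",
                                     "transforms.json"))
ledger <- j("scrnaseq", "qc_ledger.json")
cells <- read.csv(file.path("results", "typed", "cell_table.csv"))
cont <- read.csv(file.path("results", "projections", "contingency.csv"))
de <- read.csv(file.path("results", "projections", "projection_de.csv"))
cls <- read.csv(file.path("results", "scrnaseq", "class_contingency.csv"))

pct <- function(a, b) round(100 * a / b)
rsc_tot <- sum(cont$RSC); lec_tot <- sum(cont$LEC)
lines <- c(
  "# Synthetic claustrum pipeline report", "",
  "## mFISH stages",
  sprintf("- segmented cells: %d; excitatory gate retained %d / %d",
          qc$n_segmented, qc$gate$retained, qc$gate$total),
  sprintf("- registration total-shift error (px): %s",
          paste(sapply(reg, function(r)
            sprintf("round %d (%.2f, %.2f)", r$round,
                    r$total_shift_error_px$dx, r$total_shift_error_px$dy)),
            collapse = ", ")),
  sprintf("- clusters: %d (%s)", length(unique(cells$cluster)),
          paste(sort(unique(cells$phenotype)), collapse = ", ")),
  sprintf("- RSC-projecting cells in core: %d/%d = %d%%",
          cont$RSC[cont$phenotype == "core"], rsc_tot,
          pct(cont$RSC[cont$phenotype == "core"], rsc_tot)),
  sprintf("- LEC-projecting cells in shell: %d/%d = %d%%",
          cont$LEC[cont$phenotype == "shell"], lec_tot,
          pct(cont$LEC[cont$phenotype == "shell"], lec_tot)),
  sprintf("- projection DE: %s", paste(sprintf("%s p_adj=%.2g %s", de$gene,
                                               de$p_adj, de$stars),
                                       collapse = "; ")),
  "",
  "## scRNA-seq QC",
  sprintf("- ledger: %d in, -%d Snap25-low, -%d Slc17a7-low, %d retained",
          ledger$n_input, ledger$n_excluded$Snap25,
          ledger$n_excluded$Slc17a7, ledger$n_retained),
  sprintf("- RSC cells in Synpr class: %d/%d = %d%%; LEC cells in Nnat class: %d/%d = %d%%",
          cls$RSC[cls$class == "synpr_high"], sum(cls$RSC),
          pct(cls$RSC[cls$class == "synpr_high"], sum(cls$RSC)),
          cls$LEC[cls$class == "nnat_high"], sum(cls$LEC),
          pct(cls$LEC[cls$class == "nnat_high"], sum(cls$LEC))))
writeLines(lines, file.path("results", "report.md"))
cat(lines, sep = "\n")
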