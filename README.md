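# coreshell

Quantification and cell typing for iterative multiplexed single-molecule
FISH (mFISH) of the mouse claustrum, written for analysts who want the
published core/shell pipeline as tested, reusable R code: registration of
probe rounds into a common DAPI frame, percent-area-covered (PAC) scoring
per cell, Leiden typing of excitatory subtypes, and retrograde-projection
contingency analysis — plus a synthetic-data generator with complete
ground truth, so the whole pipeline is testable without any raw images,
and a small scRNA-seq quality-control module.

## The method

A 12-gene probe panel is read out over three imaging rounds (four probes +
DAPI per round). The analysis chain is:

1. **Registration.** The DAPI channel of each round is rigidly registered
   to round 1 (FFT cross-correlation, sub-pixel), then a smooth elastic
   displacement field absorbs the nonlinear tissue warping caused by
   decoverslipping (block matching on a regular grid, densified
   bilinearly). All probe channels of a round receive their round's
   DAPI-derived transform.
2. **Segmentation.** Nuclei are segmented from round-1 DAPI
   (Gaussian/Otsu/watershed) and dilated by 5 µm into disjoint somatic
   ROIs (nearest-nucleus collision resolution).
3. **Quantification.** Each probe image is binarized at the last 0.2–1% of
   its histogram tail (default 0.5%; 1% for the abundant gate gene), and

   `PAC(cell, gene) = 100 · (positive pixels in ROI) / (ROI area)`.

   Cells need one PAC of *Slc17a7* to count as excitatory; the gate gene
   is then dropped and profiles are normalized within cell.
4. **Cell typing.** UMAP (15 neighbours) embeds the normalized profiles;
   Leiden clustering on a 15-NN graph is tuned to exactly five clusters;
   marker means name them: *Synpr* → core, *Nnat* → shell, *Ctgf* → deep
   L6, *Pcp4* orders the remaining cortical clusters.
5. **Projections.** RSC/LEC retrograde-label channels are thresholded the
   same way; dual-projecting cells are excluded (reported to one decimal,
   e.g. 14/739 = 1.9%), and the core/shell × RSC/LEC contingency table and
   Mann–Whitney (Bonferroni) projection DE are computed.
6. **scRNA-seq QC.** CPM = 1e6·count/cell total; cells with Snap25
   CPM < 0.001, then Slc17a7 CPM < 1e-10 are excluded sequentially with a
   ledger (1112 − 27 − 74 = 1011 in the emulated setting).

The synthetic generator plants a core disc / shell annulus / deep-L6 ring /
cortex arrangement of five phenotypes with known expression densities,
per-round rigid + elastic acquisition transforms, and label affinities
(core RSC 0.95, shell LEC 0.95, cross 0.02, cortical background 0.10), so
every stage above can be scored against ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `analysis/07_report.R`), or do it
in one call:

```r
library(coreshell)
report <- run_all(default_config(seed = 7))
print(report)
```

which prints (abridged, from the run used for `results/report.md`):

```
run_report (seed 7): 300 planted -> 300 segmented -> 295 gated cells
clusters: k = 5 at resolution 0.10; phenotypes: 1=shell, 2=core, 3=cortex_a, 4=cortex_b, 5=deep_L6
projection contingency (counts):
      RSC LEC
core   84   0
shell   0  82
modal percentages: RSC-in-core 100%, LEC-in-shell 100%
dual-projection fraction: 1.0% (2/194)
```

Reading it: all 300 planted nuclei were segmented, 295 passed the
excitatory gate, the resolution scan found exactly five Leiden clusters
whose marker phenotypes match the planted zones (adjusted Rand index 1.00
against ground truth for this seed), and after excluding dual-labeled
cells every retained RSC-projecting cell sits in the core cluster and
every LEC-projecting cell in the shell — the synthetic affinities imply
~100% here because cross-labeled cells are nearly always dual-labeled and
excluded. The projection DE confirms the planted directions (*Synpr*
higher in RSC-projecting cells, *Nnat* in LEC-projecting;
Bonferroni p ≈ 3e-25 and 4e-29).

On the scRNA-seq side:

```r
sim <- generate_count_matrix(n_cells = 1112, seed = 7)
qc_filter(compute_cpm(sim$counts))
#> QC ledger: 1112 cells in, -27 Snap25-low, -74 Slc17a7-low -> 1011 retained
```

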