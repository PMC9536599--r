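# cytovol3d

3D image cytometry of epithelial cell and nucleus size dysregulation in
lung adenocarcinoma.

## The problem

Lung adenocarcinoma (LA) cells derived from alveolar type 2 (AT2)
epithelium can grow to many times the normal cell volume without a
matching increase in genome content. Quantifying that claim from tissue
requires an end-to-end measurement chain: 3D segmentation of cell bodies
and nuclei from multi-channel confocal stacks, DNA-stain photometry that
is robust to per-stack brightness differences, ploidy estimation against
a diploid stromal baseline, and population statistics that separate
"bigger because polyploid" from genuinely dysregulated size. `cytovol3d`
implements that chain as a tested R package, exercised end-to-end on
synthetic phantoms with known ground truth.

The package is aimed at quantitative microscopists and computational
biologists who want the individual stages (watershed segmentation,
brightness-calibrated nuclear thresholding, proportionality statistics,
flow size gating) as composable, testable functions.

## The models at the core

* **Boundary-confidence segmentation.** A small 2D UNet (trained from
  scratch, CPU-only) turns a cytokeratin-7-like membrane stain into a
  per-voxel boundary probability; marker-controlled 3D watershed grows one
  cell per nuclear seed over that landscape. A classical ridge-filter
  fallback offers the same interface without training.
* **Nuclear threshold calibration.** The DNA content *d* inside an
  isosurface falls linearly with the threshold *t* (`d = βt − mt·t`) and
  rises linearly as a lamin envelope is dilated by *l*
  (`d = βl + ml·l`). The working point captures 90% of the span,
  `d90 = 0.1·βl + 0.9·βt`, reached at `t90 = 0.1(βt − βl)/mt`, and the
  threshold varies with stack brightness *I* (DNA-histogram centre of
  mass) as `t(I) = 0.6 + k1·e^(k2·I)` (fitted defaults k1 = 0.219,
  k2 = 0.0665).
* **Ploidy.** `dna_number = nuclear DNA total / diploid stromal mode`,
  `ploidy = 2 × dna_number`; near-euploid means ploidy in [1.6, 4.4].
* **Proportionality.** A cell's volume-per-genome `V/n` is compared with
  the diploid AT2 Gaussian (582 ± 127 fL) scaled per genome:
  below (582−127)/2 = 227.5 fL/n is subproportional, above
  (582+127)/2 = 354.5 fL/n supraproportional. Patients are called by a
  conservative cascade: χ² against uniformity, two-sided binomial on
  sub vs supra, and a 2-fold enrichment requirement.
* **Distribution statistics.** Freedman–Diaconis binning
  (`2·IQR/n^(1/3)`), least-squares fits of two-Gaussian / Gaussian /
  lognormal models (`σ = width/√2`), percent-abnormal mass outside
  μ ± kσ with proportion SE `√(p(1−p)/n)`, and fold changes with a
  Taylor-approximation variance.
* **Flow size gating.** Zombie-Red⁻ → EPCAM⁺ → DNA ≤ 1.5× mode signal
  gates, SSC-W bins G1–G4 (64–79, 84–99, 101–113, 114+) inside the
  50–200 SSC-H trim, and the linear size model
  `A = −159 + 4.35 × SSC-W µm²`.
* **Global alignment.** Needleman–Wunsch with affine gaps (Gotoh; BLOSUM62,
  open 11, extend 1), reproducing the 86% identity of the mouse and human
  prosurfactant protein C propeptides bundled under `inst/extdata/`.

## Worked example

```r
library(cytovol3d)

# 1. a synthetic tumor phantom with known ground truth
shape <- c(48L, 96L, 96L); voxel <- 0.5          # um per axis
extent <- (shape - 1) * voxel
cells <- list(
  cell_truth(extent * c(0.5, 0.25, 0.25), cell_volume = 900,  nuclear_volume = 310,
             ploidy = 2, cell_class = "tumor"),
  cell_truth(extent * c(0.5, 0.75, 0.25), cell_volume = 1500, nuclear_volume = 520,
             ploidy = 4, cell_class = "tumor"),
  cell_truth(extent * c(0.5, 0.25, 0.75), cell_volume = 700,  nuclear_volume = 240,
             ploidy = 2, cell_class = "tumor"),
  cell_truth(extent * c(0.5, 0.75, 0.75), cell_volume = 1100, nuclear_volume = 380,
             ploidy = 2, cell_class = "tumor"))
ph <- generate_phantom_stack(phantom_spec(shape, voxel, cells,
                                          noise_sd = 2, rng_seed = 1))
ph$stack
#> <image_stack 'phantom-1'> 48 x 96 x 96 voxels (z,y,x), 0.5 x 0.5 x 0.5 um, channels: SPC, CK7, DNA

# 2. boundary confidence + seeded watershed segmentation
conf  <- ridge_boundary_confidence(ph$stack)
seeds <- seed_set(as.matrix(ph$truth[, c("center_z", "center_y", "center_x")]))
seg   <- segment_tumor_cells(conf, seeds, voxel)
vols  <- tabulate(seg$labels[seg$labels > 0], 4) * voxel^3
round(cbind(true_fL = ph$truth$cell_volume, estimated_fL = vols), 1)
#>      true_fL estimated_fL
#> [1,]     900        856.8
#> [2,]    1500       1436.4
#> [3,]     700        661.4
#> [4,]    1100       1047.4

# 3. ploidy from DNA totals against a diploid baseline
dna <- get_channel(ph$stack, "DNA")
totals <- vapply(1:4, function(i) sum(dna[ph$nucleus_labels == i]), 1)
baseline <- suppressWarnings(baseline_from_totals(rep(totals[1], 25)))
ploidies <- vapply(totals, function(t) estimate_ploidy(t, baseline)$estimated_ploidy, 1)
round(ploidies, 2)
#> [1] 2.00 3.98 1.98 2.01

# 4. cell-level proportionality against the wild-type band
classify_cell(vols, ploidies)
#> [1] "supra"        "supra"        "proportional" "supra"

# 5. the flow-cytometry size model and the propeptide alignment
predict_area(100, area_model())          # um^2 at SSC-W = 100
#> [1] 276
seqs <- prospc_propeptides()
needleman_wunsch(seqs[[1]], seqs[[2]])$percent_identity
#> [1] 86
```

Segmented volumes track the generating truth to a few percent; estimated
ploidies recover the assigned 2n/4n within ~1%; three of the four
phantom cells carry more volume per genome than the wild-type AT2 band
(supraproportional), which is exactly the dysregulation signature the
pipeline is built to detect; SSC-W = 100 maps to 276 µm² under the
printed size model; and the propeptide pair aligns at 86% identity.

## Layout

* `R/` — synthetic data, stack I/O and preprocessing, boundary UNet,
  segmentation, DNA quantification, morphometry, size statistics,
  proportionality, cytometry gating, alignment, pipeline orchestration
  (`run_pipeline()`, CLI in `inst/cli/cellvol3d.R`).
* `src/` — Rcpp primitives: separable Gaussian, squared EDT, 6-connected
  labelling, priority-flood watershed, per-slice hole filling, local
  maxima, marching-tetrahedra surface area.
* `vignettes/methods.Rmd` — the models, assumptions, parameter choices
  and known limitations.
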