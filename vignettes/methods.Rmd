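---
title: "Methods: models, parameters and design choices in cytovol3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cytovol3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cytovol3d` measures cell and nucleus volume dysregulation of lung
epithelial cells in 3D confocal data. This vignette records the science
behind each stage — the model, its assumptions, the tunable parameters
with units and defaults, and the choices we made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The measurement problem

Alveolar type 2 (AT2) cells are the presumed cell of origin of lung
adenocarcinoma (LA). Normal AT2 cells keep a tight cell-volume
distribution, well described by a two-Gaussian mixture whose diploid peak
sits at 582 ± 127 fL (cell body) and 202 ± 34.2 fL (nucleus). LA cells
stain strongly for cytokeratin 7 (CK7) and can reach many times these
volumes. The scientific question the pipeline supports is whether that
enlargement is explained by ploidy — polyploid cells are expected to be
proportionally larger — or whether near-euploid cells (1.6–4.4n) are
themselves dysregulated. Every stage below exists to produce one row per
cell containing a volume, a nuclear volume and a ploidy estimate robust
enough to make that call.

## 2. Synthetic data: the stated world

Real stacks for this protocol are not publicly available, so the package
generates its own inputs with known ground truth
(`generate_phantom_stack()`, `generate_measurement_table()`,
`generate_flow_events()`, `generate_annotation_pairs()`). The phantom
emulates the acquisition geometry (8-bit multi-channel stacks, isotropic
voxels, channels SPC / CK7 / DNA / optional LMN) and the features the
downstream stages depend on:

* **Geometry.** Cells are spheres or ellipsoids with exact rasterised
  labels; nuclei are concentric with `nuclear_volume < cell_volume`;
  1 fL = 1 µm³ throughout. Coordinates are voxel-indexed, 0-based, with
  z as the leading axis; physical positions always go through
  `voxel_size`.
* **DNA photometry.** Integrated DNA intensity per nucleus is *exactly*
  proportional to assigned ploidy before noise; noise is multiplicative
  lognormal with configurable CV (`noise_cv`, the paper-silent choice)
  plus optional additive Gaussian read noise. The per-voxel density is a
  flat core with a linear fall-off of width `dna_edge_softness`
  (default 0.75 µm) reaching zero at the nuclear surface. The soft edge
  is not cosmetic: the threshold-calibration model assumes DNA content
  decreases smoothly with threshold, which a hard-edged disc cannot
  provide. The width is a PSF-scale choice made once; volumes and totals
  are renormalised so ploidy-proportionality is unaffected.
* **CK7.** A membrane band of about one voxel's half-width centred on the
  true cell surface plus weak cytoplasmic fill — the realistic image of a
  membrane stain under a finite PSF. The watershed then splits the band
  symmetrically, which is what keeps phantom volume recovery unbiased.
* **Attenuation.** Intensity is scaled linearly in z from 1 at the top to
  `1/attenuation_factor` at the bottom (factor 2 reproduces the observed
  ~2-fold dimming across a deep stack); the SPC-like 488 nm channel is
  exempt, as in the source protocol.
* **Quantisation.** Channels are rounded to the 8-bit grid at generation,
  so written stacks round-trip bit-exactly.

What the phantom does *not* model: PSF convolution, chromatin texture,
multi-patient batch effects beyond a global brightness scalar, or
AT2 process networks. A green phantom test therefore establishes that the
algorithms implement their models correctly — not that the models capture
every property of real tissue.

Measurement tables draw the normal population from the two-Gaussian
mixture, with the 4n fraction defaulting to 0.17 so the mixture mean
matches the observed overall AT2 mean (682.3 fL); tumor populations are
lognormal, moment-matched to the printed near-euploid summary
(1086 ± 755.6 fL); DNA totals are `ploidy/2 × stromal mode ×` lognormal
noise with CV 0.05 (the value at which ploidy-recovery accuracy is
specified). The tumor ploidy mix (45% 2n, 20% 4n, 15% 5n, 10% 6n,
10% 8n) was chosen once to give a near-euploid fraction of ~0.65,
matching the reported range across stages.

## 3. Preprocessing

Two corrections precede all segmentation:

* **Attenuation correction** (`correct_attenuation()`): a two-point model
  — mean reference intensities measured near the top and bottom of the
  stack — defines a gain linear in z with `g(top) = 1` and
  `g(bottom) = top/bottom`. The correction commutes with global intensity
  scaling and is applied per channel (the SPC channel may use the
  identity).
* **Background subtraction** (`subtract_background()`): the source
  protocol's tool documents only a filter width (default 33.7 µm), so we
  implement it as a Gaussian high-pass with σ = width/2: the smooth
  background estimate is subtracted and the result clipped at zero.
  Constant images map to zero, PSF-scale spots pass nearly unchanged, and
  structure much broader than the width is suppressed by more than 90%.

## 4. Boundary confidence: a small UNet

Cell boundaries are predicted slice-wise by a 2D encoder/decoder network
with a skip connection, trained on annotation crops with binary
cross-entropy (clamped at ε = 1e-7), Adam, and dropout. Design points:

* The original recipe (448 px corner crops of 900 px slices → 160 base
  crops, augmented ×31 to 4960, 80/20 train/validation split,
  stop when training loss < 0.001) is the default `training_config()`;
  the synthetic test suite scales it down (64 px crops, a few epochs)
  to stay inside CPU budgets.
* Normalisation is division by 255 and per-crop mean subtraction.
* Stopping uses the *training* loss; validation loss is logged only.
* The loss as printed in the source omits the conventional negative sign;
  we implement standard positive BCE.
* Inference is 2D slice-wise, tiled with 32 px overlap and linear
  blending, assembled into a 3D confidence volume in [0, 1].
* Depth and width are configurable (`depth`, `base_channels`); only the
  architecture family is anchored by the source, so the default is the
  smallest network that passes the recovery tests.
* `ridge_boundary_confidence()` is a classical fallback (smoothed,
  normalised CK7 ridge response) behind the same contract, so the
  downstream pipeline is testable without training.

## 5. Segmentation

* **Tumor cells** (`segment_tumor_cells()`): marker-controlled watershed
  (priority flood, 6-connectivity, FIFO tie-breaking for determinism) on
  the Gaussian-smoothed (0.3 µm) confidence landscape. The stack border
  acts as an implicit background marker so labels settle on boundary
  ridges instead of flooding the stack; per-seed growth is capped at
  `max_radius` (default 20 µm, the radius of the largest plausible cell),
  and capped or edge-touching labels are flagged. This replaces the
  proprietary membrane-detection fit of the original workstation: the
  input structure (nuclear seeds + boundary ribs) maps directly onto
  marker-controlled watershed.
* **AT2 cells** (`segment_at2_cells()`): coarse SPC isosurface (1 µm
  smoothing, threshold 7–12) → 3D erosion by 0.7–1 µm via the Euclidean
  distance transform → splitting by watershed on the negative EDT with
  5 µm seed maxima → removal of process-scale fragments. Erosion
  monotonically reduces neighbour-nucleus contamination (tested as a
  property).
* **Stromal nuclei** (`segment_stromal_nuclei()`): DNA threshold, 3 µm
  seed splitting, then the two curation rules: at least 4 µm from every
  stack face and CK7-negative.
* **QC** (`qc_cells()`): the manual curation rounds of the source are
  replaced by their quantified rules — fatal if >10% of a cell's voxels
  lie on stack faces or if it overlaps >10% of a foreign nucleus; N:C
  ratios in the top/bottom deciles are flagged for review but not
  deleted (the original deleted only models that also failed visual
  checks); double nuclei are retained only when their components are
  6-adjacent (fused envelopes).

## 6. DNA quantification and ploidy

The central calibration couples two linear behaviours of the DNA content
`d` inside an isosurface: `d(t) = βt − mt·t` (content falls as the
threshold rises) and `d(l) = βl + ml·l` (content rises as a lamin-based
envelope is dilated; the lamin surface systematically underestimates the
nucleus). The working point is `d90 = 0.1·βl + 0.9·βt` — 90% of the
span up to the zero-threshold maximum — reached at dilation
`L90 = 0.9(βt − βl)/ml` and threshold `t90 = 0.1(βt − βl)/mt` (the
algebraic simplification of the printed two-term expression; the identity
is asserted numerically over random curves to 1e-9). Sweeps average
regression slopes and intercepts across fitted nuclei, and a sweep that
is not strictly decreasing in threshold is a model violation and errors.

Because `t90` drifts with overall stack brightness, it is regressed on
the DNA-histogram centre of mass `I` (computed over nonzero voxels of the
background-subtracted channel — the support is our choice, the source is
silent) through `t(I) = 0.6 + k1·e^(k2·I)` with the 0.6 floor fixed
(segmentation breaks down below it); the published fit gives k1 = 0.219,
k2 = 0.0665. The fit minimises plain least squares in t (not log-space;
an open question in the source, decided here once). Within a calibrated
brightness family the fitted curve keeps nuclear volumes stable to within
5% across ±2× rescales — the exponential cannot track a strictly
proportional t90(I) law over an arbitrary range, so calibration points
should span the brightnesses to which the model will be applied, exactly
as the original calibrated across its six test files.

`segment_nucleus()` applies `t(I)` to the cell-masked, 0.3 µm-smoothed
DNA channel, keeps the largest component, fills cavities slice-by-slice
(oversized tumor nuclei are often DNA-poor inside), and reports the
fill-only volume delta. `stromal_baseline()` fits a single Gaussian to
background-subtracted stromal totals and uses the fitted centre — not the
histogram argmax — as the diploid mode, warning below the 20-nucleus
minimum; with fewer than 8 nuclei it falls back to the median.
`estimate_ploidy()` is then `2 × total/mode`, with near-euploid defined
as the inclusive interval [1.6, 4.4] (the source writes the range without
bracket semantics; we chose inclusive).

## 7. Morphometry

Volumes are exact voxel arithmetic. Surface areas come from marching
tetrahedra on the σ = 0.7-voxel smoothed binary mask — the estimator
agrees with the field-standard marching-cubes approach and keeps
digitised-sphere areas within about a percent; sharp corners are rounded
at the resolution limit, so closed-form polyhedron checks are run at fine
voxel sizes. Sphericity `π^(1/3)(6V)^(2/3)/A` is clamped at 1 (the mesh
can undercount a digitised sphere's area by a fraction of a percent).
Ellipticities use inertia-tensor semi-axes a ≥ b ≥ c with the package
convention `prolate = (2a − b − c)/(2a)`, `oblate = (a + b − 2c)/(a + b)`
— only their ratio (elongation) is consumed downstream. Shell enrichment
erodes the nucleus by 1.5 µm via the EDT and reports shell density over
whole-nucleus density (the figure-legend variant dividing by the core
density is available behind `reference = "core"`). The Ki-67 cascade
keeps CK7-positive records (total ≥ 3×10⁴) with Ki-67 strictly > 2×10⁴,
sphericity > 0.5 and volume > 150 µm³. The 2D long axis is the major axis
of the z-projection's best-fit ellipse (4 × the major-direction SD, exact
for a filled ellipse).

## 8. Size statistics

Histograms use Freedman–Diaconis bins (`2·IQR/n^(1/3)`); constant data
errors rather than silently picking a width. The three regression models
(two-Gaussian mixture, single Gaussian, lognormal) are fitted to bin
counts by unweighted least squares with the baseline fixed at zero;
χ²/df is computed post hoc with Poisson variances floored at 1. The
Gaussian width parameterisation `exp(−((x−x1)/width)²)` means
`σ = width/√2` (179 → 127 in the canonical example). Percent-abnormal
mass outside μ ± kσ of the diploid normal Gaussian is computed in closed
form from the fitted model (k defaults to 2 and is always recorded — the
original drew the region with a magic-wand tool, so the boundary is a
config parameter here) with SE `√(p(1−p)/n)`. Fold changes use the
independence Taylor approximation for Var(X/Y); the printed SE formula is
typographically ambiguous, so the literal reading
`√(var/(nx² + ny²))` is the default and the conventional delta-method SE
is available via `method = "conventional"` — both are always returned.

## 9. Proportionality calls

Cells: `V/n` against the unrounded slopes (582 ∓ 127)/2 = 227.5 and
354.5 fL per genome (`truncate = TRUE` reproduces the printed integer
truncation). Near-WT requires volume in 455–709 fL *and* near-euploidy,
all bounds inclusive. Patients: χ² against uniform over the three bins
(df = 2, asymptotic even at small n, matching the spreadsheet formulas),
then a two-sided binomial on sub vs supra at p = 0.5 (the source does not
state sidedness; two-sided is the conservative choice), then a ≥2-fold
enrichment requirement with a zero denominator counting as enriched; any
retained null yields "Proportional". The implementation is verified
against an exhaustive enumeration of the decision tree for all count
triples totalling ≤ 30.

## 10. Flow-cytometry gating

Signal gates run sequentially — Zombie-Red⁻ (live when fixed), EPCAM⁺,
DRAQ5 ≤ 1.5× the mode — with per-stage counts logged. Cutoffs are
data-driven per sample, as in the source: the live cutoff intersects the
left slope of the dead peak at half maximum, the EPCAM cutoff sits at the
density valley between the populations, and the DNA mode is the
Freedman–Diaconis histogram argmax on the depleted population; all three
are overridable, and on overlapping lognormal populations the heuristics
deliver high but not perfect purity. Size bins G1–G4 (SSC-W 64–79,
84–99, 101–113, 114+) apply inside the 50–200 SSC-H trim; values between
bins map to none. The SSC-W → area model `A = −159 + 4.35·W µm²` is both
invertible (used by the event generator) and refittable by OLS with
parameter SEs. FCS binary parsing is out of scope; events are synthetic
or CSV-imported.

## 11. Global alignment

`needleman_wunsch()` is a three-state Gotoh dynamic programme (affine
gaps: a gap of length L costs open + extend·L; defaults 11 and 1,
BLOSUM62 from Biostrings) with deterministic tie-breaking (substitution
preferred over gaps, then gap in the first sequence). Identity divides
matches by the full alignment length including gap columns. For the
bundled mouse/human propeptide pair the optimal alignment is gapless, so
the 86% identity is robust to the substitution matrix — the test suite
asserts agreement with the plain Hamming identity, with a brute-force DP
on short sequences, and with `Biostrings::pairwiseAlignment` as an
independent reference.

## 12. Orchestration and reproducibility

`run_pipeline()` executes the stage graph (phantom → preprocess →
boundary → segmentation → DNA → morphometry → statistics →
proportionality) with a single config carrying every anchored constant
(0.6 threshold floor, 33.7 µm background width, 1.6–4.4n, 1.5 µm shell,
gates, proportionality bounds) and one seed; a statistics-only path runs
from an existing record CSV. The manifest records the package version,
seed, a config fingerprint and per-stage outputs; reruns with the same
config reproduce deterministic outputs bit-exactly. All randomness in the
package flows through explicit seeds (`with_seed()` restores the caller's
RNG state).

## 13. Known limitations

* The phantom's realism is calibrated only by downstream recovery tests;
  no PSF, spectral bleed-through or chromatin texture is simulated.
* The exponential threshold model cannot represent an exactly
  scale-proportional t90(I); brightness compensation is guaranteed only
  across the calibrated range.
* The second-pass refit of failed cell models with an enlarged diameter
  is workstation-specific and has no equivalent here.
* Surface areas (hence sphericities) are resolution-limited near sharp
  edges; at the acquisition voxel sizes the estimator is accurate to a
  few percent.
* AT2 process networks are deliberately not segmented, and cells staining
  with neither marker are invisible to the pipeline, mirroring the
  source protocol's stated exclusions.
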