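---
title: "Extracellular flux analysis of single spheroids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracellular flux analysis of single spheroids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroflux)
```

## The workflow and its assumptions

`spheroflux` analyzes Mito Stress assays on single cancer spheroids: one
scaffold-free 3-D aggregate per well of a 96-well extracellular-flux plate,
measured over repeated cycles of OCR (pmol O₂/min/well) and ECAR
(mpH/min/well) while ATP synthase (oligomycin), the proton gradient (FCCP)
and complexes I/III (rotenone + antimycin A) are sequentially inhibited.
The package assumes:

* **Per-well rates are whole-spheroid rates.** The instrument integrates
  over the well; all normalization to biological material happens
  downstream, via imaging.
* **Projected area is a linear proxy for viable cells.** Spheroids formed
  over ~72 h in U-bottom ultra-low-attachment wells are near-spherical and,
  over the practical seeding range (5–20 × 10³ cells/well), their largest
  cross-section grows linearly with the digestion-counted viable-cell
  number. The calibration intercept is *estimated*, not forced through the
  origin: a necrotic core contributes area but no viable cells.
* **Movement artifacts are discarded, not repaired.** A spheroid nudged off
  the sensor spot by a mixing step produces a step change in OCR that
  carries no biology; such wells are excluded.

## Parameter extraction conventions

With `B` the **last** basal-phase OCR, `O` the oligomycin-phase minimum,
`F` the FCCP-phase maximum and `N` the rotenone/antimycin A minimum:
non-mitochondrial = `N`, basal = `B − N`, ATP-linked = `B − O`, proton leak
= `O − N`, maximal = `F − N`, spare = maximal − basal, spare% =
`100·maximal/basal`.

Three conventions deserve justification:

* *Last basal measurement, not the basal mean.* The pre-injection signal is
  still settling from plating and equilibration; the final basal cycle (the
  3rd under the default schedule) is the conventional settled value and is
  what published box plots of "basal OCR" use.
* *Minimum after rotenone/antimycin A, not the final cycle.* Post-inhibition
  rates keep falling through the last cycles of a standard 16-cycle run;
  the phase minimum is the best available estimate of the residual.
* *Maximal respiration subtracts the non-mitochondrial floor* (vendor
  convention). `extract_params(maximal_subtracts_non_mito = FALSE)`
  reports the raw FCCP plateau for comparison with sources that do not
  subtract.

`spare_capacity_pct` is returned as `NA` with a `nonpositive_basal`
quality flag when basal respiration is ≤ 0 (rather than erroring): such
wells are biologically suspect but should surface in QC tables, not crash
a plate.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| jump threshold `theta` | 0.4 | relative | within-phase drift in settled synthetic kinetics stays ≲ 0.2; a 40% cycle-to-cycle change without an injection indicates movement. Published multi-spheroid kinetics can show late rotenone/antimycin decay steps of 30–36%, so `theta` (and per-phase screening) is exposed rather than hard-coded. |
| jump floor `epsilon` | 1 | pmol/min | guards the denominator for near-zero traces |
| displacement `delta_um` | 200 | µm | of the order of one spheroid radius; smaller shifts keep the spheroid over the sensor |
| size-class edges | 7000, 10500, 15500, 22000 | cells | published class labels leave gaps (10k→11k, 15k→16k); the midpoint closes them so classes partition the range |
| `min_size_px` (segmentation) | 100 | px | pure noise above an Otsu threshold forms only scattered specks; a real spheroid spans thousands of pixels |
| perimeter `smooth_sigma` | 1.5 | px | sub-pixel marching squares needs a lightly smoothed level set (below) |
| normalization basis | per 1000 cells / per 1000 µm² | — | keeps per-cell rates O(1); raw per-cell values are an exact rescale |
| background correction | off | — | instrument exports are usually already background-subtracted; enabling it twice is a state error |

## The synthetic cohort generator

The generator's defaults *are* the stated experimental world and are not
tuned per test:

* **Cell counts** are lognormal around `seeded × growth_factor`
  (default 10,000 × 1.25) with CV 10% for the single-spheroid protocol and
  50% for the multiple-spheroids (flask) protocol — the two published
  homogeneity regimes. Lognormality matches the long right tail of flask
  cohorts and guarantees positivity.
* **Area** follows `cells = 0.03·area` (µm²) with 3% multiplicative
  measurement noise. The slope is fixed once: it places a 12,500-cell
  spheroid at ~417,000 µm², the scale observed for single-protocol
  spheroids seeded at 10,000 cells/well.
* **Kinetics**: per-phase targets are fractions of the well's basal rate
  (oligomycin plateau 0.55·B, FCCP maximum 1.6·B, residual 0.30·B for the
  aerobic profile), approached geometrically. The first post-injection
  cycle uses a fast "entry" constant — drugs act quickly, and that pair
  spans the injection so it is never jump-tested — and later cycles a
  gentle "within" constant, keeping genuine drift steps ≈ 15%. The true
  within-phase time constants of real instruments are cell- and
  protocol-dependent; these values are documented as arbitrary and only
  guarantee monotone within-phase drift.
* **Measurement noise** is multiplicative at 8% CV (published phase SDs
  scale with the mean), redrawn when a draw would go non-positive (count
  logged).
* **Background wells** are zero-mean Gaussian traces (SD 0.5).
* **Artifacts** are persistent level drops from a given cycle onward (a
  spheroid that moved stays moved), not single-cycle spikes.
* The bundled profiles (`profile_aerobic()`, `profile_glycolytic()`)
  qualitatively mirror an aerobic, stress-responsive line versus a
  less-respiratory, glycolytically plastic one. They are synthetic: no
  claim is made that they are fitted parameters of any real cell line.

**What a green test establishes — and what it does not.** The simulation
reproduces dispersion regimes, linear area–cell structure, four-phase
kinetics shape, background behavior and artifact phenomenology. It does
*not* model oxygen diffusion into the spheroid core, instrument transients
or level (raw tick) data, cross-well optical crosstalk, or drug-response
heterogeneity within a well. Consequently, pipeline correctness and regime
reproduction are established at simulation level; published real-data PCA
variance splits (~87% for PC1+PC2) are **not** reproducible without the
original per-spheroid measurements and are deliberately out of scope.

## Numerical choices

* **Perimeter/circularity.** Circularity `4πA/P²` is used for "roundness"
  (the screen software's exact formula is unpublished; this matches the
  ImageJ convention). `A` is the mask pixel count times pixel area —
  keeping the invariant `area = pixels × pixel_size²` exact — while `P`
  comes from marching squares on a Gaussian-smoothed (σ = 1.5 px) mask
  with linearly interpolated 0.5-level crossings. A midpoint polygon on
  raw binary data overestimates smooth contours by ~6%, which would cap a
  disk's circularity at ~0.89; the sub-pixel contour brings rasterized
  disks to ≥ 0.997 and a 2:1 ellipse within 0.003 of its
  elliptic-integral value. Saddle cases are resolved by the cell-center
  mean.
* **Segmentation.** Global Otsu (256 bins) — tracker fluorescence is
  high-contrast single-object imaging, so adaptive thresholding is
  unnecessary; largest 4-connected component; interior holes filled
  before measurement (spheroid cores can image dimmer than rims);
  border-touching components measured but flagged as possibly truncated.
* **PCA** is covariance-based on the min–max-scaled matrix (the scaling
  already equalizes ranges; correlation PCA would standardize twice —
  `correlation = TRUE` is available). Loadings carry a deterministic sign
  convention (largest-magnitude loading positive), so repeated runs are
  bit-identical.
* **Min–max scaling** maps constant columns to 0 with a classed warning;
  bounds are retained for exact inversion of non-constant columns.
* **Clustering** is unweighted average linkage (UPGMA) on Euclidean
  distances via `stats::hclust`, validated in the test suite against a
  brute-force O(n³) oracle through cophenetic distances. `hclust` is
  deterministic for fixed input order; ties in distance are resolved by
  its stable merge order.
* **t-tests** default to Welch's unequal-variance form — the safer choice
  when only "unpaired t-test" is specified — with `var_equal = TRUE`
  available. Two identical constant groups return p = 1 rather than NaN.
* **CV** uses the sample (n−1) SD; this convention reproduces published
  mean/SD/CV table rows to their printed 0.1 precision.
* **Determinism.** Every simulation takes a mandatory seed; the analysis
  path is seed-free and deterministic, and all pipeline outputs are plain
  text (CSV/YAML/Newick/log) so identical (config, seed) pairs produce
  byte-identical report bundles. Plot functions exist for interactive use
  but the pipeline never writes image files.

## Degenerate inputs

Empty image stacks, masks, or foregrounds; schedules not starting at cycle
1, non-contiguous, or out of canonical phase order; rate tables with
missing columns, unknown wells, or duplicate (well, cycle) records; plates
with no background wells when correction is requested; double background
correction; normalization by zero cells — all raise classed errors
(`sf_*_error`) that name the offending entity. Wells missing single cycles
are flagged `incomplete` and skipped by parameter extraction rather than
imputed: the parameters depend on within-phase extremes, which imputation
would bias.

## Known limitations

* ECAR is analyzed as acidification only; conversion to proton efflux via
  buffer capacity, glycolytic-rate assays, and ATP-rate decompositions are
  out of scope.
* Morphometry is 2-D (largest projected section); no volumetric
  reconstruction or intra-spheroid nuclei counting.
* The jump detector formalizes what practitioners judge visually; its
  threshold is a package choice, not a published rule, and should be
  re-examined for kinetics with very deep post-inhibition decays.
* Multi-spheroid wells (flask protocol transfers) are supported only as a
  dispersion regime in the simulator; the image pipeline assumes one
  spheroid per image.
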