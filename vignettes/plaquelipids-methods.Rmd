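---
title: "Models and methods behind plaquelipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plaquelipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquelipids)
```

This vignette documents the models, defaults and numerical choices in
`plaquelipids`: what each stage assumes, which knobs matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open.

## The spectroscopic model

Tissue IR absorbance spectra are treated as an additive superposition of
vibrational bands on a smooth baseline. The two bands that carry the
biology here are the alkene =C-H stretch at 3012 cm⁻¹ (present only in
unsaturated acyl chains) and the ester C=O stretch at 1738 cm⁻¹ (one per
glycerolipid acyl linkage, hence a proxy for total lipid). Their
baseline-corrected ratio `U = A3012/A1738` is the per-pixel unsaturation
index. Using a ratio makes `U` invariant to multiplicative intensity
effects (section thickness, focus), which is the property that makes it
comparable across pixels and samples.

**Band quantification.** A band is measured as *peak height above a local
linear baseline*: the maximum absorbance within `center ± halfwidth`
minus a straight line through the mean absorbance of two flanking anchor
windows, floored at zero. Height was chosen over integrated area because
it is less sensitive to neighbouring-band overlap at the band spacings
involved; an area mode is available via `band_absorbance(mode = "area")`.
The anchor windows shipped with `band_alkene()` (2975–2990 / 3035–3050)
and `band_ester()` (1700–1712 / 1765–1777) sit in band-free regions of
the band model; height is exactly invariant to constant offsets and, for
anchors symmetric about the peak, to any linear-in-wavenumber baseline.

**Quality filtering.** SNR is defined as the amide-I peak height
(1600–1700 cm⁻¹) over the SD of the linearly detrended residual in a
band-free window (1900–2100 cm⁻¹ for full-range grids, 980–1100 cm⁻¹
for fingerprint-only grids); the conventional cutoff is SNR ≥ 100. The
underlying acquisition protocol excludes "high scattering" pixels without
stating a criterion, so the package defines a scatter score as the EMSC
baseline-coefficient energy relative to the multiplicative coefficient
(`‖a‖₂/|b|`) and, by default, excludes the top 2% tail
(`scatter_quantile = 0.98`); an absolute cutoff can be supplied instead.
This is a documented stand-in, not an inferred protocol detail.

**EMSC.** Scatter correction fits each spectrum by ordinary least squares
to a reference spectrum plus Legendre polynomials `P₀..P_k` of the
wavenumber mapped to [−1, 1] (default order 2), and divides out the
multiplicative coefficient after subtracting the additive part. The
reference defaults to the mean of (quality-valid) pixel spectra. The
basis accepts extra columns — the hook for tabulated Mie extinction
curves — but none are shipped; iterative resonant-Mie EMSC is out of
scope. Degenerate fits (|b| ≤ 1e-8) are errors rather than silently
amplified spectra.

## Plaque detection and shape export

Whole-slide images are scored tile-wise (64 px tiles, 16 px overlap;
final row/column anchored flush to the image edge rather than padding, so
no synthetic border spectra enter the scorer) and reassembled by
per-pixel maximum. The scorer is an interface: any
`function(tile) -> [0,1] matrix` can be plugged in, which is where a
trained segmentation network would sit. The shipped reference scorer uses
the amide-I shift of beta-sheet-rich deposits — the ratio
`A1630/A1655` passed through a fixed linear ramp (0 below 0.58, 1 above
0.63). The ramp endpoints are constants derived from the synthetic band
model (background ratio ≈ 0.57, lesion ratio ≈ 0.68 at
`amide1630_scale = 1.5`, with ±3 SD noise margins at noise SD
0.005 AU); fixed constants keep tile scores comparable, which
data-dependent min–max scaling would break.

The morphology cascade follows the published order (drop < 100 µm²,
dilate 15 µm, fill holes, erode 10 µm, drop < 300 µm², shape criteria);
its net effect is a +5 µm cutting margin. Radii are converted to pixels
by rounding (minimum 1 px), so at a 4.25 µm pixel pitch the effective
margin is quantized (+2 px ≈ 8.5 µm); at 1 µm pixels it is exact.
Eccentricity/solidity cutoffs are not stated in the source protocol;
the defaults `max_eccentricity = 0.95`, `min_solidity = 0.7` keep
approximately round, compact objects and are recorded in `morph_params()`
output. Connected components and hole filling use EBImage's semantics
(`bwlabel`, `fillHull`). Solidity uses the discrete convex hull (pixels
whose centers fall inside the hull of the component's pixel corners),
which gives the textbook value 5/9 for a plus-sign of five pixels.

Object outlines are traced at the half-pixel iso-contour
(`grDevices::contourLines` at level 0.5); for rectangles this reproduces
the pixel-count area up to a 0.125 px² chamfer per convex corner. Pixel
centers live at `(i − 0.5)·pixel_size` with x = columns, y = rows, origin
top-left; stage coordinates are right-handed micrometres via a 4-parameter
Helmert transform fit by least squares (exact for two pairs). Components
touching the image border are excluded from export because their outline
is not closed on tissue. Detection performance properties
(precision/recall ≥ 0.9 on synthetic lesions) are evaluated on the
binarized activation mask, *before* the cascade: the +5 µm margin is a
deliberate over-cut for LMD tissue loss and would mechanically cap pixel
precision on small objects.

## Lipidomics pipeline

Shorthand names are parsed by summing carbons and double bonds over all
chain tokens, so chain-level (`PC 16:0/18:1`) and sum-composition
(`PC 34:1`) annotations agree. Two conventions deserve note:

* **Sphingolipid double bonds.** The sphingoid-base C=C is counted (so
  `SM 18:1;O2/18:0` contributes one double bond). The alternative — only
  N-acyl double bonds — is defensible; the choice is encoded in the chain
  tokens themselves and is therefore visible, not hidden.
* **Reporting bins.** Double bonds are reported in bins 0–7 and carbons
  in even bins 30–44. Species outside those ranges stay in the totals and
  appear under their observed bin value (no renormalization), so
  distributions always close to 100 mol%.

Lysophospholipids are excluded (single-chain species are not comparable
with two-chain sum compositions), as are bracketed isotope-labeled
standards. Group statistics use Welch's unequal-variance t-test in closed
form (so that noise-free synthetic compositions degrade to NA statistics
instead of failing), two-sided, with no multiple-testing adjustment —
matching the conventions of the underlying workflow. Plaque-vs-surrounding
comparisons are paired per case: mean ± SD of per-case differences,
which is what the error bars in the difference profiles show. PCA
standardizes each species to zero mean and unit SD (correlation-matrix
PCA via SVD), drops zero-variance species with a warning, and fixes signs
so each component's largest-magnitude loading is positive. The linear
separator is an SVM (`e1071`, linear kernel) with soft-margin cost 1 —
in the separable configurations this package produces, the cost is
rarely active. Correlation reporting flags pairs with |r| ≥ 0.6 and
p ≤ 0.05; the caption conventions in the printed source invert both
inequalities, which is not usable as printed, so the package implements
the evidently intended directions.

## The synthetic cohort generator

No tissue data are deposited for this workflow, so the package ships a
generator whose *defaults are the study conditions*: 8 AD cases with
paired plaque/surrounding samples and 8 controls.

**Calibration.** Per tissue group, target mol% distributions over
double-bond and carbon bins are fixed in
`default_group_bin_targets()`. The printed group means (saturated
lipids 11 ± 2%, unsaturated 88 ± 1% in plaques vs 91 ± 1% in
surrounding) and the printed paired effect (+1.6 ± 0.5 pp saturated)
cannot all hold as exact equalities; the default calibration resolves
this by setting plaque/surrounding unsaturated fractions to 88.6% /
90.2% — inside both printed ± ranges — which makes the paired effect
exactly +1.6 pp. The control saturated bin (10.6%) keeps plaques the
least-unsaturated group. Carbon targets hit mean chain lengths 37.02 C
(surrounding) and 36.76 C (plaque) exactly, with the C32 bin carrying
the largest paired increase (+1.9 pp) and C40 a small decrease (−0.5 pp)
consistent with its printed uncertainty. Unprinted bins are free
parameters chosen once to resemble human grey matter (abundant DB1,
DB4 and DB6 from oleoyl, arachidonoyl and docosahexaenoyl species;
sparse DB3/DB5).

**Joint structure.** A species panel (67 species across PC, ether PC,
PE, PS, PI, SM, Cer, HexCer) provides a seed joint distribution over
(carbon, double-bond) cells that encodes the real coupling between chain
length and saturation. Each group's joint table is obtained by iterative
proportional fitting of this seed to the group's two marginals, which
preserves the seed's dependence structure. The species-level anchor —
PC 32:0 up by +1.8 pp in plaques — is then enforced exactly by a
marginal-preserving 2 × 2 mass transfer on the (C32/C34 × DB0/DB1)
block; PC 32:0 is the sole species in the (32, 0) cell, so the species
difference equals the cell difference.

**Noise.** Logistic-normal at the cell level: each AD case draws one
perturbation shared by its two samples (`sigma_case = 0.12` on the log
scale) and each sample an independent one (`sigma_sample = 0.045`);
controls use twice the case scale, giving them the broad between-case
spread expected of whole-gray-matter sampling. These scales were set
a priori from the printed dispersions (group SD ≈ 1 pp on the saturated
bin, paired-difference SD ≈ 0.5 pp) via the delta approximation
`SD(bin) ≈ σ · sqrt(Σ mᵢ²)` over the bin's cells. At
`noise_sd_scale = 0` every sample reproduces its group targets to
machine precision, which is what the exactness tests use.

**What is and is not emulated.** The generator reproduces compositional
structure, paired case effects and group dispersions. It does not emulate
ion suppression, isotope-overlap correction, extraction chemistry, class-
specific response factors, or within-cell species correlations beyond the
shared cell mass — so passing tests demonstrate the *pipeline's*
correctness on realistic compositions, not robustness to raw-MS
artifacts. Likewise the IR scene generator uses Gaussian bands, a
sinusoid-plus-slope stand-in for Mie ripple (not a physical scattering
model), and i.i.d. noise; it supports testing band mathematics and
detection geometry, not instrument-level effects such as water vapour or
detector nonlinearity.

## Numerical choices and problem sizes

* Wavenumber grids are stored ascending; descending file order is
  remembered and restored on write. Cubes are exchanged as multi-frame
  32-bit TIFF plus a JSON sidecar (wavenumbers, pixel size, affine
  intensity encoding), giving ~1e-7 relative round-trip accuracy.
* Otsu's threshold uses 256 uniform bins over the observed range and
  returns a bin edge; the foreground convention is `values >= threshold`.
* IPF iterates to a margin error below 1e-10 (cap 5000 iterations) and
  fails loudly if the seed support cannot carry the requested margins.
* The test suite and the acceptance script run on deliberately compact
  problem sizes — 96 × 96 px QCL scenes, 24-sample cohorts, 20-seed
  Monte-Carlo loops, 10⁴ Welch null replicates — chosen so the full
  suite completes in a few minutes on one core while keeping every
  statistical check's Monte-Carlo error well inside its assertion margin.

## Known limitations

* The unsaturation index requires the 3012 cm⁻¹ band and therefore
  full-range (FTIR) spectra; fingerprint-only QCL grids raise an error
  rather than silently returning noise.
* The reference tile scorer is calibrated to the synthetic band model; on
  real QCL data it is a placeholder for a trained model, not a validated
  detector.
* The paired analysis assumes one plaque and one surrounding sample per
  case; unpaired cases are dropped with a warning rather than modelled.
* Band-height measurement assumes locally linear baselines between the
  anchor windows; strongly curved residual baselines (under-corrected
  scatter) bias the index, which is why quality filtering precedes
  mapping.
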