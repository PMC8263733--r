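---
title: "Methods: FTIR band analysis for dry biomolecule preservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTIR band analysis for dry biomolecule preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryspec)
```

## The problem

Dry (anhydrobiotic) preservation embeds cells or biomolecules in a sugar
glass instead of freezing them. Whether the preservation worked is visible in
the infrared: DNA changes conformation when water is removed, sugar matrices
are glassy or liquid depending on how hydrogen bonding responds to
temperature, and storage damage slowly reshapes the fingerprint region of the
spectrum. `dryspec` implements the complete analysis chain for these three
questions, plus the small gravimetric and image assays that accompany a
drying experiment, and — because no public spectra accompany this kind of
experiment — a synthetic-spectrum generator that serves as ground truth for
every stage.

## Spectral model

A measured FTIR absorbance spectrum is modelled as a sum of component bands

$$A(\nu) = \sum_i a_i \exp\!\left(-4\ln 2\,\frac{(\nu - c_i)^2}{w_i^2}\right)$$

(Gaussian by default; a Lorentzian option exists), where $c_i$ is the band
center (cm⁻¹), $w_i$ the FWHM and $a_i$ the peak absorbance. Band *positions*
in the generator are literature assignments:

| band | hydrated (B-form) | dried (A-form) |
|------|------------------|----------------|
| νC–C backbone | 970 | 965 |
| νC–O deoxyribose | 1052 | 1050 |
| νPO₂⁻ sym | 1089 | 1089 |
| νPO₂⁻ asym | 1225 | 1235 |

RNA carries ribose-ring bands at 993 and 1125 cm⁻¹; dried trehalose has five
bands inside 960–1170 cm⁻¹; albumin contributes amide I (~1650) and amide II
(~1550). Widths and amplitudes are **not** reported by any source — they are
simulator choices (FWHM 15–30 cm⁻¹ in the fingerprint region) constrained by
an enforced invariant: on the canonical 1 cm⁻¹ grid the second-derivative
minimum of each *composite* preset spectrum must fall within 1 cm⁻¹ of every
planted center. The test suite verifies this for every shipped preset.

Hydration morphs the DNA marker centers linearly between the two endpoint
columns; the paper-level observation that the symmetric phosphate band gains
intensity on drying is modelled as $a_{sym} \times (1 + k(1-h))$ with $k =
0.5$ by default ($k$ is a free simulator parameter; no printed value
constrains it). Noise is additive iid Gaussian and a seed is mandatory
whenever it is requested; heteroscedastic detector noise is out of scope.

## Preprocessing

Analysis operates on the fingerprint region (900–1500 cm⁻¹), resampled to a
uniform 1 cm⁻¹ grid by linear interpolation (band shapes are smooth; linear
interpolation cannot ring), vector-normalized to unit Euclidean norm, then
differentiated twice with a Savitzky–Golay filter (21-point window, order 3).
Decisions worth knowing:

* **Order of operations.** "Normalized second-derivative spectra" is read as
  *normalize, then differentiate*; the reverse path is available via
  `fingerprint_d2(..., normalize_after = TRUE)`. Both commute with positive
  scaling of the input, so the choice does not affect band positions, only
  the absolute derivative scale.
* **Polynomial order.** Unstated in the source methods; default 3 (order 2
  yields identical second derivatives on symmetric bands; 3 tracks asymmetric
  shapes better). Exposed in `pipeline_config()`.
* **Units.** The derivative is divided by the squared grid step once, so
  values are per cm² and intensity *ratios* are step-invariant.
* **Edges.** The half-window at each end is returned as `NA` and excluded
  from peak searches. Padding would fabricate curvature at region borders.

## Markers, ratio, conformational call

Bands are local minima of the second derivative with a prominence of at
least 2% of the region's maximum |d²A/dν²| (suppresses noise wiggles at the
tested noise levels). Each of four search windows — 950–985, 1040–1065,
1075–1100, 1200–1260 cm⁻¹, chosen to bracket both endpoint positions with
margin — contributes its most intense band (ties: larger prominence, then
lower wavenumber; fully deterministic). The conformational statistic is
I(νPO₂⁻asym)/I(νPO₂⁻sym) with intensities |d²A/dν²| at the window minima; a
fixed-position lookup variant was considered and rejected as the default
because the window-minimum convention is robust to the 1225↔1235 shift
itself. The B/A call is a majority vote of the three shifting markers by
nearest endpoint, with 1228–1230 cm⁻¹ left unassigned to avoid knife-edge
calls; fewer than two usable markers is `indeterminate`, not an error.

## νOH position and the WTC

The OH-stretch position is the mean of the two outermost wavenumbers where
absorbance crosses 80% of the full peak height in 3000–3700 cm⁻¹ (linear
interpolation between bracketing grid points). "Full height" is measured
from zero: inputs are assumed baseline-corrected, and a linear-baseline
toggle exists for real data. Note that adding a constant offset *does* move
the crossings of an asymmetric band under this definition — only symmetric
bands are offset-invariant — which is why the toggle exists.

The wavenumber temperature coefficient (WTC) is the OLS slope of position on
temperature over 25–50 °C, endpoints inclusive (6 points at the conventional
5 °C interval). Liquids show large WTC; vitrified matrices show small WTC
because the glass arrests the thermal expansion of hydrogen bonds. The
shipped OH presets (water 3400 cm⁻¹ / 0.50 cm⁻¹ °C⁻¹, liquid sugar matrix
3370 / 0.40, dried glass 3300 / 0.12) are package choices that reproduce the
qualitative ordering — position and WTC both decreasing from water to glass —
since no numeric values are printed for them; the generator round-trip tests
recover whatever slope is planted, which is the property that matters.

## PCA drift monitoring

Storage monitoring uses covariance-matrix PCA (mean-centered, *not*
correlation-scaled) of vector-normalized original fingerprint spectra —
second derivatives are deliberately not fed to PCA. Loading signs are fixed
(largest-magnitude element positive) so results are deterministic. The drift
summary expresses the distance between two groups' score centroids in units
of the pooled within-group standard deviation, per PC; "clustered together"
means every requested PC is below the threshold (default 1 pooled SD — an
artifact-defined operationalization of what the source assesses visually).
The published variance percentages (69/28/1.8%) derive from real instrument
spectra and are intentionally not targets; the synthetic tests assert
separation (> 1 SD) for degraded-vs-baseline sets and non-separation for
identity images of the same replicates.

On that last point: a noise-only *resampled* split of ~12 replicate spectra
exceeds 1 pooled SD on some of PC1–3 with roughly 30% probability under iid
noise (the per-PC distance behaves like 0.58|t|), so "noise-only replicates
cluster" is only a deterministic property in its identity reading —
`degrade(severity = 0)` is exactly the identity — and that is what the test
asserts.

## Dry assays

* Water content: $(w_{dry} - w_{bake}) / (w_{bake} - w_{slide})$ g/g.
* Drying endpoint: earliest time where the slide-subtracted weight changes by
  < 0.5% (relative) across 3 consecutive readings; both parameters exposed,
  since the stability criterion behind "stable state" is not stated anywhere.
  "Not reached" is a value (`NA`), not an error.
* Molarity: 10 × %(w/v) / M mol/L; full precision, rounding only at
  presentation. 1.71% at 342.30 g/mol → 49.96 ≈ 50 mM. (At 180.16 g/mol the
  same w/v is 94.9 mM — the often-quoted "100 mM" is a round-up.)
* Formazan index: `background − mean(grey)`, clipped at 0, over all pixels or
  a mask — the inversion is explicit so the index *increases* with blue/purple
  formazan coloration. Images are 8-bit matrices; ASCII PGM (P2) is the only
  file format parsed, keeping the package free of binary I/O; convert RGB
  micrographs with Rec. 601 luma weights upstream.

## What a green test does and does not establish

The generator produces smooth, baseline-free, additively-noisy sums of
analytic bands on an exact grid. Real ATR-FTIR spectra carry baselines,
scatter artifacts, water-vapour residuals, ATR penetration-depth dispersion
and band-shape asymmetries none of which are modelled (deliberately:
out-of-scope atmospheric compensation is assumed already applied by the
instrument). A green marker-recovery test therefore establishes that the
*analysis chain* is correct — normalization, differentiation, detection,
window logic, voting — not that the thresholds are validated against
instrument data. The same applies to the PCA drift flag: the 1-SD threshold
is a QC convention, not a calibrated decision boundary.

## Numerical choices

Linear interpolation everywhere a grid is changed; no extrapolation ever
(errors instead). CSV serialization at 17 significant digits so write→read
round trips are bit-for-bit. SG filters validate window parity and length.
Degenerate inputs (zero-norm region, all-zero weights, empty mask, clipped
νOH flanks, < 3 PCA spectra, < 3 WTC points) raise early, named errors.
Seeds: every stochastic generator requires an explicit seed and restores the
caller's RNG state, so library use never perturbs a user's session RNG.
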