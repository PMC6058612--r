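---
title: "Methods: dual-isotope lung targeting from MSI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-isotope lung targeting from MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungtarget)
```

This vignette is the package's own account of its methods: the model behind
each pipeline stage, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical choices a maintainer would want written down.

## 1. The measurement model

An MSI dataset is a set of pixels on an integer grid, each carrying a mass
spectrum. We model the per-pixel, per-channel intensity as

> true regional mean × biological pixel effect × counting noise × per-pixel
> acquisition drift,

where the drift multiplies *every* peak of a pixel equally. That last
property is what total-ion-count (TIC) normalization exploits: rescaling
each pixel's spectrum to a common total removes the drift term exactly and
only the drift term. `tic_normalize()` therefore:

* rescales every retained pixel to a common target — by default the mean
  raw TIC of the dataset, which keeps the global intensity scale
  interpretable for display; a fixed numeric target (e.g. 1) is available
  and is what the algebraic cancellation tests use, because the mean-TIC
  target of a drifted dataset differs from that of its drift-free
  counterpart;
* drops pixels with zero TIC (they carry no spectral information; the count
  is reported in the metadata rather than imputed);
* conserves within-pixel peak proportions to machine precision, and is
  idempotent.

Ion images are extracted as the sum of intensities in a closed m/z window.
Windows default to ±0.1 Da, a TOF-like tolerance; ppm mode is available for
Orbitrap-like data. The bundled analyte table uses the salmeterol
protonated molecule at m/z 416.1; the d3-salmeterol mass defaults to
416.1 + 3 × 1.00628 Da (three ²H–¹H substitutions) and the marker masses
(Heme b 616.177, PC(32:0) 734.569, PC(36:4) 782.569) are monoisotopic
assumptions — all overridable via `analyte()` or a CSV/YAML table, since a
real study would use instrument-measured exact masses. Only the
disjointness of the windows matters to any downstream statistic.

An acquired pixel whose window is empty scores 0; a grid cell that was
never acquired is missing (`NA`). Statistics consume only masked, acquired
pixels — restricting "whole lung" quantities to tissue is always explicit,
via `compute_tissue_mask()`.

## 2. Tissue masking

`tic_threshold` marks pixels whose raw TIC exceeds a quantile of the TIC
distribution (default 0.45). The default assumes the section occupies
roughly half the field of view, so the threshold falls in the wide TIC gap
between off-tissue pixels (matrix-cluster ions only) and tissue; on the
default phantom, whose off-tissue fraction is ≈45%, the resulting mask
overlaps the ground-truth tissue with Jaccard ≈0.98. For fields of view
with very different tissue fractions the quantile should be set
accordingly, or `marker_union` used (pixels where any structural marker
exceeds its own quantile).

## 3. Segmentation

Pixels are clustered on their TIC-normalized, binned spectra (0.5 Da bins,
empty bins dropped) under the correlation distance 1 − Pearson(u, v) — the
parameterization colloquially called "distance correlation" in commercial
MSI software. Székely's distance-correlation statistic is a different
quantity; `correlation_distance(..., method = "szekely")` provides it for
comparison, but the clustering always uses the Pearson form. A vector with
zero variance is uninformative and is assigned distance 1 to everything.

**Weak denoising.** Before clustering, each spectral channel is smoothed
with a Gaussian of σ = 1 px, the mildest standard choice consistent with
"weak". The convolution is masked and renormalized: off-mask pixels
contribute nothing and the kernel weights are rescaled over the mask, so
edges are not darkened. Two consequences worth recording:

* the smoothing is applied *separately* inside and outside the tissue mask.
  Smoothing across the section boundary blends tissue and off-tissue
  spectra into a coherent intermediate class several thousand pixels
  strong, which then absorbs bisections that should separate real tissue
  classes. Splitting the domains removes the artifact entirely;
* mass conservation of the renormalized kernel is exact only away from mask
  borders (the kernel is truncated at 4σ and the per-pixel weights vary
  near edges); the tests assert conservation to 1e−6 in the interior and
  1e−3 against a mask edge.

**Bisecting k-means.** Top-down: all on-mask pixels start in one segment;
k − 1 times, the segment with the largest within-segment sum of correlation
distances to its mean-vector centroid is split by 2-means under correlation
distance (ties: larger pixel count, then lower label). The centroid is the
plain mean of member vectors. The first 2-means restart is initialized
deterministically (farthest point from the segment centroid, then farthest
point from that), which makes the partition permutation-invariant on
separable data; additional restarts (default 5) use seeded random pairs and
the best final objective wins. Empty clusters are re-seeded at the farthest
point; iteration caps at 100; a segment whose rows are all identical is
unsplittable and is skipped (stopping early, with a warning and
`k_actual < k`, if nothing is splittable). On micro-instances the split
objective equals the exhaustive minimum over all bipartitions; on the
default phantom the six-segment map matches the ground-truth compartments
with adjusted Rand index ≈0.98.

k defaults to 6 for the lung phantom — three quantified tissue compartments
plus lumen, vessel, and off-tissue background. The source experiments do
not state their k or denoising strength; these defaults are this package's
choices, not reproductions.

**ROI naming.** Segments become named compartments by marker enrichment
ranking: highest mean PC(32:0) → alveolar; among the rest, the
highest-PC(36:4) segment that is ring-shaped → epithelium; the segment
adjacent to the epithelium with the next-highest PC(36:4) →
sub-epithelium; highest Heme b → vessel; lowest TIC → lumen-or-background;
leftovers unassigned. The ring criterion (boundary²/area ≥ 30; a filled
disk scores ≈4π ≈ 12.6) is only a tie-break for the epithelium — an
adversarial phantom with swapped markers is named by markers, not shape.

## 4. The targeting factor

For compartment *c*, route means are taken over the ROI on TIC-normalized
channels, each normalized by its route's plasma concentration, and ratioed:

TF*₍c₎* = (*Ī*₍inh,c₎ / *C*₍inh₎) / (*Ī*₍IV,c₎ / *C*₍IV₎).

Both channels come from the same dual-dosed section, so every pixel weight
cancels between numerator and denominator; the factor is exactly invariant
to common intensity rescaling, and scales inversely with one route's plasma
value (both properties are tested algebraically). Replicates are aggregated
per-replicate-then-mean by default, preserving biological variance; pooled
pixel aggregation is available. The section-level factor uses the whole
tissue mask, not the union of the three ROIs. No ionization response
correction is applied between the isotopologues by default
(`response_factor = 1`), matching standard practice for deuterated pairs.

One estimator caution that shaped the synthetic defaults: after TIC
normalization, a channel that contributes a large, noisy share of its own
pixel's TIC is biased low (pixels where the channel fires high are exactly
the pixels scaled down hardest). With the drug channels at a trace share of
TIC (a few percent, as for a real dosed xenobiotic among structural
lipids), the bias is negligible; it is why the generator's drug intensities
are an order of magnitude below the lipid markers.

## 5. The synthetic lung

`lung_scenario()` defines a 200 × 200 px pseudo-section at 10 µm (2 × 2
mm): an elliptical parenchyma occupying ≈55% of the field, six circular
airways (lumen radius 6–12 px with 3 px epithelium and 4 px sub-epithelium
rings — 30/40 µm layers around 60–120 µm lumens, rat-bronchiole scale),
five vessels, and 5% alveolar porosity punched as 1–2 px blobs (airspaces,
not isolated pixels — isolated holes plus smoothing would manufacture a
spurious "hole boundary" spectral class no real section has).

Channels: the two drug isotopologues, three structural markers in their
home compartments, two matrix-cluster ions (strongest off tissue, as
crystallized matrix is), and a uniform baseline ion. Lumens carry a weak
PC(36:4) bleed (analyte delocalization) and baseline. The per-compartment
IV-drug means are design inputs; the inhaled means are *derived* from the
requested ground-truth targeting factors (5 / 31 / 45 for alveolar /
sub-epithelium / epithelium) and the plasma concentrations, so truth is
internally consistent by construction and parameter recovery is well posed.
Plasma values (inhaled 1.2, IV 12, arbitrary nmol/L) are inventions — the
source experiments do not publish theirs — sized so the IV bolus gives
ten-fold higher plasma than nebulization.

Noise, in order: a mean-one log-normal per-airway deposition multiplier on
the inhaled drug (σ = 0.5; inhaled deposition is patchy per airway),
mean-one log-normal pixel effects (σ = 0.9 inhaled, 0.3 IV, 0.2 others),
Poisson counting noise on scaled counts (2 counts per intensity unit), then
mean-one log-normal TIC drift (σ = 0.25) on all peaks. Mean-one
multipliers keep ROI means and targeting factors unbiased; the ordering
puts drift last so TIC normalization removes exactly and only the drift.
The resulting pixel-RSD contrast (inhaled ≈120–140% vs IV ≈50%) reproduces
the qualitative heterogeneity gap of real inhaled-versus-IV sections,
scaled down in magnitude.

What the generator does **not** emulate: branching airway trees, realistic
isotope envelopes and adduct chemistry, mass-dependent resolution,
section-to-section thickness variation, or co-registration error against
histology. Passing tests therefore demonstrate the pipeline's correctness
and statistical behavior under a faithful noise structure — not performance
on any particular instrument's data.

## 6. Problem sizes and determinism

The validation suite runs the default 200 × 200 phantom for the
segmentation-accuracy (10 seeds), targeting-recovery (10 seeds × 3
replicate sections, median relative error ≤ 15% per compartment),
regional-ordering (40 single-section pipeline runs), heterogeneity-direction
(20 seeds) and correlation-structure (40 seeds) checks; unit tests use
40–80 px sections. A full single-section pipeline takes ~1–2 s on one CPU.
Everything stochastic is seeded: geometry and noise generation restore the
caller's RNG state, the clustering is deterministic given its seed, and
`run_pipeline()` outputs are byte-identical across reruns with the same
configuration and seed (the manifest hashes the configuration minus its
output location).

## 7. Known limitations

* ROI naming assumes the marker panel's home compartments; tissues where
  PC(32:0)/PC(36:4) enrichment is atypical need a custom panel.
* The epithelium/sub-epithelium boundary is 1–2 px wide at 10 µm; cluster
  assignment of boundary pixels dilutes the epithelium factor by a few
  percent toward the sub-epithelial value (visible as recovered factors
  ≈42 vs a true 45 on phantom averages).
* The pixel-to-pixel RSD is reported on TIC-normalized intensities within
  the tissue mask; computing it on raw intensities (flag available)
  conflates drift with biology, and including off-tissue zeros would
  inflate it arbitrarily.
* Correlation tables apply no multiple-testing control, matching the
  descriptive use they serve here.
* 2-D sections only; no 3-D reconstruction, no vendor raw formats
  (imzML + ibd is the interchange point), no peak picking or mass
  recalibration.
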