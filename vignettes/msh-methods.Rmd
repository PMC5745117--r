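---
title: "Multimodal spectral histopathology: models, parameters and design choices"
author: "RamanMSH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal spectral histopathology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanMSH)
```

## The problem

During Mohs micrographic surgery for basal cell carcinoma (BCC), the surgeon
needs to know whether the surface of the freshly excised tissue layer still
carries tumour. Multimodal spectral histopathology (MSH) answers this without
frozen-section histology: a wide-field auto-fluorescence (AF) image of the
resection surface decides *where* to measure — tumour is darker than the
collagen-rich stroma — and Raman micro-spectroscopy at a few hundred selected
points decides *what* each location is. A final counting rule converts the
per-pixel tissue map into a binary per-sample call.

This package implements the complete computational chain on seeded synthetic
data: phantom AF images, class-specific synthetic Raman spectra, adaptive
segmentation, selective sampling, spectral classification, the two-round
segment diagnosis, and the exact binomial decision model.

## AF segmentation

The raw AF image is first separated from the dark background with a set
intensity threshold (`tissueMask()`, default 200 a.u. for the phantoms) and
flattened by dividing by a Gaussian-blurred copy of itself, rescaled to keep
the mean (`flattenImage()`, sigma defaulting to a tenth of the image width).
Division rather than subtraction makes the correction exact for
multiplicative illumination and stitching gradients. The pipeline masks the
tissue *before* flattening: the flattening rescale maps the ratio image back
to the tissue's mean intensity, which would lift far-from-tissue background
(where the ratio is close to 1) to tissue-level values and destroy the
background threshold if applied first.

Segments are 8-connected components of *below*-threshold pixels inside the
tissue mask — tumour is dark, and the area fraction in the objective below is
only meaningful when segments capture part of the tissue. Components smaller
than a 60 µm disc (`defaultMinSegmentArea()`) are discarded as noise specks;
connectivity and the minimum area are configurable.

The segmentation threshold is chosen per image by sweeping 256 evenly spaced
levels between the masked minimum and maximum and maximising one of two
objectives (`optimizeThreshold()`):

* `f_A = N`, the segment count, and
* `f_B = N * A`, segment count times the captured area fraction.

Both have a global maximum in the interior of the sweep; ties are broken
toward the lowest threshold (the most conservative segmentation). The
pipeline uses `f_B`, which captures more area and therefore more of the
tumour; the package also computes the two quality metrics used to compare
the objectives against an annotation: `rho`, the fraction of annotated
tumour inside segments, and `epsilon`, the fraction of healthy tissue inside
a segment (healthy means annotated non-BCC *tissue*; background is
excluded — the package's reading of an ambiguity in how the metric treats
non-tissue pixels).

## Sampling-point allocation and placement

A total budget of `nTotal = 800` points is allocated with a minimum of
`nMin = 5` per segment; the remainder is shared proportionally to
`Var(i) * Area(i)`, the intensity variance times area of each segment, so
large heterogeneous segments — the ones most likely to hide tumour — are
sampled densely. Variance is computed on the flattened image, the same image
the segmentation sees. Fractional shares are integerised by the
largest-remainder method, which preserves the total exactly; if the minima
alone exceed the budget, segments receive their minimum in decreasing-area
order until the budget runs out (a case flagged with a warning). All-zero
weights fall back to a uniform share, also flagged.

Within a segment, "uniform" placement (Config 2, the default) is realised as
farthest-point sampling started at the pixel nearest the centroid:
deterministic, evenly spread, and never closer than one pixel to an excluded
(already measured) location. A pure-random mode exists for Monte-Carlo
properties. Config 1 pins the first two points at the intensity minimum and
maximum of the segment (ties toward the lowest row-major pixel) and spreads
the rest the same way. Plans are scored by the tumour *hit rate* (points on
BCC among points in BCC-bearing segments) and by the number of BCC-bearing
segments left without a single tumour hit.

## Raman preprocessing and features

Spectra live on the standard 400–1800 cm⁻¹ grid at 2 cm⁻¹ spacing
(701 points); arbitrary input axes are linearly interpolated onto it.
Narrow cosmic-ray spikes (runs of at most 2 points more than 5 MADs above a
7-point running median — detector parameters of this package's own choosing)
are replaced by the median-filtered value. The SNR statistic is the height
of the CH₂ band, taken as the *maximum* over 1450 ± 20 cm⁻¹ above the local
linear baseline through the window endpoints, divided by the RMS residual of
a linear fit over the empty 1750–1800 cm⁻¹ region; detrending makes the
statistic invariant under affine intensity transforms. Three SNR regimes
are preset in `mshConfig()`: training (strictly above 15), validation
(at least 7, with 20 points per segment and a 1200-spectrum cap) and
diagnosis (at least 4).

Features are the areas of 13 bands (675, 680, 786, 870, 906, 944, 952,
1092, 1144, 1298, 1376, 1528, 1744 cm⁻¹) after subtracting, per band, the
straight line through the window's endpoint intensities; windows are
centre ± 8 cm⁻¹ except the adjacent 675/680 pair, which uses ± 3 cm⁻¹ to
stay disjoint (half-widths are not fixed by the method description and are
configuration here). The area vector is normalised to unit Euclidean norm
(L1 is available as an option), making features invariant to intensity
scale and offset. Optionally, spectra are denoised before classification by
projection onto the top 50 principal components of an independent basis
set.

## Tissue classification

The classifier is a single-hidden-layer neural network (20 hidden nodes,
softmax outputs) over the 13 features, fitted with `nnet` under a fixed
seed, light weight decay (1e-3) and inverse-frequency class weights — the
optimiser, regularisation and imbalance handling are unspecified in the
method description and are this package's choices, all exposed as
arguments. The five classes are BCC, dermis, fat, dye and EMI (epidermis,
muscle and inflammation merged, because their spectra are mutually
similar). Class assignment is the probability argmax. Performance is
estimated by 5-fold cross-validation grouped by patient identifier, so no
patient contributes to both training and test folds. `kmeansAnnotationMap()`
provides the k-means cluster image used to annotate raster scans against
histology.

## Two-round segment diagnosis

Each segment is diagnosed independently (`diagnoseSegmentRound1()`):

1. spectra with SNR below 4 are discarded; if *more than* 80 % were
   discarded the segment is `Unclassified` and takes no further part;
2. retained spectra are (optionally PCA-denoised and) classified;
3. no BCC and a single class: the segment takes that label; no BCC and
   several classes: the segment is split by nearest-neighbour assignment of
   every pixel to its closest sampling point;
4. exactly one BCC spectrum is ignored and the previous rules reapply;
5. more than 80 % BCC labels the segment BCC outright; otherwise (at least
   two BCC spectra but at most 80 %) a second round runs.

Both 80 % rules are strict: 4 BCC out of 5 spectra is exactly 80 % and
triggers the second round rather than a whole-segment label — the literal
reading, and the one that makes the decision model's "at least two spectra"
simplification coherent for five-point segments. The second round
(`runRound2()`) places an equal number of new points avoiding round-1
locations, filters them by the same SNR rule, joins both rounds' retained
spectra, classifies, and *always* finalises by nearest-neighbour splitting —
the whole-segment BCC shortcut belongs to round 1 only, following the
procedure's statement that the split is the final labelling. A segment left
with no retained labelled points becomes `Unclassified`.

`assembleDiagnosis()` paints every diagnosed segment into the tissue map and
counts `N_BCC`, the number of 8-connected BCC regions in the *final* image —
so a split segment can contribute several small BCC detections, consistent
with the observation that second-round splitting can create additional small
positive regions. `sampleDecision()` calls the sample BCC-positive when
`N_BCC >= nTh`, with `nTh = 8` as the default operating threshold (the
revised value; 5 was the original proposal).

## The binomial decision model

With hit rate $h$, per-spectrum sensitivity $se$ and specificity $sp$, a
spectrum measured in a tumour-bearing segment is called BCC with probability

$$p = h \cdot se + (1-h)(1-sp).$$

Simplifying the two-round rule to "a segment is BCC iff at least $m = 2$ of
its $n = 5$ spectra are BCC", the per-segment sensitivity is
$P(\mathrm{Bin}(n,p) \ge m)$ and the per-segment specificity is
$1 - P(\mathrm{Bin}(n, 1-sp) \ge m)$. At the reference operating point
($h = 0.6$, $se = 81.8\%$, $sp = 96.3\%$) these give 81.94 % and 98.73 %.
With $T \sim \mathrm{Bin}(N_{BCC}, \text{seg. sens.})$ true detections and
$F \sim \mathrm{Bin}(150, 1 - \text{seg. spec.})$ false alarms assumed
independent, the per-sample sensitivity $P(T + F \ge N_{th})$ is computed by
exact convolution over $T$ (no Poisson approximation — the printed digits
require it) and the specificity is $P(F < N_{th})$. The probability of a
positive call built entirely on false alarms is $P(T=0) P(F \ge N_{th})$.
`monteCarloCheck()` validates the closed forms by simulating per-spectrum
Bernoulli outcomes through the segment and sample rules. The 10-BCC-segment
configuration together with 150 non-BCC segments is also the configuration
under which the $N_{th} = 8$ operating point (92.93 % / 99.93 %) is
computed. The model deliberately ignores inter-segment correlation, which
its source flags as a simplifying assumption.

## What the synthetic data emulate — and what they do not

`generatePhantom()` builds a stroma disc (mean 1000 a.u.) on dark background
(50 a.u.) with a multiplicative Gaussian texture smoothed at a ~5 pixel
scale (SD 80 a.u.), darker tumour blobs (mean 600 a.u.) shaped as unions of
overlapping discs ("micronodular") or thickened random-walk strands
("infiltrative"), and a dye arc along part of the boundary. The default
geometry is 512 × 512 pixels at 40 µm/pixel, a 2 cm × 2 cm field. Blobs are
placed with pairwise separation so the annotation has exactly the requested
number of connected BCC components; default radii are 150–500 µm. No
published pixel size or intensity statistics exist for the source images,
so all phantom parameters are free choices documented here.

Each blob is surrounded by a thin (2 px) smooth rim slightly brighter than
the stroma mean, emulating the condensed, collagen-rich peritumoral stroma
reaction around BCC nests (collagen dominates tissue AF, so condensed stroma
reads bright). This rim is load-bearing for the phantom's behaviour: the
`f_B` objective peaks near the percolation onset of any stationary texture
field, and without a locally contrasted boundary a tumour blob joins a
near-critical texture patch or not on a per-seed coin flip, which no texture
amplitude or correlation scale avoids. Real AF images resolve this with
genuine tissue structure; the rim is the phantom's stylised stand-in, and
`rimWidthPx = 0` switches it off for studying the un-rimmed regime.

Synthetic spectra are Gaussian bands on a linear baseline plus white noise.
Band positions follow the class-characteristic features (BCC: 788 and
1098 cm⁻¹ DNA bands; dermis: collagen near 851/950 cm⁻¹ and amide III; dye:
680, 748, 1144, 1528 cm⁻¹; CH₂ at ~1450 cm⁻¹ in every tissue class);
heights and widths are stylised to make the classes separable through the
13 features with realistic ordering of difficulty (dermis and EMI closest).
The noise scale is calibrated with a fixed-seed probe so the *measured* SNR
statistic matches the requested target in expectation — the naive
height/target scaling reads several percent high because the windowed
maximum picks up positive noise excursions. For dye, which has no CH₂ band,
the noise scale is referenced to the tallest dye band instead.

Consequences worth stating plainly: the phantoms make tumour segments purer
and the hit rate higher than the published clinical medians (hit rate ~1
versus ~0.6), so passing end-to-end tests demonstrates the correctness of
the computational chain under favourable, controlled contrast — not
clinical-grade performance. The published clinical confusion matrices are
not reproducible without the clinical spectra, and nothing here attempts
them. Lineshape physics (Lorentzian/Voigt profiles, fluorescence baselines,
detector etaloning) and optics (PSF, vignetting, tile stitching) are out of
scope.

## Numerical choices and degenerate inputs

Problem sizes used by the test suite and kept deliberately desk-scale:
spectral libraries of 60–120 spectra per class, 50-seed end-to-end phantom
batches, 10⁶-draw Monte-Carlo validation of the decision model, and
100-phantom placement comparisons. Other choices:

* connected components via a compiled union-find labeller (4- or
  8-connectivity; 8 is the default everywhere), verified in the tests
  against a pure-R flood fill;
* threshold ties at objective maxima resolve to the lowest grid value;
  nearest-neighbour ties to the lowest point index; intensity-extrema ties
  to the lowest row-major pixel;
* an empty segmentation is a valid result (k = 0) and yields `N_BCC = 0`,
  hence BCC-negative;
* a constant image is rejected by `optimizeThreshold()`; an all-zero image
  by `flattenImage()`; sub-pixel blur sigmas are rejected;
* binomial tails come from `pbinom`/`dbinom`, which are numerically stable
  for the n = 150, small-p regime the model needs;
* every stochastic routine takes an explicit integer seed and is a pure
  function of its inputs; `withr::with_seed` keeps the global RNG state
  untouched.

## Known limitations

The phantom is a geometric cartoon: no optics, no real stromal
heterogeneity, a single tissue-disc shape, and a rim device standing in for
real peritumoral contrast. The spectral models are five fixed band sets, so
classifier results quantify the pipeline, not spectroscopic reality. The
decision model inherits its independence assumptions. The validation-mode
preset changes budgets and thresholds but the package does not model
instrument acquisition times.
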