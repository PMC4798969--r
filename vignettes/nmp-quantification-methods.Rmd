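---
title: "Counting Sox2/T double-positive progenitors in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting Sox2/T double-positive progenitors in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmpquant)
```

## The problem

Neuromesodermal progenitors (NMPs) of the caudal mouse embryo are
operationally identified as nuclei co-expressing the neural factor Sox2 and
the mesodermal factor T (Brachyury). Counting them in wholemount confocal
stacks requires a chain of image-analysis steps, each of which can bias the
final count: nuclear instance segmentation of the DAPI counterstain,
per-nucleus intensity measurement in the Sox2 and T channels, a positivity
threshold for each marker, and per-embryo statistics across developmental
stages. `nmpquant` implements this chain as a reusable, fully testable
pipeline. Because the original image data are not publicly deposited, the
package ships a ground-truthed synthetic stack generator, so every stage can
be validated by parameter recovery rather than by eye.

## The synthetic embryo generator

`embryo_model()` describes a 3-channel 8-bit stack (DAPI, Sox2, T; arbitrary
units, AU, 0–255) of ellipsoidal nuclei at tissue density. What it emulates:

* **Population structure.** Each nucleus belongs to one of four classes —
  Sox2+T+ double positive, Sox2-only, T-only, or double negative — drawn
  multinomially from `class_proportions` (or fixed exactly via
  `class_counts`, which is how stage series realise a configured fold
  change in ground truth before any pipeline error).
* **Spatial structure.** The rostrocaudal axis is x. Sox2-only nuclei are
  placed rostrally, T-only caudally, double positives in the bridging
  domain, negatives anywhere; an optional T-bright ventral-caudal stripe
  stands in for the notochord. Channel intensities are modulated by
  opposing rostrocaudal gradients (Sox2 declining caudally, T rostrally).
* **Acquisition artefacts.** Additive Gaussian voxel noise (default s.d.
  5 AU) and multiplicative depth attenuation (default 0.3% per z slice),
  the artefact that motivates Welch-corrected comparisons between stacks
  acquired at different depths.

Each nucleus carries a single per-channel mean drawn from a truncated
normal (one draw per nucleus, uniform within the nucleus before
noise/attenuation), so recorded ground-truth means are exact; with noise
and attenuation off, means recomputed from the image agree with ground
truth to within the 0.5 AU quantisation bound, and this is asserted in the
test suite.

Default conditions: a 48 × 160 × 160 voxel stack with 500 nuclei of
semi-axes 3–6 voxels (roughly 20% foreground density), class proportions
(0.30, 0.25, 0.25, 0.20), double positives at (20, 18) AU, single
positives at 25 AU in their own marker, negatives at ~2 AU, spreads 1–3
AU. No voxel calibration for the reference imaging exists, so these are
the package's own choices of a realistic regime: marker separations of
about 8 spread-units, tissue-like packing, noise well below the
signal. What the generator does **not** model — PSF blur and deconvolution
residues, anisotropic voxels, segmentation-relevant nuclear shape
irregularity, autofluorescence structure — bounds what passing tests can
claim: they demonstrate correct recovery under the stated geometry and
noise model, not performance on arbitrary real stacks.

## Segmentation

`segment_nuclei()` is a standard 3D instance-segmentation pipeline:
Gaussian smoothing (default sigma 1 voxel), a global foreground threshold
(Otsu on the smoothed histogram, or a fixed AU value), the exact Euclidean
distance transform of the foreground, distance maxima as seeds (plateaus
merged; maxima suppressed within a Chebyshev radius of
`min_seed_separation`, default 3 voxels, and below `min_seed_distance`,
default 1.5 voxels — roughly the smallest real nucleus radius), and a
seeded watershed flooding the inverted distance map. The original analysis
used a dedicated nuclear-segmentation tool whose internal parameters are
not published; the acceptance surface here is therefore ground-truth
recovery (count error within the 15–18% margin established by the manual
control comparison), not equality with any particular tool. On the default
synthetic conditions the count error is well under 1%.

The **debris filter** removes every object of volume ≤ 2000 voxels
(exclusive at the threshold: a 2000-voxel object is debris, a 2001-voxel
object is a nucleus). The 2000-voxel default is tied
to the original imaging's voxel scale; synthetic stacks use smaller nuclei,
so pipeline configurations for them pass a threshold matched to the
generator geometry (20 voxels for radii 3–6).

The **manual control route**, `seed_and_grow()`, mirrors the
seed-and-grow procedure used to estimate the automated method's error: one
seed per nucleus, grown by multi-source breadth-first region growing over
the foreground mask so that seeds sharing a blob partition it. Growth uses
the raw (unsmoothed) counterstain: smoothing before masking erodes convex
boundaries and biases volumes low. The debris filter is deliberately not
applied — each manual seed asserts a real nucleus. `segmentation_error()`
compares the two routes as `|K_auto − K_manual| / K_manual` on retained
counts; counts are the currency of every downstream analysis, which is why
the comparison is count-based rather than volume- or voxel-overlap-based
(the reference text does not specify which quantity its 15%/18% figures
compare; this is a module decision).

## Threshold calibration and classification

Positivity thresholds are calibrated per sample on four internal control
regions: (a) only Sox2+ cells, (b) only T+ cells, (c) single positives of
either marker, (d) no positivity. `calibrate_thresholds()` grid-searches
candidate (Sox2, T) threshold pairs (default step 0.5 AU — finer than 8-bit
quantisation is pointless) and maximises total per-nucleus agreement with
the crops' expected statuses. Ties are broken at the midpoint of the
contiguous optimal interval per channel, which maximises the margin on both
sides and is deterministic. The search is joint over the pair; in separable
data the per-channel optima coincide with independent calibration.

When the generator extracts control regions (`generate_control_rois()`),
the single-marker crops prefer the *dimmest* available positive nuclei.
This reflects what the control is for: a detection threshold. Anchoring the
optimal interval just above the negative floor keeps the calibrated
threshold below genuinely low-expressing double positives; anchoring it
with bright cells (e.g. notochord-level T) would push the midpoint above
the double-positive range and misclassify them — an instructive failure
mode the test suite originally exposed.

Classification is closed at the threshold: a nucleus is positive when its
mean is **≥** the threshold, so a threshold of 7 AU makes 7 AU positive —
consistent with the first T-level bin starting at 7. T levels follow the
half-open scheme: negative i < 7; level 1, 7 ≤ i < 12; level 2, 12 ≤ i <
24; level 3, 24 ≤ i < 36; level 4, 36 ≤ i < 48; level 5, i ≥ 48 (the
reference figure legend prints the last two bins with duplicated "level 2"
labels; they are read as levels 4 and 5, the only monotone reading, but
this is flagged rather than silently assumed elsewhere).

## Statistics

Per-embryo counts are summarised as mean ± sample s.d. (n − 1; undefined
and flagged at n = 1). Stage comparisons use the unpaired Student's t-test
(pooled variance, df = nₐ + n_b − 2) and the Welch-corrected test
(Welch–Satterthwaite df, kept fractional). Both delegate to
`stats::t.test()` with explicit handling of zero-variance degeneracies
(identical constant samples: t = 0, p = 1; distinct constants: an
infinite-t flag), and both are cross-checked in the tests against
independently coded closed forms. Tests are two-sided (sidedness is not
stated in the reference; two-sided is conservative). Significance is
strict at p < 0.05, with stars `*` (p < 0.05) and `**` (p < 0.0001). No
multiple-testing correction is applied, matching the reference analysis.
Fold changes are reported raw and to 2 significant figures (the
convention behind "2.4-fold": 2338/960 = 2.435 → 2.4).

## Perimeter scoring of graft contributions

For transverse neural-tube sections, a donor-cell mark is scored as a
percentage of the NT perimeter: 0% at the dorsal-right extreme, 50% at the
ventral midline, 100% at the dorsal-left extreme. Since nothing guarantees
the ventral anchor sits at exactly half the perimeter of a real outline,
arc length is rescaled piecewise — dorsal→ventral spans 0–50 and
ventral→dorsal spans 50–100 — so the printed anchor percentages hold for
any outline shape. Coordinates are image coordinates (y down); the travel
direction from the dorsal anchor is chosen by the sign of the cross
product with the dorsoventral axis, making scores invariant to rigid
rotation and translation. Marks snap to the nearest outline point within a
tolerance (default 3 length-units; donor cells line the neuroepithelium,
so lumen-adjacent marks project outward). The 0%/100% extremes are treated
as the same dorsal anchor approached from either side; if a study needs two
distinct dorsolateral endpoints, they are explicit inputs.

## Numerical and engineering choices

* Voxel arrays are R arrays in (z, y, x) order, 1-based, column-major;
  the low-level kernels (connected components, exact Euclidean distance
  transform, separable Gaussian, priority-flood watershed, multi-source
  region growing) are C++ via Rcpp, since no installed R package provides
  3D versions of these operations.
* Watershed flooding uses a FIFO tie-break at equal priority, making the
  partition deterministic; Otsu takes the first maximising bin.
* All generator randomness consumes a single explicit seed in a documented
  call order, so identical models are bit-identical and the class draw can
  be replayed independently as a test oracle.
* Rejection-sampled placement caps attempts per nucleus (500) and raises a
  packing-failure error rather than looping forever; placement bands that
  cannot contain a nucleus fail immediately.
* Degenerate inputs are contracts, not crashes: all-background stacks give
  zero labels; empty label maps give empty record tables; a manual seed on
  background gives a minimal label plus a logged warning; a zero early
  count makes a fold change an explicit error.

## Problem sizes used in validation

The shipped tests validate segmentation recovery on 500-nucleus default
stacks at noise 5 and 10 AU, calibration recovery on a 300-nucleus stack,
and end-to-end fold-change recovery on a two-stage series (420 and 640
nuclei, the later stage on a proportionally larger stack at fixed tissue
density) configured with an exact 2.4-fold double-positive increase; the
recovered fold change is required to be within 15% of 2.4, the error
margin the manual segmentation comparison established for counts. Test
sizes were chosen so the whole suite exercises every stage at realistic
density while remaining quick to run; the same recovery behaviour holds at
larger sizes.

## Known limitations

* The generator's nuclei are axis-aligned ellipsoids with uniform interior
  intensity; real nuclei are irregular and textured, so real-data error
  rates will exceed the synthetic ones. The 15–18% published margin, not
  the synthetic near-zero error, is the realistic expectation.
* Calibration quality depends on the control regions actually containing
  the statuses they claim; contradictory controls raise a calibration
  failure rather than returning a meaningless pair.
* The perimeter score assumes a simple closed outline with both anchors on
  it; outlines are supplied, not detected from images.
* No anisotropic voxel correction: distances and volumes are in voxel
  units throughout.
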