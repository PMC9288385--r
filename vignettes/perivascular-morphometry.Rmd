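---
title: "Perivascular and retinal vessel morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perivascular and retinal vessel morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

# Scope and model

`perivasc` implements the image-quantification procedures used in rodent
studies of cerebral small-vessel disease, where endothelial dysfunction is
read out through several complementary imaging assays: the geometry of the
retinal vasculature (a window onto systemic microvascular change), the
spatial organisation of myelin and other markers around brain vessels,
tracer leakage across the blood–brain barrier, vessel coverage by mural
cells, and protein expression per cell measured by immunogold electron
microscopy. Each assay is a module with a small, typed surface, and each is
paired with a synthetic generator that plants the quantity the module is
supposed to measure.

All modules share one geometric convention: images are matrices indexed
`[row, col]` from 1, and the physical position of a pixel centre is
`(index − 1) × pixelSize` micrometres. A rendered tube contains a pixel iff
the pixel centre lies within `width/2` (Euclidean) of the centreline — the
exact counterpart of recovering the radius from the Euclidean distance
transform (EDT).

# Segmentation

The retinal protocol binarises inverted, contrast-enhanced ROIs with
Phansalkar local thresholding. `preprocessRoi()` inverts and linearly maps
the 1st–99th intensity percentiles onto [0, 1] (clipping beyond): the
stretch operator is deliberately parameter-light and deterministic, since
the upstream protocol names contrast enhancement without an operator. The
threshold at each pixel is

$$ t = \mu \left(1 + p e^{-q\mu} + k\left(\frac{\sigma}{r} - 1\right)\right) $$

with $\mu,\sigma$ the mean and *population* SD over the
$(2R+1)^2$ window ($R$ = `windowRadius`, default 15 px), computed with
mirror padding so small ROIs keep their borders. The constants default to
the method's original publication values (k = 0.25, r = 0.5, p = 2,
q = 10) and are all exposed. `filterMask()` then removes 8-connected
objects below a minimum area, fills interior holes below an area cutoff
(holes touching the border or an exclusion zone are never filled — this
makes the operation idempotent), and clears user-supplied exclusion zones
for staining artefacts.

# Skeleton morphometry

`skeletonize()` uses Zhang–Suen thinning: it guarantees a one-pixel-wide,
8-connected, topology-preserving skeleton with no reconnection heuristics.
The cited skeleton family (Voronoi-based medial axes) and EDT-ridge methods
produce the same centreline up to pixel resolution but need post-hoc
reconnection at ridge gaps, so thinning was preferred as the default. The
radius at each skeleton pixel is the exact EDT — the "distance erased" —
which is what the downstream diameter statistic consumes.

**Diameter calibration.** Two candidate calibrations exist: `2·EDT` and
`2·EDT − 1` px. On rendered tubes of known width we measured that
`2·EDT − 1` is exact only for bars aligned with the pixel grid at odd
integer widths (where background pixel centres sit half a pixel beyond the
true edge); at generic orientations the nearest background centre lies
essentially *on* the edge and `2·EDT` is unbiased, while `2·EDT − 1`
under-reads by a full pixel (a planted 8 µm sinusoidal trunk measures
7.94 µm vs 6.94 µm). Since real vessels are never grid-aligned, `2·EDT` is
the default and the half-pixel correction is an explicit option
(`skeletonDiameters(halfPixelCorrection = TRUE)`) for axis-aligned
geometry.

**Graph construction.** Pixels with one neighbour are end nodes; pixels
with more than two are branch pixels, after removing redundant diagonal
links (a diagonal step that also has a two-step orthogonal route would
otherwise make staircase corners look like junctions). Adjacent branch
pixels merge into one node at their centroid, so a thick X-junction is one
branch point, not four. Thinning occasionally leaves a small mesh at a
junction — two or three branch clusters connected by 1–3 px paths or tiny
loops; those connector pixels are absorbed into a single junction node
(deleting them instead can erode and even disconnect the junction).
Terminal spurs shorter than `pruneLen` (default 8 px) are removed and the
graph rebuilt to stability: thinning burrs at tube ends otherwise inflate
branch counts. The default is deliberately below the shortest biologically
meaningful inter-node segments generated or measured here (≥ 20 px) and
above the longest burrs observed on rendered junctions (≈ 5 px).

**Arc length.** A raw 8-chain step sum (1 or √2 per step) overestimates
the length of a smooth digitised curve by up to ~8% depending on
orientation (~5.5% averaged over a semicircle), which would make even a
perfect circle look tortuous. Edge arc length is therefore the sum of
chords of the pixel path resampled every 5 px (endpoints always included),
which tracks true curve length to within ~1.5% on digitised lines and arcs
while remaining ≥ the chord by the triangle inequality, so tortuosity
τ = arc/chord never falls below 1 by construction error. Closed loops have
chord 0, are flagged `NA`, and are excluded from means. The ROI mean
tortuosity is the unweighted mean over edges (with ≥ 5 path pixels); the
per-ROI radius statistic is the mean over skeleton pixels. Both choices are
config-free defaults rather than claims about the upstream protocol, which
does not state its weighting.

`majorVesselDiameter()` reproduces the calliper protocol for named major
vessels: widths measured along the local perpendicular at fixed arc-length
intervals (default 200 µm) from origin to terminal bifurcation, samples
whose perpendicular leaves the image dropped with a warning.
`axonDiameterFromPerimeter()` is the circle-assumption conversion
perimeter/π.

# Perivascular rings

`makeRings()` formalises the no-double-counting rule: for each non-vessel
pixel and vessel $v$, the candidate ring index is
$\lceil d_v / w \rceil$ with $d_v$ the Euclidean distance to $v$'s mask
(EDT of the complement — distance from the vessel *edge*, so vessels of
different calibre get equal-width annuli). The pixel joins the vessel with
the smallest candidate index ≤ `nRings`; ties leave it unassigned. With a
single ring this reduces exactly to subtracting the overlap between one
vessel's ring and another's; with several rings it generalises the same
priority. Ring densities divide positive-pixel counts by ring area × section
depth (depth 1 when unknown, giving per-area densities), and the
normalised density divides by the image-wide positive density over
non-vessel pixels, which is exactly 1 under uniform signal and makes rings
comparable across images. Per-image thresholding defaults to Otsu ("set
for each image"); note that with an empty intensity gap between modes the
Otsu objective has a plateau of equivalent maximisers, so equivalence
checks compare achieved inter-class variance, not the threshold position.

# Tracer profiles

Profiles are bilinear interpolations of each channel at evenly spaced
points along a user-drawn line (reversing the line reverses the profile
exactly). The vessel extent on a profile is delineated from the
vessel-filling lectin channel by its half-maximum crossings walked outward
from the peak, with the background estimated from the outer 10% of samples
at both line ends and sub-sample linear interpolation at the crossing;
profiles without a peak of at least `minProminence` (default 0.1) above
background are flagged and excluded. Extravascular means are taken beyond
the boundaries plus a 1 µm margin (wall bleed), per non-lectin channel,
optionally minus a known acquisition background. Per-animal summaries flag
animals with fewer than 7 analysed vessels. The line length (default
~20 µm either side) and sample count are free parameters of the
acquisition, not claims from the upstream protocol.

# Immunogold densities and simple ratios

Densities are counts over reconstructed volumes (particles/µm³); fold
differences are plain ratios; the positive/negative expression call
compares a cell's density against `positivityFactor ×` the nuclear
background density (default background 2.5 particles/µm³). The positivity
factor has no external standard — the upstream assay classifies by eye —
so it defaults to 3, is always reported beside the raw density, and should
be treated as a configurable surrogate. `percentVolume()` and
`norPreference()` are the volumetric percentage and novel-object
preference ratios used in the same studies.

# Statistics

The wrappers standardise the tests named in this literature: Student's
*pooled* t (the pooled degrees of freedom $n_a + n_b - 2$ match the df
reported for equal-sized animal groups), exact Mann–Whitney U (exact for
small untied samples, normal approximation otherwise), Fisher's exact 2×2,
the two-sided variance F test reported as larger-over-smaller variance,
Pearson correlation, one-way ANOVA with Tukey HSD (which reduces to the
pooled t for two groups), and the Wilcoxon signed-rank test (exact up to
n = 15 non-zero differences). All tests are two-sided and no correction
beyond Tukey is applied. Exact tests are verified against full enumeration
oracles in the test suite. One sizing subtlety: the exact Mann–Whitney test
at n = 6 per group is discrete with true two-sided size 0.0411 at
α = 0.05, so Monte-Carlo estimates of its rejection rate sit below 0.05 by
construction, not by miscalibration.

# The synthetic generator: what it emulates, and what it does not

The generators plant exactly the quantities the pipeline measures:

- **Retina** (`generateRetinaImage`): a sinusoidal trunk with side
  branches attached at known points, rendered as tubes of known width
  (defaults 8 and 6 µm at 1 µm/px — comfortably above the 3 px rendering
  floor), planted per-segment tortuosity (defaults 1.08 trunk / 1.05
  branches, solved numerically from the amplitude–wavelength pair),
  additive Gaussian noise (default SD 0.02) and vessels dark on a bright
  background so the invert-and-threshold protocol applies. Branch
  placement uses deterministic rejection sampling so no two tubes approach
  within the sum of their half-widths: planted junctions are then the
  *only* junctions, which is what makes exact branch-count recovery a
  meaningful test. Layout and noise have separate seeds, so one geometry
  can be re-imaged under independent noise.
- **Sections** (`generateSectionImage`): marker pixels are independent
  Bernoulli draws with probability `p(r)` a function of distance from the
  nearest vessel edge — the planted analogue of a perivascular density
  profile, with exact binomial error bars.
- **Tracer** (`generateTracerImage`): a filled lectin delineation plus
  tracer channels with an intravascular plateau and an extravascular leak
  planted *on top of* the background pedestal, keeping Gaussian noise away
  from the [0, 1] clip so zero-leak recovery is unbiased.
- **EM counts** (`generateEmCounts`): Poisson counts at planted
  density × volume.

What passing these tests does *not* show: the generator has no point-spread
function, channel bleed-through, tiling or illumination artefacts, no
vessel calibre variation along a segment, no curvature beyond a single
sinusoid mode, and its noise is additive Gaussian rather than
Poisson-dominated shot noise. Recovery on these images bounds algorithmic
error (digitisation, graph construction, assignment rules), not robustness
to real acquisition physics; segmentation parameters will need adjustment
on real material.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty masks skeletonise to empty
skeletons; constant images fall back to inversion only (preprocessing) or a
fixed 0.5 threshold with a warning (Otsu); zero-area rings and flat tracer
profiles are flagged rather than erroring; all-zero paired differences give
p = 1 with a flag. Ties in the ring assignment are resolved to
"unassigned" by design. The validation suite sizes are chosen to keep the
full run around a minute on one core while leaving the statistical checks
well-powered: 50 noiseless trees for exact branch recovery, 20 noisy
256×256 images for morphometry recovery, 100 random 64×64 fields against
the brute-force ring oracle, 10 seeds for ring-profile recovery, 10
vessels per tracer condition, and 2000 null replicates for the type-I
rates.

# Known limitations

- Thinning-based skeletons displace junctions by up to about a vessel
  radius from the geometric attachment point; counts are exact but
  junction *positions* are approximate.
- The diameter statistic averages over all skeleton pixels, including
  junction neighbourhoods where the EDT reflects the junction blob rather
  than either vessel's calibre; with the default geometries this biases
  means by ~2%.
- `n_rings > 1` generalises the published single-ring protocol; the
  normalisation of densities across experiments implemented here
  (per-image relative density) is one reading of a procedure whose exact
  formula is not public.
- The CLI (`inst/scripts/perivasc.R`) is a thin convenience wrapper; the R
  functions are the supported interface.
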