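# perivasc

Quantitative image analysis for studies of cerebral small-vessel disease
(SVD) and vascular biology, written for researchers who quantify vessels and
their surroundings in fluorescence microscopy: retinal flat-mount vasculature,
perivascular marker staining in brain sections, blood–brain-barrier tracer
leakage, vessel-marker coverage, and immunogold electron microscopy. Every
stage ships with a synthetic-data generator that plants known ground truth,
so the whole pipeline is validated end to end against exact answers.

## What it computes

**Retinal vessel morphometry.** A binarised vessel plexus is reduced to a
one-pixel centreline by topology-preserving thinning; the local radius at
every skeleton pixel is the exact Euclidean distance transform value ("the
distance erased"). The skeleton graph classifies pixels by their neighbour
count — end points (1 neighbour), branch points (> 2) — and its edges carry:

- *tortuosity* τ = arc length / chord length between adjacent nodes (τ ≥ 1,
  1 for a straight segment),
- *branching index* = branch points per µm² of ROI,
- *mean diameter* = 2 × EDT at skeleton pixels, calibrated to µm.

Binarisation follows the standard retinal protocol: inversion, contrast
stretch, then Phansalkar local thresholding,
t = µ·(1 + p·e^(−qµ) + k·(σ/r − 1)) over a sliding window, with the original
constants k = 0.25, r = 0.5, p = 2, q = 10.

**Perivascular rings.** Concentric annuli (default 10 µm wide) are grown
around each vessel with a uniqueness rule — each pixel belongs to the vessel
for which its ring index ⌈d/width⌉ is smallest, ties unassigned — so no
tissue is counted twice. Per-ring positive-pixel densities are adjusted for
ring area and section depth and normalised by the image-wide positive
density.

**Tracer line profiles.** Intensities of lectin + tracer channels are
sampled along lines perpendicular to the vessel wall; the lectin half-max
extent delineates the vessel, and each tracer's mean intensity outside the
boundaries (plus a safety margin) measures extravasation.

**Immunogold densities.** Particle counts over reconstructed cell volumes
give densities in particles/µm³, fold differences between cells, and a
configurable positive/negative call against nuclear background labelling
(2.5 particles/µm³ in the assay this emulates).

**Statistics.** Pooled two-sample t, exact Mann–Whitney U, Fisher's exact
test, two-sided variance F test, Pearson correlation, one-way ANOVA with
Tukey HSD, Wilcoxon signed rank — each wrapped with a uniform result table
and verified against enumeration oracles.

## Worked example

Generate a synthetic retina image with planted truth, segment it, and
measure it:

```r
library(perivasc)
cfg <- synthConfig(imageSize = c(256, 256), pixelSize = 1,
                   noiseSd = 0.02, seed = 7)
syn  <- generateRetinaImage(cfg, nBranches = 4, trunkWidth = 8,
                            branchWidth = 6)
pre  <- preprocessRoi(syn$image)
mask <- filterMask(phansalkarThreshold(pre),
                   minObjectArea = 25, fillHoleArea = 25)
morphometry(mask, pixelSize = 1)
#>  mean_diameter mean_tortuosity n_branch_points branching_index roi_area n_edges
#>        7.00198        1.040343               4    6.103516e-05    65536       9
```

The planted truth for this seed is an (arc-length-weighted) mean width of
~7.0 µm (trunk 8 µm, branches 6 µm), mean segment tortuosity 1.0401 and 4
branch points in the 65,536 µm² field — the recovered diameter, tortuosity
and branch count match it to within ~2%, 0.1% and exactly, respectively.

Immunogold densities for five reconstructed endothelial cells:

```r
cells <- data.frame(cell_id = paste0("EC", 1:5),
                    count = c(1330, 1500, 1960, 1700, 140),
                    volume = rep(10, 5))          # um^3
emDensityTable(cells, positivityFactor = 10)
#>  cell_id count volume density fold_vs_reference positive
#>      EC1  1330     10     133           9.50000     TRUE
#>      EC2  1500     10     150          10.71429     TRUE
#>      EC3  1960     10     196          14.00000     TRUE
#>      EC4  1700     10     170          12.14286     TRUE
#>      EC5   140     10      14           1.00000    FALSE
```

Cell EC5 expresses 9.5–14× less than its neighbours — the heterogeneity
signature this assay was designed to quantify.

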