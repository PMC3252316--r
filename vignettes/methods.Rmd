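---
title: "3D nuclear morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D nuclear morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomorph3d)
```

# The problem and the pipeline

Nuclear structure — size, shape, nucleus-to-cytoplasm ratio, chromatin
texture — is the backbone of cytopathological grading, yet it is usually
assessed from 2D sections of intrinsically 3D objects. `nucleomorph3d`
analyses isotropic 3D optical-density volumes of single H&E-stained cells:
it segments the cell, the nucleus, nucleoli and chromatin condensation
states, computes a canonical vector of 42 morphological and textural
descriptors per cell, classifies each nucleus into one of four shape
categories, and screens all features for discriminatory power across three
populations (normal-, fibrocystic- and metastatic-like).

One `VoxelGrid` holds one cell: a 3D array of non-negative optical
densities with a single voxel spacing in micrometres. Isotropy is a premise
of every distance-based feature, so anisotropic metadata is rejected at
load time rather than resampled. Voxel centres sit at
`(index − 1) × spacing` along each axis in R's native 1-based, column-major
order; all features are reported in micrometre-derived units, so the axis
convention is unobservable in the results.

# Segmentation model

The de-noising and segmentation operators are deliberately simple,
parameter-free substitutes validated on phantoms (the operators used on the
original instrument data are not public):

* **De-noising**: median filter, radius 1 voxel (idempotent on
  piecewise-constant regions; a Gaussian alternative is provided).
* **Cell**: Otsu threshold on the full volume, largest 26-connected
  component, morphological hole fill. Otsu on a min–max-binned histogram is
  equivariant under affine OD rescaling `d → a·d + b`, which the tests
  assert.
* **Nucleus**: Otsu restricted to cell voxels (hematoxylin makes the
  nucleus the dense class), largest component, hole fill. Secondary nuclear
  components below 30 % of the main component's volume are reported as
  micronucleus candidates, never merged — merging would corrupt nuclear
  volume and hide exactly the phenotype (micronuclei vs multilobed nuclei)
  that 3D imaging can distinguish.
* **Condensation states**: thresholds one population standard deviation
  either side of the mean nuclear density; voxels below `μ − σ` are low,
  above `μ + σ` high, medium otherwise. The population (÷N) convention is
  used for every variance in the package, for consistency with this σ.
* **Nucleoli**: voxels above `μ + k·σ` (default `k = 2`), 26-connected,
  discarding components below 0.2 µm³. Nucleoli are part of the
  high-density state; the k·σ criterion separates the brightest bodies from
  ordinary high-density chromatin. Two nucleoli closer than one voxel merge
  — a documented resolution limit of connected-component labelling.

# The 42 descriptors

The registry (see `featureRegistry()`) fixes names, order and units:
9 morphological, 5 descriptive, 24 discrete, 4 Markovian. Two naming
choices deserve a note. The canonical vector reports the *variance* in
nucleolar volume; the mean nucleolar volume is exposed as a non-canonical
extra, because the two published enumerations of the feature set disagree
on this entry and the discriminatory table is the more complete one. The
quantity called `markovian_heterogeneity` is the co-occurrence homogeneity
(inverse difference moment) under its variant published name; one quantity
is computed and dual-named rather than guessing an unstated complement.

Surface area, needed by sphericity and compactness, comes from a
triangulated isosurface: the binary mask is padded, smoothed by one
Gaussian pass (σ = 1 voxel), and triangulated at the 0.5 level by marching
tetrahedra on the 6-tetrahedron Freudenthal decomposition of each lattice
cell. Smoothing first removes the voxel staircase; digital balls measure
within 3 % of 4πr². For objects so small that smoothing pulls the field
below 0.5, the level adapts to half the field maximum, with an exposed
voxel-face count as the degenerate-case fallback — a single-voxel mask
still gets a positive, finite area.

The extinction ratios operationalize "smoothness of transition between
condensation states", which the source material names but does not define:
for a state pair (A, B), A the lower-density state, the ratio of the mean
OD of A-voxels face-adjacent to B over the mean OD of B-voxels
face-adjacent to A. The form is bounded by 1, scale-invariant, and equals
the plain density ratio for abutting constant slabs.

Markovian features use a symmetric 3D gray-level co-occurrence matrix:
nuclear ODs are min–max quantized to G = 32 levels (configurable; min–max
quantization makes the features affine-OD-invariant), and pairs are pooled
over all 26 neighbourhood orientations before the statistics are computed
(pooled counts, not per-direction averaging — the alternative reading is
noted as unknowable). Displacements are the 26 unit offsets scaled
per-component by `k = round(scale / spacing) ≥ 1`; with 0.35 µm spacing the
three scales 0.44 / 0.74 / 1.5 µm give k = 1, 2, 4. Integer scaling keeps
exactly 26 offsets with no interpolation, at the cost of a known radial
bias along diagonals (√3·k·spacing). The 0.74 µm scale fills the canonical
vector; the full sweep is exported separately.

# Shape classification

Four categories: (1) marked concavity and slender, (2) slight concavity
and bulky (the common "mushroom cap"), (3) overall convex, (4) irregular /
multilobed. The published categorization is qualitative (and possibly
manual); this module is an explicit algorithmic surrogate built on three
measures:

* **concavity index** `c = 1 − V/V_hull`. Both volumes are voxel-center
  counts — the mask count versus the count of voxel centres inside the
  convex hull of surface-voxel centres. Comparing a continuous hull volume
  against a voxel-count volume would bias flat nuclei by half a voxel of
  surface rind, which is larger than the concavity signal itself.
* **elongation** `e`: shortest/longest principal-axis ratio from the
  mask's second-moment ellipsoid.
* **lobe count**: regional maxima of the h-maxima transform (h = 20 % of
  the maximum) of the interior Euclidean distance transform, smoothed by
  one voxel. Using regional maxima of the reconstruction — rather than the
  raw `dt − rec ≥ h` support — makes a ridge ring around an indentation
  count as one plateau instead of fragmenting into spurious "lobes".

The rule set is total and deterministic: category 4 if lobes ≥ 2 or
`c ≥ 0.25`; else 3 if `c < 0.008`; else 1 if `e ≤ 0.55`; else 2. The
convex/concave boundary (0.008) was calibrated once on generator sweeps and
frozen: voxelized ellipsoids measure `c ≤ 0.002` while the shallowest
"slight concavity" phantoms measure `c ≥ 0.012` — the hull of a dimpled
dome hugs it, so realistic concavity indices are an order of magnitude
smaller than intuition suggests. All thresholds live in `StudyConfig`.

# The phantom generator

The generator emulates the statistical structure of H&E-stained mammary
epithelial cells, not their optics: an ellipsoidal cytoplasm of low OD
containing a nucleus of one of the four shape categories, with planted
nucleoli (brightest), low- and high-density spherical chromatin clumps,
optional micronuclei in the cytoplasm, and additive Gaussian noise
truncated at zero (no negative densities; no PSF or tomographic artefact
simulation). Base ODs are ordered
background < cytoplasm (0.25) < low clump (0.38) < nuclear base (0.5) <
high clump (0.62) < nucleolus (0.95); the cytoplasm sits high enough that
Otsu's first split separates background from cell rather than cytoplasm
from nucleus.

Nucleus geometry: category 3 is a general ellipsoid (volume exact);
categories 1/2 are a spheroid indented by an axis-centred sphere — for a
spheroid the sphere–spheroid intersection reduces to piecewise polynomial
integrals split at the height where the two cross-sections coincide, so
the planted volume is exact, not approximated; category 4 is a union of
2–4 overlapping ellipsoidal lobes, displaced by 0.92 times the sum of the
two directional radii so necks stay detectable, with a Monte-Carlo volume
(200 000 points) and its standard error recorded. Structures are placed by
rejection sampling on the interior distance transform with pairwise surface
gaps of at least two voxels (so 26-connected labelling separates them),
with whole-configuration restarts when sequential sampling corners itself.

Three population presets order themselves as the study populations do:
mean cell and nuclear volumes increase normal → fibrocystic → metastatic;
the abnormal presets plant more nucleoli and more chromatin clumps; all
four shape categories occur everywhere, with category 2 commonest and the
metastatic-like preset carrying the largest irregular fraction and
occasional micronuclei. The numeric ranges are invented (the source study
reports no category-wise shape parameters) and frozen; they are conditions,
not tuning knobs. Default grids are the cell bounding box padded by 3 µm at
0.35 µm spacing — roughly 55–90 voxels per axis, desk-scale.

What passing phantom tests does **not** show: robustness to reconstruction
artefacts, PSF anisotropy, staining variability, touching cells, or
mitotic figures. The segmentation operators are validated only on this
generator's contrast model.

# Statistics

Per feature: Shapiro–Wilk per group at 0.05; one-way ANOVA when all three
groups pass, Kruskal–Wallis otherwise ("appropriately applied", read
conservatively). Pairwise contrasts are Scheffé-corrected: on the ANOVA
path the pairwise F-contrast divided by k−1 against F(k−1, N−k); on the
rank path a Dunn-type rank contrast whose squared z is referred to
chi-square with k−1 degrees of freedom — the closest coherent rank
analogue of Scheffé's projection, isolated in one function precisely
because the published pairing of a rank test with Scheffé correction is
unexplained. The decision level α = 0.0025 is taken verbatim from the
published table header; its derivation is not reconstructed. The
normal-vs-abnormal call requires *both* normal-vs-X contrasts significant.
Scheffé projection makes the screen conservative; the null simulation in
the acceptance suite keeps the per-feature type-I rate well under 0.01 at
this α.

# Numerical choices and degenerate inputs

* Variances: population convention everywhere.
* Otsu: 256 bins between min and max; constant inputs are errors ("no cell
  detected" / "degenerate nucleus histogram"), never silent defaults.
* Missing spacing metadata is an error; spacing is never assumed to be 1.
* Inapplicable features (zero nucleoli, empty states, σ = 0) are explicit
  `NA`s, never zeros.
* Ties: equal-size foreground components keep the first label and emit a
  multiplicity warning.
* Per-cell failures inside `runStudy` are quarantined with a
  stage-attributed message; a study aborts only if more than 20 % of its
  cells fail.
* Problem sizes in the shipped tests and acceptance script — 30 noise-free
  phantoms for parameter recovery, a 102-phantom shape sweep, 2000
  screening replicates at n = 50 per group — were chosen as the package's
  own desk-scale defaults.

# Known limitations

* The published per-feature significance calls are shipped as a fixture
  and summarized; the real 450-cell biological numbers (group means,
  figure percentages) derive from imaging data that is not deposited and
  are not reproduced here.
* TIFF float output is restricted to ODs in [0, 1] by the underlying TIFF
  writer; NRRD/MetaImage carry arbitrary ranges and full spacing metadata.
* Clump compactness on few-voxel clumps is dominated by discretization;
  values are comparable across cells analysed at one spacing, not across
  spacings.
* The extinction-ratio and rank-Scheffé formulations are this package's
  documented operationalizations of named-but-undefined published
  quantities; alternative readings would change absolute values, not the
  testing framework.
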