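---
title: "Methods: chromatin texture, foci counting and compartment scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin texture, foci counting and compartment scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtex)
```

## What the package measures

DNA-damaging treatment condenses chromatin: under a DAPI stain, nuclei
shift from a smooth, homogeneous interior towards a clumped,
heterogeneous one. `chromtex` quantifies that shift with second-order
texture statistics, counts punctate DNA-damage foci per nucleus, and
scores a target channel inside cytokeratin-defined tissue compartments
on TMA cores. Because such microscopy is rarely shareable, the package
ships a synthetic-scene generator with complete ground truth, and every
stage is validated against generated scenes.

## Grey-level co-occurrence texture

For a quantized nuclear region the GLCM entry $p(i,j)$ is the
probability that a pixel of grey level $i$ has a neighbour of level $j$
at a fixed offset (distance $d$, one of the four 2-D directions 0°,
45°, 90°, 135°). Five statistics summarize the matrix:

* **ASM** $\sum_{i,j} p(i,j)^2$ — uniformity; high for homogeneous
  chromatin.
* **Contrast** $\sum_{i,j} (i-j)^2\, p(i,j)$ — local grey-level
  variation.
* **Correlation**
  $\sum_{i,j} \frac{(i-\mu_x)(j-\mu_y)\,p(i,j)}{\sigma_x \sigma_y}$ —
  linear dependency of neighbouring levels, computed from the marginal
  moments.
* **IDM** $\sum_{i,j} \frac{p(i,j)}{1+(i-j)^2}$ — local homogeneity.
* **Entropy** $-\sum_{i,j} p(i,j) \log_2 p(i,j)$ — disorder of the
  co-occurrence distribution, in bits, with $0 \log 0 := 0$.

Key numerical choices:

* **Quantization, G = 32 by default.** GLCMs are built after uniform
  binning of the 8-bit axis (`floor(v * G / 256)`). Nuclear ROIs hold a
  few hundred to a few thousand pixels; a 256×256 matrix built from so
  few pairs is almost entirely empty and makes correlation numerically
  unstable. G = 32 keeps the matrix well populated while preserving the
  intensity ordering; G = 256 remains available in `glcm_params()`.
* **Offsets.** Default distance 1, all four directions, symmetric pair
  counting, features averaged over directions (matrices are never
  averaged). A single-direction, asymmetric configuration is one
  `glcm_params()` call away, and the parameters used are recorded in
  every pipeline output.
* **Masked pairs.** Both endpoints of a pair must lie inside the
  nuclear mask; pairs crossing the boundary are discarded, so
  bounding-box background cannot leak into the matrix.
* **Degenerate correlation.** When a marginal standard deviation is
  zero (e.g. a constant nucleus) correlation is reported undefined and
  excluded from aggregation — never coerced to 0 or 1. The count of
  such nuclei is reported alongside every per-sample mean.
* **Entropy base.** Base-2 throughout; entropies are bits and the
  two-level closed forms (checkerboard = 1 bit, uniform 2×2 = 2 bits)
  pin the convention in the tests.
* **Boundary erosion.** `nucleus_texture_profile(erode_px = 2)` erodes
  each nuclear mask by 2 px before pair extraction. Segmentation places
  its boundary on the intensity fall-off at the nuclear rim; those
  partial-volume pixels otherwise contribute spurious dark–bright pairs
  that inflate contrast and distort correlation. Two pixels matches the
  default smoothing radius; set `erode_px = 0` to use masks as given.

Per-nucleus features are averaged to one value per sample, and group
effects are expressed as percent change of treated over control means —
the same per-sample-then-compare structure used for group testing.

### Pattern interpretation

`interpret_chromatin_pattern()` reads a vector of per-feature percent
changes as calls on three chromatin patterns. Each feature with
$|\Delta| \ge$ 5% votes with its association sign: homogeneity is
raised by ASM and IDM and lowered by entropy; heterogeneity is raised
by entropy and lowered by correlation; contrast is raised by the
contrast feature and lowered by IDM. Unanimous votes give
increased/decreased, all-subthreshold gives unchanged, and mixed votes
give indeterminate. The association table is one constant
(`pattern_associations()`); the 5% default threshold sits just below
the smallest change the package treats as biologically meaningful, and
sub-threshold features abstain rather than vote.

## Synthetic scenes: what they emulate, and what they do not

`generate_texture_scene()` places non-overlapping elliptical nuclei
(mean radius 12–18 px, eccentricity 1.0–1.6) on a dark background.
Control interiors are `base_level` (120) plus a smooth Gaussian field
(sd 10, correlation length ≈ radius/4) — homogeneous chromatin with
gentle large-scale variation. Treated interiors additionally receive
disk-shaped heterochromatin clumps (radius ≈ radius/5) planted at
random until they cover the `clumpiness` fraction (default 0.4) of the
nuclear area. Two design points matter:

* **The nuclear mean is conserved exactly.** Clumps are bright
  (`clump_gain`, default 1.2) and the inter-clump background is dimmed
  to compensate, so the regimes differ in *pattern*, not brightness,
  and texture effects are not confounded with gain.
* **Clump intensity is jittered.** Each clump's gain is drawn uniformly
  around `clump_gain`. With one flat clump level, a nucleus at high
  clumpiness is again nearly homogeneous (one plateau) and ASM/entropy
  reverse direction; jittered clumps keep the feature response
  monotone in clumpiness across 0 → 0.4 → 0.8, which the acceptance
  suite checks at 20 seeds per level.

Noise is Poisson-like: Gaussian with sd `noise_sd` (default 5) scaled
by $\sqrt{I/\text{base}}$, so brighter structures are noisier, as in
photon-limited acquisition.

`generate_foci_scene()` plants Gaussian spots (sd 1.5 px, peak 150 over
a background of 10) at uniform in-nucleus positions with pairwise
separation ≥ 4σ. That separation bounds how many spots fit: random
sequential packing saturates near half of the hexagonal bound, so the
foci preset uses 8 nuclei of radius 22–28 px on a 360² canvas, where up
to 12 spots per nucleus are feasible. `generate_tma_scene()` builds a
circular core whose epithelium blob is carved as the upper quantile of
a smooth field — the realized epithelial fraction equals the request to
within pixel rounding — with nuclei inside the epithelium and a target
channel at distinct nuclear/cytoplasmic levels.

Scenes are deterministic given `(spec, seed)`; one seed drives all
draws through a single generator stream, and the caller's RNG state is
restored afterwards.

What the generator does **not** emulate: optics (no PSF, so nuclear
edges are sharper than real acquisitions), 3-D structure, uneven
illumination, staining variability between slides, overlapping nuclei
(except the explicit touching-ellipse fixture), or brightfield H&E
rendering. Passing tests therefore demonstrate correctness of the
measurement pipeline on known ground truth, not performance on real
tissue; on real images the segmentation parameters and the detection
threshold should be re-examined first.

## Segmentation

`segment_nuclei()` is deterministic: Gaussian smoothing (sd 2 px), Otsu
global threshold, hole filling, optional distance-transform watershed
(tolerance 3, so a single convex nucleus is not oversplit), area filter
(100–10 000 px²) and optional border removal. A constant image returns
an empty mask rather than an error. Compartment masks threshold the
cytokeratin channel the same way; the nuclear compartment is segmented
nuclei ∩ epithelium, the cytoplasmic compartment the remainder, so the
two are disjoint by construction. The manual "mark focused regions"
step of interactive workflows has no algorithmic analogue; the pipeline
instead accepts pre-made masks anywhere a `label_mask` is taken.

## Foci counting

`detect_foci()` maximizes a scale-normalized Laplacian-of-Gaussian
response over 4 scales (σ 1–2.5 px), keeps local maxima above
`detection_threshold` (0.15) × the channel's dynamic range inside
nuclei, and greedily suppresses maxima closer than `min_separation`
(5 px), strongest first. Because the threshold is relative to dynamic
range, counts are invariant to linear gain rescaling. A cell is
**positive** when its count strictly exceeds the cut-point (default 5),
i.e. up to five foci are treated as negative background; whether
exactly five should be positive is a convention, recorded with every
result, and switchable by setting `positivity_cutpoint = 4`. Fewer than
100 analysed nuclei triggers a warning (not an error), reflecting the
usual per-slide counting practice.

## Compartment scoring

`score_core()` reports mean target intensity per compartment in
arbitrary units. Proprietary immunofluorescence scoring systems apply
an undocumented final normalisation; no stand-in transform is applied
here, so scores are directly the compartment means. Cores with
epithelium fraction strictly below 5% are excluded (`= 5%` is kept,
the literal reading of the rule); the filter reports dropped core ids
and is idempotent.

## Group statistics

`mann_whitney_u()` uses midranks and switches between an exact and a
corrected-normal two-tailed p: exact when the combined sample is ≤ 20
and tie-free (twice the smaller tail of the null U distribution, capped
at 1 — identical to full enumeration of all rank assignments, which the
test suite verifies to 1e-12 on 200 random small-sample pairs), normal
approximation with tie and continuity corrections otherwise. The
threshold reflects the small per-group sample counts typical of
xenograft texture comparisons. `t_test_groups()` is the pooled-variance
two-sample t with explicit zero-variance conventions (p = 1 for equal
means, p = 0 flagged otherwise). No multiple-testing correction is
applied to the per-feature comparisons, matching the per-parameter
reporting convention; apply `p.adjust()` downstream if desired.

## Problem sizes and determinism

The validation suite runs on 160–360 px scenes with 5–12 nuclei, 20
seeds per condition — sizes chosen so each property is measured on
hundreds of nuclei while the whole suite completes in well under a
minute on one CPU. The pipeline writes no timestamps, so a config plus
seed reproduces every CSV/JSON byte for byte;
`scripts/acceptance.R --seed N --out f.json` regenerates the headline
quantities from scratch for any seed.

## Known limitations

* Texture features depend on the quantization and offset configuration;
  values are comparable only within one configuration (which is echoed
  into every output).
* Watershed splitting handles touching, roughly convex nuclei; heavily
  overlapping nuclei are out of scope.
* The LoG detector counts foci but deliberately reports no focus
  intensity/size morphometry or cross-channel colocalisation.
* Absolute compartment scores from real instruments are not
  reproducible here; only relative, within-configuration comparisons
  are meaningful.
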