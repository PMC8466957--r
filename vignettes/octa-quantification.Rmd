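---
title: "Quantifying macular microvasculature in lamellar macular holes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular microvasculature in lamellar macular holes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmhocta)
```

## The measurement problem

A lamellar macular hole is a partial-thickness foveal defect. A subset of
these eyes progresses: the retinal gap visible on OCT B-scans enlarges
between visits, and vision declines. The analysis this package implements
asks whether progressive eyes differ from stable ones in the
microvascular quantities OCT-angiography can measure — vessel and
perfusion density around the fovea, and the size and shape of the central
capillary free zone (CFZ) — and whether the amount and speed of tissue
loss track perfusion and visual acuity.

Patient angiograms for this question are not publicly available, so the
package is built around a synthetic-data module that generates every
input with known ground truth. All claims the tests make are claims about
the pipeline's behavior on that synthetic family; see "What the generator
does and does not emulate" below.

## The pipeline

### Binarization

En-face angiograms are normalized min–max to [0, 1] and binarized by
fusing three operators:

* a **global threshold** keeping the white-pixel band [0.7, 1.0] (lower
  bound inclusive);
* a **multiscale Hessian vesselness filter**: Gaussian-derivative Hessians
  at scales {1, 2, 3} px, eigenvalues ordered |λ1| ≤ |λ2|, bright-ridge
  response `exp(-(λ1/λ2)²/(2β²))·(1-exp(-S²/(2c²)))` with β = 0.5,
  S² = λ1² + λ2², and c set per scale to half the maximum of S — the
  standard ridge-enhancement construction for capillaries;
* an **adaptive threshold**: pixel intensity must exceed its local mean
  over a 15 px window (reflective padding) by 0.02. Thin bright vessels
  exceed their local mean; uniform regions do not.

The fusion rule is `global OR (adaptive AND vesselness ≥ 0.05)`: the OR
preserves large bright vessels wherever they are, while the AND admits
faint capillaries only where the ridge filter agrees, suppressing noise.
Published descriptions of this binarization list the three operators
without a combination formula, so the rule is a design choice here, and every cut is exposed as
a parameter so alternatives are testable. Connected components under
5 px (4-connectivity) are removed as speckle; this size is small enough
never to delete a real capillary segment at 5.7 µm pitch.

A pixel is **perfused** when it is vessel and its inter-frame
decorrelation `D = 1 - mean_t[2 f_t f_{t+1}/(f_t² + f_{t+1}²)]` reaches
τ_D = 0.05. With no frame stack the perfusion map is refused rather than
silently equated to the vessel map. Both D-based masks are monotone in
their thresholds (raising a cut never adds pixels), which the tests
assert.

### Sector grid

The analyzed extent is a 1 mm-diameter foveal disc plus a parafoveal ring
out to 2.9 mm, each split into four quadrants by diagonal boundaries at
45°/135°/225°/315° (the ophthalmic four-sector convention; a rotation
offset is exposed). Radial intervals are inner-inclusive/outer-exclusive
and angular arcs half-open `(a, a+90]`, so the eight regions form an
exact partition — conservation that the tests check pixel by pixel. The
quadrant containing the (user-supplied) tissue-loss direction is the ROI;
the opposite quadrant is R3. The fovea center is supplied by the user or
defaults to the image center in the demo; automatic foveal detection is
out of scope.

### CFZ morphometry

Circularity is `4πA/P²`. Values above 1 violate the isoperimetric
inequality and raise a warning rather than being clamped (a value of
1.02 is allowed as discretization slack on rasterized contours). The
perimeter is taken from a **sub-pixel marching-squares contour** of the
lightly smoothed avascular region (σ = 1 px), never from boundary-pixel
counting, which overestimates perimeters by ~27% and would wreck
circularity; the tests hold the contour of a rasterized disk to within 2%
of 2πr for r ≥ 30 px. Before flood-filling, the vessel mask is closed
with a 3 px box to seal 1–2 px segmentation breaks in the perifoveal
capillary ring; without this, the fill occasionally leaks into a
neighboring inter-vessel pocket and inflates the CFZ. Manual contours
(JSON vertex lists) remain first-class inputs; mask-derived extraction
exists for synthetic testing.

### Tissue loss

Per section, TL = follow-up gap area − baseline gap area: the
subtraction is oriented so that a loss — an enlarging gap — is a positive
number, the convention under which every reported loss value is positive. Negative
TLs (gap shrinkage) are kept algebraically and flagged. The quantitative
TL is the sum of the 3 largest per-section values (ties at third place
broken by ascending section id; with ≤ 3 sections, all are summed), the
0.02 mm² enrollment cutoff is **inclusive** ("at least"), and speed =
top-3 sum / interval, with the interval computed as exact day difference
/ 365.25 when dates are given. Per-patient speeds are summarized by their
median and IQR (whether the published median speed was computed per
patient or as a ratio of medians is not stated; per-patient is the
defensible choice).

### Statistics

Every quantitative comparison is gated by Shapiro–Wilk at α = 0.05 per
group: both groups normal → two-tailed independent t (Welch by default —
only "independent samples t test" is specified, and unequal variances are
the safer assumption at n = 14); otherwise Mann–Whitney, exact when
n_x + n_y ≤ 20 without ties. Paired BCVA/IOP changes use Wilcoxon signed
rank (zeros dropped, exact ≤ 25 untied pairs). Counts use Fisher's exact
test when any expected cell is below 5, else χ² with continuity
correction; Bonferroni post hoc corrections are applied only inside
tables larger than 2×2 — published p-values are raw row by row, so no
across-row multiplicity correction is applied. Spearman correlations use
average ranks and a permutation p-value: full enumeration of the n!
permutations for n ≤ 8, otherwise 10⁵ Monte-Carlo permutations under a
fixed seed — exact where the cohort sizes live. Grader agreement is
ICC(2,1), the two-way random-effects absolute-agreement single-measure
form, computed from ANOVA mean squares; absolute agreement is the
strictest common choice and the default, with consistency and one-way
forms exposed. IQRs use
linear-interpolation (type 7) quantiles; IQR values depend on this
choice, so it is fixed and documented.

All exact branches are verified in the test suite against brute-force
enumeration oracles (all group assignments, sign patterns, rank
permutations, hypergeometric tables) for every sample size up to 8.

## The synthetic-data generator

The generator's defaults are the study conditions: a 512 px raster at
5.7 µm/pixel (a 2.92 mm field; the published "2.9 × 2.9 mm at 5.7 µm" is
not exactly consistent with any integer raster, so the 2.9 mm analysis
grid, not the raster edge, defines the analyzed extent) and two groups of
14 patients.

**CFZ contours** are radial sinusoidal perturbations of a circle (two
harmonics, seed-dependent phases); the amplitude is solved numerically on
the polygon itself so requested area is met within 1% and circularity
within 5% across C ∈ [0.3, 1].

**Vessel networks** are seeded branching trees grown from the image
border toward the FAZ: tips advance 5 px per step with angular jitter,
branch with probability 0.12, die on entering the FAZ, and are rasterized
at 1–3 px width. A continuous terminal capillary ring is drawn 2 px
outside the FAZ border — as the perifoveal arcade does anatomically —
which also makes the avascular zone a bounded region. Trees are added
until the vessel pixel fraction reaches its target (default 0.25);
pixel-level statistics (density, width, FAZ exclusion) are the only
contracted properties — the growth process is not physiology-calibrated.

**Rendering** draws vessels at 0.9 on a 0.15 background with additive
Gaussian noise (default SD 0.02). Frame stacks (default 8 frames) give
perfused pixels independent per-frame multiplicative speckle |N(1, 0.6)|
while non-perfused pixels stay static. Frames render vessels at a lower
amplitude (0.45) so the speckle is not flattened by the [0, 1] clip —
clipping measurably suppresses decorrelation. This calibration puts the
per-pixel probability of a perfused pixel falling under τ_D = 0.05 at
about 2%, which is what bounds the perfusion-recovery error in the
acceptance tests.

**Cohorts** draw each variable per group from the published location/
scale pairs: mean ± SD entries as normal, median (IQR) entries as a
shifted lognormal matched by median and IQR (component median set to the
IQR, fixing sdlog ≈ 0.713 — a mild right skew, preserving the asymmetry
that motivated the nonparametric tests, and valid for negative-located
variables like spherical equivalent). Inter-variable correlations beyond
the two published monotone links are not specified anywhere and are
simulated as independent. The TL group's top-3 tissue loss is drawn at
median 0.09 mm² / IQR 0.055, resampled to stay ≥ 0.03 mm² so the
0.02 mm² cutoff separates groups cleanly; the ST group grows below
0.012 mm². BCVA decline is 3.0 × speed-of-loss plus N(0, 0.005) noise,
and SCP parafoveal PD is 36 − 40 × TL-amount plus N(0, 0.3): monotone
links tight enough that Spearman |ρ| > 0.95 is recoverable, mirroring the
near-perfect published correlations without claiming their exact values.
Follow-up durations are uniform on (1.6, 2.9) years, matching the
published 2.25-year median. The published parafoveal VD/PD cells are
internally inconsistent in scale (values like "0.44 ± 2.36" beside foveal
percentages); densities here are simulated at realistic percentage
levels (~33–36%) consistent with the printed ROI median of 31.3, and
those cells are never used as numeric checks.

**Graders** see the true areas plus iid Gaussian noise truncated at 0;
for a target ICC the noise solves `sd² = sd_true²(1−ICC)/ICC`, which the
tests use to recover ICC ≈ 0.86.

### What passing tests do and do not show

The generator emulates branching capillary geometry, an enclosed
avascular zone, frame-to-frame decorrelation of perfused pixels, and the
group-level distributional structure of the clinical tables. It does not
emulate OCT speckle physics, projection artifacts between plexuses,
motion or segmentation artifacts, vessel-caliber distributions, or
intra-patient correlation among clinical covariates. Recovery results
(Dice ≥ 0.8, PD within 3 percentage points, CFZ within 5%) therefore
certify the measurement chain's correctness on clean vascular imagery,
not its robustness to device-specific artifact — on real angiograms the
binarization parameters would need revalidation against manual grading.

## Numerical choices and degenerate inputs

* Constant images normalize to all zeros with a warning and a degenerate
  flag; the vesselness of a flat image is exactly 0 (the discrete
  second-derivative kernels are mean-centered to make this true).
* All-tied samples give Mann–Whitney p = 1 with a degenerate flag, as do
  all-zero paired differences.
* ICC is flagged undefined at zero between-subject variance.
* Self-intersecting polygons are rejected with the crossing edge pair;
  repeated vertices contribute zero length.
* Every generator takes an explicit seed, restores the caller's RNG
  state, and derives per-stage sub-seeds deterministically (< 2³¹), so
  whole runs are bit-reproducible.

## Problem sizes

Tests and the demo run the full 512 px raster; recovery properties are
checked over 10 seeds, cohort-level direction/power properties over 200
simulated cohorts of 14 + 14 patients, type-I calibration over 2000 null
replicates, and ICC calibration over 100 replicates — sizes chosen so
binomial noise on the checked rates is well inside the asserted margins.

## Known limitations

* The ROI angle is an explicit input; deriving it from B-scan positions
  (device registration) is out of scope, as is retinal-layer segmentation
  producing the SCP/DCP slabs (images are consumed as given; the slab
  label is carried as metadata).
* No projection-artifact removal between plexuses; no skeleton-based
  metrics (none enter the analysis this pipeline reproduces).
* The cohort generator treats each eye's sector densities and CFZ
  metrics as cohort-level draws rather than measuring them from a
  rendered angiogram per patient — the image pipeline is validated
  separately on ground-truthed angiograms; wiring all 28 eyes through
  image rendering would add runtime without adding information about
  either component.
* Multivariate modeling is deliberately absent: at 14 patients per group
  it would be uninterpretable.
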