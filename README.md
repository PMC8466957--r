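# lmhocta

Quantification and statistics for en-face OCT-angiography (OCTA) of
lamellar macular holes (LMH), built around one clinical question: do eyes
whose foveal defect progresses — losing retinal tissue between OCT visits
— differ microvascularly and functionally from morphologically stable
eyes?

The package implements the full measurement chain on calibrated en-face
angiograms and paired B-scan gap contours, and ships a synthetic-data
module that generates every input with known ground truth, so the whole
pipeline is testable end to end without patient data.

## What it computes

**Binary vessel and perfusion maps.** A normalized angiogram is binarized
by fusing three operators: a global white-pixel threshold (intensities in
[0.7, 1.0]), a multiscale Hessian (Frangi-type) vesselness filter, and an
adaptive local-mean threshold; components under 5 px are removed. A pixel
is *perfused* when it is vessel and its inter-frame decorrelation

    D = 1 - mean_t [ 2 f_t f_{t+1} / (f_t^2 + f_{t+1}^2) ]

reaches a threshold (default 0.05) — OCTA's motion-contrast definition of
flowing blood.

**Sector densities.** Vessel density VD and perfusion density PD (percent
of region pixels) over a foveal 1 mm disc and a 2.9 mm parafoveal ring,
each split into four diagonal quadrants; the quadrant colocalized with
tissue loss is the ROI, its neighbours R1/R2, the opposite quadrant R3.

**Capillary free zone (CFZ) morphometry.** Area A, perimeter P, and
circularity

    C = 4 * pi * A / P^2

(1 for a circle, toward 0 as the contour roughens). Contours come either
from manual polygons (JSON) or, on synthetic data, from sub-pixel
marching-squares extraction of the avascular zone.

**Tissue loss.** Per B-scan section, TL = follow-up gap area − baseline
gap area (loss positive); per patient, the sum of the 3 most involved
sections. At least 0.02 mm² classifies the eye as progressive (TL group),
otherwise stable (ST); speed of loss = top-3 sum / interval in years.

**Statistics.** Shapiro–Wilk-gated descriptives and tests (Welch t or
exact Mann–Whitney), Wilcoxon signed rank for paired BCVA/IOP, Fisher /
chi-squared for counts, permutation Spearman correlations (exact for
n ≤ 8), and two-way random-effects ICC(2,1) for grader agreement.

## Worked example

The `analysis/` directory is a five-step narrative over the package
(simulate → binarize → sector metrics → tissue loss → cohort statistics);
each step prints its findings and writes tables under `results/`. A run
of all five steps prints, among other lines:

```
cohort: 28 patients (14 TL / 14 ST)
TL eye: Dice 0.975 | VD 25.82% (truth 27.16%) | PD 20.35% (truth 21.73%)
TL eye: foveal VD 11.60%, PD 10.68% | CFZ A 0.460 mm^2, C 0.51 (truth 0.51)
ST eye: foveal VD 15.96%, PD 8.66% | CFZ A 0.409 mm^2, C 0.60 (truth 0.60)
classified 14 TL / 14 ST; agreement with generator labels 1.00
TL group: median loss 0.084 mm^2, median speed 0.038 mm^2/year
two-grader ICC(2,1) = 0.821 (noise sd 0.0334 mm^2)
tl_amount_vs_scp_parafoveal_pd: rho = -0.9692, p = 1e-05 (mc_permutation)
tl_speed_vs_bcva_change: rho = -0.9824, p = 1e-05 (mc_permutation)
ROI PD median 29.7% vs other quadrants 33.3% (p = 0.0001)
```

Reading this: the binarizer recovers the ground-truth vessel mask at Dice
0.975 and the perfused share within 1.5 percentage points; the recovered
CFZ circularities (0.51 progressive, 0.60 stable) match the values the
contours were generated with; the tissue-loss classifier reproduces every
generator group label; and the simulated cohort reproduces the study's
qualitative findings — lower foveal/parafoveal perfusion in progressive
eyes, the ROI quadrant lowest of the four, and near-perfect monotone
correlations of tissue loss with parafoveal perfusion and of loss speed
with visual-acuity decline.

Or in one call:

```r
library(lmhocta)
run_demo(simulation_config(seed = 1), out_dir = "results/demo")
```

## Layout

- `R/` — the package: synthetic-data generators, binarization, sector
  grid, metrics, tissue loss, statistics, pipeline orchestration.
- `analysis/01_simulate.R` … `05_cohort_stats.R` — the narrative drivers.
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent brute-force oracles.
- `vignettes/octa-quantification.Rmd` — the methods vignette: models,
  parameter choices, generator calibration, limitations.
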