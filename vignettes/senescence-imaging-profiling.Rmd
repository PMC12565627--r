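---
title: "Methods: organelle-level profiling of cellular senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle-level profiling of cellular senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senoscope)
```

## The problem

Cellular senescence is heterogeneous: no single marker separates senescent
from proliferating cells reliably. This package implements a quantitative
imaging pipeline that characterises senescence at the organelle level across
three model systems — fibroblasts from young (YD) and old (OD) donors,
replicatively exhausted cultures (RS, 20+ passages), and genotoxic induction
(doxorubicin, cisplatin, etoposide, bleomycin) under serum starvation. Its
readouts are:

1. **Lysosomal remodelling** from acidotropic-dye intensity (LysoTracker-type
   probes): per-cell, area-normalised intensity distributions summarised as
   multimodal histograms whose local maxima mark lysosomal subpopulations.
2. **Mitochondrial membrane potential** from potentiometric-dye intensity
   (MitoTracker-type probes): per-cell mean densities segmented into
   depolarised / mid / hyperpolarised fractions at data-driven thresholds.
3. **Population-level senescence scores**: the SA-β-Gal positive fraction
   S%, relative survival V%rel, and the selectivity index
   SI = S% / (100 − V%rel).

## Area normalisation

Senescent cells spread: raw integrated fluorescence confounds organelle
content with projected area. Every intensity readout is therefore divided by
the cell's 2-D projected area (mask pixel count × squared pixel size, µm²),
giving intensity densities in a.u./µm². The lysosomal arm uses the full
*per-pixel* density distribution of each cell (thousands of events per
cell); the mitochondrial arm uses one *per-cell* mean density (integrated
intensity / area), a morphology-independent proxy for Δψ~M~ density. Masks
are treated as filled regions; an optional fill step (`load_mask(fill =
TRUE)`) handles outline-style masks, since an outline has near-zero area and
would corrupt the normalisation. Mask rasters are thresholded at 50% of
their maximum value, which is robust to 8- versus 16-bit encodings. Stacks
are reduced before quantification: 4-D (channel, z, y, x) arrays have
channel 1 summed over z; 3-D arrays contribute channel 1; the isotropic
pixel size is the mean of the per-axis physical sizes when both are present.

Accepted inputs are plain TIFF (multi-page = channel stack), PNG masks,
in-memory arrays, and a sidecar JSON (`<image>.json`) carrying
`pixel_size_x_um` / `pixel_size_y_um`. Condition labels always come from a
manifest CSV, never from filename parsing.

## Histogram profiling and peak detection

Per-condition profiles bin all positive densities into `n_bins` log-spaced
intervals, count per cell, and average across cells (counts · bin⁻¹ ·
cell⁻¹). Log spacing cannot include zero, so the lower edge is the smallest
positive observed value × (1 − 10⁻⁶); zero-intensity events are excluded
and their count is logged on the profile and in the run log.

Local maxima are detected on the raw curve by **topographic prominence**
(height above the higher of the two key saddles, exhaustive valley search)
and **minimum distance** (greedy pruning by descending height). Plateaus
report their left-most bin. Peaks are reported at bin centres on the log10
axis, ascending, with ordinals 1..k. Defaults: 30,000 bins, prominence 2% of
the maximum mean count, minimum distance 1% of the bin count, no smoothing.
All are configurable, and positions are invariant to vertical rescaling of
the curve when the prominence threshold is rescaled with it.

**Desk-scale settings.** The defaults above suit full-scale data
(10⁴–10⁵ in-mask pixels per cell). The bundled synthetic scenario runs at
desk scale — 200 cells × 500 events per condition — where a 30,000-bin
histogram holds ~3 events per bin and per-bin Poisson noise (~30% relative)
would mint spurious maxima. The scenario therefore declares its own
analysis settings: 3,000 bins, a 51-bin moving-average smoothing window
(≈ 0.046 log10 units, well under the component log-SD of 0.15, so it
attenuates noise without shifting symmetric peaks), prominence 5% of the
maximum, distance 1%. With these, the two-component recovery error is
≈ 0.02 log10 units (RMSE).

## The peak-position mixed model

Peak positions are modelled as

log10 X~peak~ ~ donor + inducer + peak_id + (1 | curve)

with donor ∈ {YD, OD, RS}, inducer ∈ {C10, C1, Doxo, Cis, Eto, Bleo}, the
peak ordinal as a numeric covariate (successive maxima occur at higher
positions; a monotone trend is the scientific claim), and a per-curve random
intercept absorbing the dependence of several peaks measured on one curve
(staining efficiency, confluence, acquisition settings). One curve = one
(donor, inducer) histogram. The donor reference is YD; the inducer reference
defaults to C10 and is configurable, because control naming is ambiguous
between the serum conditions (both a 10% and a 1% serum control exist).

**Interval estimation.** The default inference is REML with Kenward-Roger
adjusted standard errors and degrees of freedom (Satterthwaite fallback;
`df_method = "wald"` gives the plain maximum-likelihood fit with z
intervals). This is a deliberate choice: at the bundled design's scale
(60 curves, curve-intercept SD 0.1, residual SD 0.05), simulation shows
plug-in Wald z intervals cover the true fixed effects only 90–94% of the
time at nominal 95%, because they ignore variance-component uncertainty;
Kenward-Roger restores 94–96.5% coverage. Diagnostics follow the pipeline's
conventions: Shapiro–Wilk on conditional residuals, Brown–Forsythe/Levene
(median-centred) on the donor groups, with the degenerate all-constant case
reported as statistic 0, p = 1.

## Distribution-shape comparison

Within each inducer, the donors' peak-position samples are compared with the
k-sample Anderson–Darling test (Scholz–Stephens, midrank/tie-adjusted
variant), sensitive to centre, shoulder and tail differences. The package
implements the statistic, its null standardisation, and the tabulated
critical-value interpolation directly (no installed R package provides it);
p-values outside the tabulated range [0.001, 0.25] are clamped and flagged
as approximate. An inducer enters the test only when **every** donor
subgroup contributes at least 2 peaks; failures are reported as exclusions,
not errors. Raw p-values are Benjamini–Hochberg adjusted across included
inducers. The output carries a standing caveat: peaks from one curve enter
the test as if independent, so main-factor inference should rest on the
mixed model.

## CDF inflexion-point segmentation

Per-cell mitochondrial mean densities X are summarised as an empirical CDF
α(u), u = log10 X, scaled to 0–100% of cells on a uniform 1,000-point grid.
The derivative dα/du — the population density on the log axis — is
estimated by central differences, smoothed by a moving average, and its
local maxima are the thresholds θ₁ < θ₂ (by construction these sit at the
density modes). Fractions are evaluated from the **exact** empirical CDF at
θ, not the gridded curve, to avoid grid bias:

Δψ₁ = α(θ₁), Δψ₂ = α(θ₂) − α(θ₁), Δψ₃ = 100 − α(θ₂),

which sum to 100 for every curve. Cells are labelled depolarised / mid /
hyperpolarised by the same cuts, so classified percentages match the
fractions exactly. Condition comparisons are pure redistributions of these
percentages; changes of ≤ 5 percentage points are reported as not
significant, and the three deltas of any comparison sum to zero. The
three-segment partition (from two thresholds) is the implemented form; the
pipeline surfaces this as its segmentation convention.

Numerical choices, all config-exposed: smoothing window 5% of the grid
(at a few hundred cells, a 2% window lets derivative noise bumps through —
see below), prominence floor 25% of the maximum smoothed derivative,
prominence ranking when more than two maxima pass. Degenerate inputs are
defined outcomes: exactly one maximum → two-segment fallback (Δψ₃ unset);
no interior maximum (flat or monotone density, e.g. a uniform-in-u sample)
→ single-population flag with fractions (100, 0, 0).

The noise analysis behind the window: with n cells and an effective window
of width W in u, the relative error of the derivative estimate is
≈ √(100 / (f · n · W)) for density level f (%/u). At n = 500 and W ≈ 0.07
(2% window), bumps of ~30% relative prominence appear and pass a 25% floor;
W ≈ 0.15 (5% window) keeps them under it while shifting symmetric modes by
nothing and costing ~0.05 u in mode-location resolution — acceptable
against the component log-SD of 0.25.

## Senescence scoring

S% is computed per visual field and summarised as mean ± SE **across
fields** (fields are the replication unit; a pooled binomial SE would
understate between-field variation). V%rel is each treated field's total
divided by the mean control total, × 100; values above 100 are legal
everywhere except the selectivity index, where SI = S% / (100 − V%rel) is
returned as an explicitly undefined result (with reason) when survival
reaches 100%. Flow summaries report the median fluorescence intensity and
IQR with linear-interpolation quartiles (R type 7), declared in the output.

## The synthetic scenario

Raw study images are not deposited, so validation runs on a generator whose
defaults *are* the emulated study conditions:

- **Lysosomal arm**: per (donor, inducer) curve, events from a 1–3-component
  lognormal mixture. Component log-modes are base (0.6) + donor offset
  (YD 0, OD +0.3, RS +0.5) + inducer offset (C10 0, C1 +0.10, Doxo +0.12,
  Cis +0.18, Eto +0.08, Bleo +0.22) + 0.4 × component index, shifted by a
  per-curve N(0, 0.1) intercept; component log-SD 0.15; 200 cells × 500
  events (the study averaged 95–600 cells per condition). Offsets are
  calibration constants chosen so that age and induction shift peaks
  upward detectably at desk scale; they are configuration, not biological
  claims. Peak-observation draws for model validation use the same linear
  structure with residual SD 0.05 and random 1–3 peaks per curve (a cyclic
  assignment would alias peak count with the condition grid).
- **Mitochondrial arm**: per-cell densities from a bimodal lognormal
  mixture, modes at u = 1.0 and 2.5, SD 0.25, weights (0.3, 0.7), 500
  cells; the analytic mixture CDF is attached so recovered fractions can be
  compared to truth at any threshold.
- **Scoring arm**: field totals Poisson around the per-field load scaled by
  true survival; positives binomial around true S% (defaults 2.5 / 9.1 /
  16.3% for YD / OD / RS, the magnitudes reported for young, old and
  replicatively exhausted fibroblast populations); flow events lognormal
  with the condition MFI as median.
- **Image arm**: non-overlapping elliptical cells of known pixel area
  painted with mixture intensities, written as 16-bit TIFF + PNG masks +
  sidecar JSON + manifest, with exact per-cell ground truth.

Seeding: one parent seed fans out to named streams through a
Lehmer-avalanche child-seed function, and every generator discards one full
Mersenne-Twister block after seeding — nearby raw seeds otherwise produce
correlated first draws, which is visible as spurious bias when averaging
across many replicate seeds. Identical spec + seed gives byte-identical
outputs end to end.

**What the generator does not emulate**: optics (PSF, camera noise,
photobleaching, background), segmentation error, spatial intensity
structure within cells, and any correlation between the lysosomal,
mitochondrial and scoring arms. Passing tests therefore demonstrate that
the *computational* pipeline recovers known distributional structure, not
that the biological claims hold on real images.

## Problem sizes and limitations

The bundled scenario runs 18 conditions × 200 cells × 500 events
(lysosomal), 500 cells per condition (mitochondrial), 5 fields × ~200 cells
(scoring); validation suites use up to 100 mixed-model replicates and 1,000
Anderson–Darling null replicates. These sizes were chosen so a full
validation pass completes on a laptop-class single core in a couple of
minutes while keeping every recovery margin comfortably resolved.

Known limitations: peak detection near the prominence threshold is
sensitive to floating-point-scale perturbations (ties are broken
deterministically: height, then prominence, then index); adjacent mixture
components closer than ~3 log-SDs shift each other's density modes inward,
so "true mode" comparisons use the realised mixture, not component means,
where that matters; the Anderson–Darling p-value is interpolated from
tabulated critical points and clamped outside [0.001, 0.25]; and the
selectivity index is undefined without net cell loss — by design, not
failure.
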