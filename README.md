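# senoscope

Quantitative organelle-level profiling of cellular senescence from
fluorescence microscopy.

Senescent cells remodel their lysosomes and mitochondria long before any
single marker becomes definitive. `senoscope` turns masked single-cell
fluorescence images into population-level, statistically testable readouts
of that remodelling, for three classic model systems: fibroblasts from young
(YD) and old (OD) donors, replicative senescence by serial passaging (RS),
and genotoxic induction (doxorubicin, cisplatin, etoposide, bleomycin) under
serum starvation.

## What it computes

**Area-normalised intensity densities.** Raw fluorescence inside a manually
drawn cell mask is divided by the cell's 2-D projected area (pixel count ×
pixel size², µm²), giving densities in a.u./µm² that decouple organelle
content from cell spreading. Per-pixel densities feed the lysosomal arm;
per-cell mean densities feed the mitochondrial arm; a nuclear/cytoplasmic
mean-intensity ratio gives p16 enrichment.

**Lysosomal subpopulation peaks.** Densities are binned into log-spaced
intervals (30,000 by default), counted per cell and averaged across cells.
Local maxima of the resulting curve — detected by topographic prominence
and minimum peak distance — mark lysosomal subpopulations. Peak positions
(log₁₀ X_peak) are modelled with a linear mixed model,

    log10_xpeak ~ donor + inducer + peak_id + (1 | curve)

whose random intercept absorbs the dependence of peaks measured on the same
curve. Distribution shapes across donors are compared per inducer with the
k-sample Anderson–Darling test (inducers lacking ≥ 2 peaks in any donor
subgroup are excluded, as a result, not an error), under Benjamini–Hochberg
FDR control.

**Mitochondrial membrane-potential fractions.** Per-cell mean densities are
summarised as a cumulative curve α(u), u = log₁₀ X, and segmented at the
inflexion points θ₁ < θ₂ (local maxima of dα/du) into depolarised, mid and
hyperpolarised fractions Δψ₁ = α(θ₁), Δψ₂ = α(θ₂) − α(θ₁),
Δψ₃ = 100 − α(θ₂), which sum to 100 for every curve. Condition effects are
reported as redistributions of these fractions; |Δ| ≤ 5 percentage points
counts as not significant.

**Senescence scores.** Field-level SA-β-Gal positive percentages (S%, mean ±
SE across fields), relative survival versus control (V%rel), the selectivity
index SI = S% / (100 − V%rel), and flow-cytometry MFI ± IQR summaries.

A seeded synthetic-data generator emulates all of these inputs with known
ground truth (lognormal mixtures with donor/inducer/peak-order structure,
bimodal mitochondrial populations, binomial field counts, painted cell-field
images), so the entire pipeline is validated end to end without any
microscope data.

## Worked example

```r
library(senoscope)
rep <- run_pipeline(list(seed = 42, out_dir = "senoscope_run"))

head(rep$peaks[, c("curve_id", "peak_id", "log10_position", "prominence")], 4)
#>   curve_id peak_id log10_position prominence
#> 1   YD_C10       1          0.958     0.0849
#> 2   YD_C10       2          1.345     0.4183
#> 3   OD_C10       1          1.345     0.3818
#> 4   OD_C10       2          1.681     0.0942

rep$lmm$fixed_effects[, c("term", "estimate", "se", "df", "p")]
#>          term estimate     se    df        p
#> 1 (Intercept)    0.645 0.1049 11.91 5.15e-05
#> 2     donorOD    0.451 0.0870 10.08 4.03e-04
#> 3     donorRS    0.513 0.0868  9.98 1.51e-04
#> 4 inducerBleo    0.211 0.1227  9.96 1.17e-01
#> 5   inducerC1    0.142 0.1227  9.96 2.73e-01
#> 6  inducerCis    0.209 0.1231 10.08 1.21e-01
#> 7 inducerDoxo    0.179 0.1231 10.08 1.77e-01
#> 8  inducerEto    0.153 0.1231 10.08 2.42e-01
#> 9     peak_id    0.304 0.0210 19.17 8.98e-12

subset(rep$mito, donor == "YD")[1:3, ]
#>   donor inducer theta1 theta2 dpsi1 dpsi2 dpsi3 n_cells
#> 1    YD     C10  1.077   2.44  17.6  41.0  41.4     500
#> 2    YD      C1  1.029   2.53  14.8  47.2  38.0     500
#> 3    YD    Doxo  1.008   2.52  13.0  53.2  33.8     500

rep$scores
#>   condition S_percent  S_SE V_rel    SI SI_defined
#> 1   control      1.05 0.404 100.0    NA      FALSE
#> 2        YD      2.03 0.399  93.3 0.304       TRUE
#> 3        OD      8.63 0.512  85.1 0.581       TRUE
#> 4        RS     18.67 1.084  69.0 0.603       TRUE
```

Reading the output: each (donor, inducer) curve yields one to three ordered
peaks; the mixed model estimates that OD and RS peaks sit ~0.45 and ~0.51
log₁₀ units above YD (the generating scenario plants +0.3 and +0.5, within
the intervals at 18 curves), and successive peaks climb by ~0.30 per
ordinal. The mitochondrial table gives each condition's thresholds and
fraction triple (each row sums to 100). The score table recovers the
scenario's planted S% gradient (2.5 / 9.1 / 16.3%) and marks SI undefined
for the control compared with itself (no net cell loss). Every table is
also written as CSV under `out_dir`, alongside `diagnostics.json` and
`run_log.txt`; `render_figures(rep)` draws the profile panels (shared axis
limits across conditions), stacked fraction bars and peak box summaries
from those same tables.

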