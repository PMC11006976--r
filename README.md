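# seedtol

Seed germination stress-tolerance indices and trait–environment analysis for
multi-population common-garden germination assays.

## The problem

Dryland shrub populations are routinely compared by how well their seeds
germinate under drought (PEG-6000 osmotica), cold and saline-alkali stress.
A standard design sows 50 seeds per dish, 3 replicate dishes per population,
across five graded levels of each stress, and counts newly germinated seeds
daily for up to 15 days. `seedtol` turns those counts into severity-weighted
tolerance indices and carries them through the downstream population-biology
analyses: among-population variation, geographic gradients, environmental
attribution, mixed models of seed intrinsic attributes, and a recursive path
model of the whole causal system.

## The indices

The germination index of a dish is the speed-weighted count

GI = Σ_d n_d / t_d,

where n_d seeds germinate on day t_d. Each treatment level i carries a
severity weight — D_Ri = 1 + |W_i| for water potential W_i (MPa),
C_Ri = T_1 / T_i for temperature T_i below the 25 °C control,
S_Ri = S_i / 10 for saline concentration S_i (mmol/L), with the control
level of every experiment fixed at weight 1 — and each tolerance index is
the weighted mean over the five levels:

GDTI = (Σ_i GI_i · D_Ri) / 5, GCTI = (Σ_i GI_i · C_Ri) / 5,
GSTI = (Σ_i GI_i · S_Ri) / 5.

Germinating well *under severe stress* is thus rewarded more than
germinating well in the control. Indices are per dish-set (not normalized by
dish size), so they are comparable only at equal seeds per dish.

Downstream, the package provides per-trait variation summaries (min, max,
Max/Min, mean, CV, one-way ANOVA across populations), simple regressions of
population-mean traits on latitude/longitude/altitude, standardized multiple
regressions on climate (MAT, MAP) and soil (SOC, AN, AP, pH) predictors,
random-intercept linear mixed models fitted by profile REML with a
commonality-style decomposition of explained variation between morphology
and nutrient blocks, and a recursive path model over first-PC block
composites with ML fit indices (χ², GFI, CFI, RMSEA).

Because raw field data of this kind are rarely public, a synthetic-data
generator (`simulate_dataset()`) emulates the full design — 21 sites in the
Qinghai-Tibetan envelope (35.83–38.32 °N, 90.86–102.76 °E, 1,866–3,832 m,
MAP 67–427 mm, MAT −1.5–8.3 °C), causally structured traits, and dish-level
daily counts from a discrete-hazard germination model — so every stage is
testable end to end.

## Worked example

```r
library(seedtol)

sim <- simulate_dataset(simulation_config(random_seed = 1))
head(sim$indices, 3)
#>   population_id replicate  GDTI  GCTI  GSTI
#> 1           P01         1 10.95 20.48 40.76
#> 2           P01         2 14.61 22.55 40.66
#> 3           P01         3 14.38 22.88 36.89

tab <- trait_variation_table(sim$traits, digits = 2)
tab[tab$trait %in% c("TGW", "GDTI"), ]
#>   trait minimum maximum max_min_ratio  mean cv_percent df f_statistic  p_value
#> 4   TGW    0.32    0.87          2.70  0.58       21.5 20        27.7 4.89e-18
#> 9  GDTI   10.95   38.84          3.55 22.17       26.6 20        41.0 2.59e-21
```

Population P01's first dish set has GDTI ≈ 11: its seeds germinate, but slowly
and mostly at mild water potentials. The variation table mirrors the usual
report layout: each row is one trait, `max_min_ratio` is the spread between
the extreme populations, `cv_percent` the coefficient of variation, and the
F test (here on 20 between-population degrees of freedom) asks whether
populations differ at all.

```r
pa <- path_analysis(sim$traits, sim$sites)
pa$coefficients[pa$coefficients$to == "GDTI", ]
#>         from   to estimate  se p_value significance_class
#> 5    climate GDTI    0.414 0.2   0.053                 ns
#> 6 morphology GDTI    0.311 0.2   0.137                 ns
pa$fit
#> chi^2 = 13.47 on 9 df, GFI = 0.871, CFI = 0.923, RMSEA = 0.158
```

Here climate and seed morphology both push the drought-tolerance index
upward (standardized paths 0.41 and 0.31), though neither clears p < 0.05 at
n = 21 populations; the fit indices judge how well the sparse causal graph
reproduces the 7 × 7 composite covariance matrix.

`run_all(trials, traits, sites, out_dir = "out/")` chains every stage and
writes `indices.csv`, `summary.csv`, `gradients.csv`, `env_attribution.csv`,
`lmm_*.json`, `sem_fit.json`, `sem_effects.csv` and a run manifest.

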