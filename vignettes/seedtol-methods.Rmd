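---
title: "Methods: germination stress-tolerance indices and their downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination stress-tolerance indices and their downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtol)
```

# The measurement model

A germination assay exposes dishes of 50 seeds to five graded levels of one
stress — water potentials of 0 to −1.2 MPa imposed with PEG-6000,
temperatures of 25 down to 5 °C, or saline-alkali concentrations of 0 to
200 mmol/L — and counts newly germinated seeds daily for up to 15 days. Two
quantities summarise a dish:

* the **germination index** GI = Σ_d n_d / t_d, which rewards early
  germination (a seed on day 1 counts fully, a seed on day 10 counts a
  tenth);
* a **severity weight** per treatment level: `1 + |W|` for drought,
  `T1 / T` for cold, `S / 10` for salinity, with every control level fixed
  at 1 so weights are ≥ 1 and increase with severity.

Each tolerance index (GDTI, GCTI, GSTI) is the mean of GI × weight over the
five levels. Germination retained under severe stress therefore contributes
multiplicatively more than control germination.

Two genuinely open readings had to be settled:

* **The saline index.** We compute GSTI with the same structure as the other
  two indices, `(Σ_{i=1..5} GI_i S_Ri)/5`, including the control term with
  its unit weight. This keeps the three indices structurally identical and
  honours the stated role of the 0 mmol/L level as the standard control. The
  alternative reading that drops the control's GI term is available via
  `gsti_literal = TRUE` and differs from the default by exactly GI₁/5.
* **Replicate pairing.** Nothing forces a choice between weighting each
  replicate's GI separately or averaging GI over replicates first. The
  default (`aggregation = "per_replicate"`) pairs replicate r across the
  five levels, because the downstream ANOVA needs within-population
  replication; `"population_mean"` averages first. Since the index is linear
  in GI, the population mean of per-replicate indices equals the index of
  mean GI — the choice matters only for replicate-level analyses, not for
  population means.

Day numbers are 1-based counting days; a trial terminated early simply has a
shorter count vector. Indices are deliberately *not* normalised by dish
size: they are comparable only between assays with equal seeds per dish.

# Descriptive statistics and regressions

`summarize_trait()` reports min, max, Max/Min, mean and CV. The CV uses the
sample standard deviation (n − 1), the standard choice in trait-variability
work. `one_way_anova()` groups by population with replicates as
observations. Gradient regressions (`gradient_panel()`) are ordinary least
squares on population means — one point per population, matching how such
results are plotted — with a replicate-level mode behind a flag. A constant
response is returned as a flat fit (slope 0, R² 0, p 1) rather than an
error, so degenerate synthetic traits cannot halt a panel; a constant
*predictor* is always an error.

`fit_multiple_regression()` enters all six environmental predictors (MAT,
MAP, SOC, AN, AP, pH) simultaneously — no stepwise selection — and by
default standardizes both response and predictors, so coefficients are
comparable across predictors and the significance tiers (which include the
marginal p < 0.1 tier) can be displayed heat-map style. A raw-coefficient
mode is available; note that with a raw response the coefficient on a
z-scored predictor estimates the generating slope directly, whereas the
fully standardized coefficient is that slope divided by the response SD —
both modes are exercised in the tests.

# The mixed model

The three index-on-attributes models are random-intercept LMMs,
y = Xβ + b_pop + e. We fit them by **profiling the REML criterion over the
variance ratio** λ = σ²_pop/σ²_e: because the random design is a group
indicator, V(λ) = I + λZZᵀ is block diagonal, V⁻¹ and log|V| have closed
group-wise forms, and the whole fit reduces to `optimize()` over log λ on
[−8, 8] in log₁₀ units (tolerance 1e−9) plus an explicit λ = 0 boundary
evaluation. Variance estimates are clipped at the boundary and flagged
`singular`, never negative. On balanced one-way data this reproduces the
ANOVA method-of-moments estimators ((MSB − MSW)/n₀ and MSW), which the test
suite verifies to 1e−6, and the profile optimum is checked against a
101-point λ grid.

Fixed-effect p values use t statistics with n − p − g + 1 residual degrees
of freedom (p counting the intercept, g the number of groups). This is a
deliberate approximation: a Satterthwaite correction is out of scope, and
the suite checks agreement with `lmerTest` on a balanced fixture.

"Effect decomposition" between the morphology block (length, width, LWR,
TGW) and the nutrient block (CSP, CSS, CS, CCF) is not uniquely defined in
the field, so the package implements a **commonality-style partition of the
marginal R²** (variance of Xβ̂ over total variance): each block gets its
unique increment plus half of the common portion, normalized to sum to 1.
An alternative based on summed absolute standardized coefficients is
available via `method = "abs_coef"`. Shares from either method are
descriptive, not a reproduction claim for any particular published
percentage.

# The path model

Blocks (climate, soil, morphology, nutrients) enter as **first principal
component scores** of their z-scored variables. PCA signs are arbitrary, so
each component is oriented to make the sum of its loadings positive (tie
broken by the first variable's loading), giving deterministic,
"more = more" composites.

The structural model is fully recursive, so per-equation OLS on z-scored
variables *is* the maximum-likelihood estimator; no iterative covariance
fitting is needed. The implied covariance is assembled as
(I − B)⁻¹ Ψ (I − B)⁻ᵀ with the exogenous (climate–soil) block fixed at its
sample covariance and residual variances computed with the same n − 1
denominator as the sample covariance — which is exactly why a saturated
(just-identified) specification reproduces S and scores χ² = 0, df = 0,
GFI = CFI = 1, RMSEA = 0. Fit indices follow the standard ML discrepancy;
the CFI baseline is the conventional independence model (all covariances
zero, variances free). Total effects come from (I − B)⁻¹ − I, so
total = direct + indirect holds identically. The default edge set encodes:
soil → morphology and nutrients, climate → nutrients (plus an estimated
climate → morphology path), climate and morphology → GDTI and GSTI, and
climate, soil and nutrients → GCTI; it is a plain edge-list object the user
can replace.

# The synthetic-data generator

The generator is the package's stand-in for unpublished field data and
defines the study conditions under which everything is tested: 21 sites
uniform in the 35.83–38.32 °N × 90.86–102.76 °E × 1,866–3,832 m envelope,
MAP rising linearly eastward within 67–427 mm and MAT falling with altitude
within −1.5–8.3 °C (Gaussian noise, clipped); soil chemistry driven by a
climate composite; trait blocks driven by the configured structural
coefficients with population intercepts and replicate noise, then mapped to
realistic mean/CV scales (e.g. TGW 0.55 g at 23 % CV); and LWR computed as
length/width. Germination follows a **discrete daily hazard**
`base_hazard × exp(tolerance_effect × latent tolerance) × exp(−sensitivity × severity)`,
with counts as binomial draws over the seeds still ungerminated — matching
daily counting rather than continuous time-to-event. The latent tolerance
enters the hazard, not the index arithmetic, so index magnitudes are
produced by the same weighting code the package ships; tests confirm the
Spearman link between latent tolerance and computed indices rather than
asserting equality. The optional five-zero-day stopping rule is off by
default so fixtures are rectangular.

What the generator does **not** emulate: spatial autocorrelation, real seed
physiology (dormancy, viability loss), measurement error structure of
microscopy or assay kits, and any particular published dataset. Passing
tests therefore demonstrate the estimators' correctness and calibration on
data with the assumed causal and noise structure — not that any specific
field result is recovered.

# Problem sizes and numerical choices

The test suite and acceptance script use: 21 populations × 3 replicates for
pipeline checks; 500 populations for environmental and mixed-model recovery
(the latter on z-scored predictors, averaged over 5 generator seeds, since a
single draw's standard error is comparable to the ±0.1 check); n = 2000 for
path-effect recovery; and 100 seeded null runs for the α = 0.001 gradient
false-positive rate. The REML profile uses `optimize()` at tolerance 1e−9;
λ at the lower search bound is reported as a boundary fit. Covariance
matrices entering `fit_indices()` must be symmetric positive definite
(checked by eigenvalues); RMSEA is defined as 0 at df = 0; F_ML is floored
at 0 against round-off.

# Known limitations

* Indices are dish-size dependent by construction; compare only at equal
  seeds per dish.
* Mixed-model p values are approximate (no Satterthwaite df).
* The block decomposition is one defensible definition among several.
* The path model handles observed composites only — no latent measurement
  model, bootstrap errors or model search.
* With 21 populations the path model is powered only for large effects; the
  generator's defaults reflect that honestly (wide p values at n = 21).
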