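---
title: "From sward cuts to quality-adjusted yield and Euro: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sward cuts to quality-adjusted yield and Euro: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqyield)
```

This vignette documents the modelling choices behind `gqyield`: what is
estimated, what the synthetic generator does and does not emulate, and the
numerical conventions a user relying on the results should know about.

## The estimation problem

A grassland diversity–management experiment crosses sown species richness
(D ∈ {1, 2, 4, 8, 16, 60}, replicated 16/16/16/16/14/4 over 82 main plots
in 4 blocks) with five management intensities per plot: extensive (1 cut,
no N), less intensive (2 cuts, no N), intensive (2 cuts, 100 kg N ha⁻¹ a⁻¹),
highly intensive (4 cuts, 100 N) and very highly intensive (4 cuts, 200 N).
One plot × regime combination is a *sward*; 82 × 5 = 410 swards. (Field
descriptions of this layout sometimes count 390 units by treating the four
managed subplots separately from the core area; the generator enumerates
all 410 plot × regime combinations.)

The response chain is:

1. **Per-cut chemistry → nutritive value.** Metabolizable energy and net
   energy for lactation come from the gas-test estimation equations (see
   `metabolizable_energy()`; all coefficients positive, so both are
   increasing in gas, crude protein and ether extract, and ME > NEL
   termwise). Milk production potential is NEL divided by the energy
   requirement per kg milk. Utilizable crude protein uses the incubation
   ammonia balance and exists only for the first cut.
2. **Cuts → annual sward values.** Annual biomass yield is the sum over
   cuts; annual quality the biomass-weighted mean; quality-adjusted yield
   the sum of biomass × quality with a g→kg conversion, hence MJ (or g,
   or kg milk) m⁻² a⁻¹. These three satisfy the exact identity
   qa_yield = biomass_yield × quality / 1000, which the tests enforce to
   machine precision.
3. **Annual values → diversity effects.** A linear mixed model with one
   √D slope per management, legume × management, functional-group and
   group-presence covariates, and random intercepts for block and plot.
4. **Effects → Euro.** Milk-potential yield × milk price versus itemized
   variable costs of intensification or diversity restoration.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `nel_per_kg_milk` | 3.2 | MJ NEL kg⁻¹ milk | energy requirement per kg milk; a calibration constant consistent with ME-yield vs milk-potential magnitudes of roughly 9.6 MJ m⁻² ↔ 1.8 kg m⁻². It is *not* measurable from these data; milk numbers scale inversely with it. |
| `min_biomass` | 1 | g DM m⁻² | "very small biomass" is not a quantified notion in field protocols; the filter threshold is configurable and every removal is reported with a reason and a per-richness histogram, so the choice is auditable. |
| `milk_price` | 0.31 | Euro kg⁻¹ | two-year German average used for valuation; revenue is exactly proportional to it. |
| `diversity_form` | `"sqrt"` | — | allows a diminishing diversity effect; challenged against linear, linear+quadratic, log and 1/D by AIC/BIC on ML fits over the identical observation set. |
| `n_tests` | 6 / 1 | — | Bonferroni family size: six forage-quality variables per family, one for biomass yield. |

## What the generator emulates — and what it does not

`simulation_params()` encodes the data-generating process the model
assumes: per-management intercepts and √D slopes for annual biomass,
per-management legume effects, small functional-group and group-presence
effects, Gaussian block (σ_B = 40), plot (σ_P = 60) and per-cut residual
(σ_e = 80 g DM m⁻²) noise, and 2% randomly missing cut records. Defaults
were chosen once to resemble a temperate floodplain meadow: monoculture
annual yields of 250–600 g DM m⁻² rising with management intensity,
diversity slopes of 60–120 g m⁻² per √species (largest under intensive
management), and first-cut chemistry around 48 mL gas day⁻¹, 160 g CP,
25 g EE, 440 g NDF and 85 g ash kg⁻¹ DM.

Two structural choices deserve emphasis:

* **Per-cut biomass is the annual structure divided by the cut count plus
  per-cut noise.** The model is specified on annual sums, which leaves
  within-year allocation free; equal split is the least informative
  choice. A by-product is residual heteroscedasticity across regimes
  (annual residual SD σ_e/√h), which is exactly the situation the robust
  covariance is there for.
* **Chemistry noise is drawn at the sward level, with a deterministic
  linear per-cut trend** (gas and CP declining, NDF and ash rising,
  sign-constrained in the constructor). Monotone seasonal change is the
  empirical fact that licenses linear interpolation of quality between
  the first and last analysed cut; per-cut chemistry noise would break it.
  Consequently the generator cannot test robustness of the interpolation
  step to non-monotone seasons — a real-data feature outside its scope.

Also not emulated: species identity (only functional-group composition
enters any downstream equation), weeding dynamics and species loss,
spatial autocorrelation or soil gradients within blocks, and any
systematic placement effect of the extensive subplots at plot margins
(absorbed by block/plot random effects). Passing tests therefore certify
the estimation machinery under the model's own assumptions, not the
field validity of those assumptions.

## Numerical and inferential choices

* **Random structure.** Block and plot enter as random intercepts
  (`(1|block) + (1|plot_id)`); plot labels are unique so this realizes
  plots nested in blocks, matching the field layout. REML estimates are
  reported; AIC/BIC come from an ML refit.
* **Robust covariance.** "Robust standard errors" admits many estimators.
  We use a cluster-robust sandwich with plots (82) as clusters and a
  working within-plot covariance σ²_e I + (σ²_P + σ²_B) J. The plain CR0/CR1
  forms showed the well-documented downward bias in designs with a few
  high-leverage clusters — here the four 60-species plots — inflating the
  pairwise Wald type-I error to ~8.6% at nominal 5%. The implementation
  therefore uses the CR2 bias-reduced linearization with Bell–McCaffrey
  Satterthwaite degrees of freedom, whose measured size in the test suite
  is within [3.5%, 6.5%]. Model-based standard errors are reported
  alongside for transparency.
* **Degenerate data.** Noise-free input (an exact linear fit) makes the
  mixed-model likelihood ill-defined; `fit_diversity_model()` detects it
  and switches to ordinary least squares with zero variance components,
  preserving the fixed-point property that generated coefficients are
  recovered exactly.
* **Prediction covariate policy.** Functional groups, legume presence and
  group flags co-vary with richness by design, and no canonical choice
  exists for where to hold them when drawing diversity gradients.
  `predict_diversity_grid()` makes the policy explicit: `"mean"` (grand
  means; smooth curves, the default), `"design"` (within-richness means)
  or `"fixed"` (user values). Management-equivalence calculations use the
  same policy, so the reported revenue gaps inherit it.
* **Interpolation index.** Equal spacing over cut number, not calendar
  date — dates are not part of the data model.
* **Rounding.** All ledgers are computed at full precision; whole-Euro
  figures are display conventions. Management-switch totals additionally
  report the printed convention of rounding each unit cost (165 / 9 / 77
  Euro) before multiplying by counts, because that is how the headline
  −174 / −493 Euro figures are conventionally quoted; the full-precision
  totals (−173.69 / −493.62) are always available in the ledger.
* **Welch test.** `welch_test()` is provided as the unequal-variance
  comparison utility for predicted revenue samples between two
  managements; it deliberately stays a thin, well-defined primitive
  because its exact role alongside the mixed model is a choice the
  analyst must make per question.
* **uCP.** Measured at the first cut only; its annual value is the
  first-cut value and its "yield" uses first-cut biomass, flagged
  `ucp_first_cut_only` so it is never silently mixed with full-year
  yields. Negative uCP values (ammonia balance exceeding blank + sample
  N) are physically impossible, so they are flagged with a warning rather
  than clipped.

## Simulation sizes used by the test suite

The statistical guarantees are checked at the full design size (82 plots,
410 swards): 500 replicate experiments for slope recovery (each slope's
mean within 2 Monte-Carlo SEs of truth), 200 replicates for functional-
form selection (√D first by BIC in ≥ 90%), 2,000 null replicates for the
pairwise Wald size ([3.5%, 6.5%] at nominal 5%), and 1,000 random swards
for the aggregation identity. These sizes keep the whole suite in the
minutes range on a single core while leaving Monte-Carlo error well below
the tested margins.

## Known limitations

* Reproducing the coefficients of any particular field campaign requires
  that campaign's data; the package validates machinery, not field
  estimates.
* The milk conversion coefficient is a calibration, so absolute milk and
  revenue levels carry its uncertainty (effects scale linearly with it).
* Single-year scope: no carry-over effects, reseeding dynamics, or
  multi-year price risk.
* The cost ledger covers variable costs only — no machinery depreciation,
  land or opportunity costs beyond the hay-transfer donor compensation,
  and no subsidy modelling.
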