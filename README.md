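# gqyield

Quality-adjusted yield and bioeconomics of managed grassland diversity
experiments.

Agronomic assessments of grassland biodiversity usually stop at biomass.
This package carries the analysis through to what the biomass is *worth*:
it converts per-cut sward measurements into forage nutritive values,
aggregates them into annual quality-adjusted yields, estimates how those
yields respond to sown plant diversity under contrasting management
intensities, and values the response in milk revenue against the variable
costs of intensification or diversity restoration. It is written for
quantitative ecologists and agricultural economists working with blocked
species-richness × management experiments (82 main plots in 4 blocks,
sown richness 1–60, five regimes from one unfertilized cut to four cuts
at 200 kg N ha⁻¹ a⁻¹).

Because the field data of such experiments are large and slow to collect,
the package ships a first-class synthetic generator that reproduces the
design and the statistical structure the model assumes, so every stage is
testable end to end.

## The model

For each annual response *y* (biomass yield, forage quality, or
quality-adjusted yield) the package fits the linear mixed model

y = α_M + β_{D×M} √D + β_{L×M} L + β_FG FG + β_G G + β_H H + u_B + u_P + e

with a separate square-root diversity slope β_{D×M} per management
intensity M (cell-means coding), legume presence L interacted with
management, number of functional groups FG, grass (G) and tall-herb (H)
presence, and random intercepts for block (u_B) and plot (u_P). The √D
transform allows a diminishing diversity effect and is compared against
linear, linear+quadratic, logarithmic and inverse alternatives by AIC/BIC
on maximum-likelihood fits. Inference uses a cluster-robust (CR2,
bias-reduced) sandwich covariance with plots as clusters and
Satterthwaite degrees of freedom; per-management tests are Bonferroni
corrected within response families and slope equality between managements
is tested pairwise by Wald statistics.

Upstream, nutritive values come from the standard in-vitro gas-test
estimation equations — e.g. metabolizable energy
ME (MJ kg⁻¹) = 3.16 + 0.0695·gas + 0.000730·gas² + 0.00732·CP + 0.02052·EE
— and annual aggregation follows

  biomass yieldₕ = Σ_cut biomassₖ,
  qualityₕ = Σ_cut qualityₖ · biomassₖ / biomass yieldₕ,
  quality-adjusted yieldₕ = Σ_cut biomassₖ · qualityₖ,

with linear interpolation of quality between the first and last analysed
cut. Downstream, milk production potential is valued at 0.31 Euro kg⁻¹ and
set against itemized variable costs (fertilizer, application, cutting,
reseeding, fresh hay transfer).

## Worked example

```r
library(gqyield)

exp <- simulate_experiment(simulation_params(seed = 42))
ann <- aggregate_annual(add_quality(exp$cuts))
fit <- fit_diversity_model(ann, "qa_me")     # metabolizable-energy yield
effect_inference(fit, n_tests = 6)
```

```
Diversity effects per management intensity (response: qa_me )
Bonferroni family size: 6  adjusted levels: 0.00833/0.00167/0.000167

            management estimate     se       t     df     p signif.
             extensive   0.4251 0.0799  5.3191 7.3213 0.001      **
        less_intensive   0.7767 0.0635 12.2293 7.3309 0.000     ***
             intensive   1.1305 0.0932 12.1364 7.1263 0.000     ***
      highly_intensive   0.8895 0.0783 11.3598 7.3409 0.000     ***
 very_highly_intensive   0.8493 0.0755 11.2457 7.1454 0.000     ***
```

Each estimate is the gain in annual metabolizable-energy yield
(MJ m⁻² a⁻¹) per unit √(species richness) under that management; here the
effect is positive everywhere and strongest under intensive management, a
structure the generator builds in. Averaged over managements, predicted ME
yield rises from 5.8 (1 species) to 8.2 (16) and 11.2 MJ m⁻² a⁻¹ (60) for
this seed.

The economic layer attaches Euro values to the same fits:

```r
ann$revenue <- revenue(ann$qa_milk_potential)$revenue
rfit <- fit_diversity_model(ann, "revenue")
equivalent_diversity_change(rfit, "less_intensive", "intensive", D_start = 1)
#> revenue gap 826 Euro ha-1 a-1  ->  equivalent richness increase 1 -> 8

management_switch_cost("less_intensive", "intensive")
#>              fertilizer         165
#>  fertilizer_application           9
#> Total: 174 Euro ha-1 a-1
```

So for this synthetic experiment, intensifying from "less intensive" to
"intensive" buys the same predicted revenue as raising sown richness from
1 to about 8 species — but costs 174 Euro ha⁻¹ a⁻¹ in extra fertilizer and
application every year.

A full run (simulate → evaluate → aggregate → fit → economics, with
provenance-stamped CSV outputs) is

```sh
Rscript scripts/pipeline.R --seed 1 --out runs/exp1
```

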