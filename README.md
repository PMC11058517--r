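# vernarch

Cross-cultural comparative analysis of traditional (vernacular) house
architecture.

Across the world's societies, houses differ in ground plan (rounded vs
angular), floor level (subterranean, ground, elevated), wall material
(thick masonry, wood/bamboo, hung fabrics or skins, thatch) and roof shape
(rounded/domed, sloped, flat). `vernarch` implements a complete pipeline
for asking *why*: how much of that variation is explained by climate, by
social organisation (polygyny, nomadism, political complexity), by
borrowing from spatial neighbours (horizontal cultural transmission), and
by shared ancestry as proxied by language family (vertical transmission)?
It is aimed at researchers in cultural evolution and macroecology working
with Ethnographic Atlas / D-PLACE style society tables.

## The method

For each society with monthly temperature and precipitation series, the
package computes means, variances and **Colwell's predictability index**
over a month-by-state frequency table with row totals `X_m`, column totals
`Y_k` and grand total `N`:

    H(X)  = -Σ_m (X_m/N) log(X_m/N)          (months)
    H(Y)  = -Σ_k (Y_k/N) log(Y_k/N)          (states)
    H(XY) = -Σ_mk (N_mk/N) log(N_mk/N)       (cells)

    constancy    C = 1 - H(Y)/log s
    contingency  M = (H(X) + H(Y) - H(XY))/log s
    predictability P = C + M = 1 - (H(XY) - H(X))/log s

`P` ranges from 0 (completely unpredictable) to 1 (fully predictable).
The eight environmental variables (temperature mean/variance/P,
precipitation mean/variance/P, elevation, slope) are Box-Cox normalised,
centred, scaled and reduced to three varimax-rotated principal components
— *temperature harshness*, *mountain dwelling* and *xeric harshness*.

Each house feature is then modelled by baseline-category (binary or
multinomial) logistic regression with a **language-family random
intercept** per non-reference category, plus a **borrowing fraction**
predictor: the share of the 10 nearest neighbours (great-circle distance)
exhibiting the focal society's category. All nested sub-models of the full
specification are fitted on a common complete-case dataset, ranked by

    AICc = -2ℓ + 2K + 2K(K+1)/(n - K - 1),

and combined with Akaike weights `w_i = exp(-Δ_i/2)/Σ exp(-Δ_j/2)` into an
average model with unconditional standard errors
`sqrt(Σ w_i (SE_i² + (β_i - β̄)²))`, per-predictor **relative importance**
(sum of weights of models containing the predictor), averaged predictions
and accuracy against chance (`1/J`) and modal-category baselines. Residual
spatial structure is checked with a Moran's I correlogram over 12
equal-width distance classes.

A synthetic-world generator produces societies on a sphere with spatially
clustered language families, autocorrelated seasonal climate with a
tunable predictability knob, and house traits drawn from a multinomial
logit with family intercepts and an optional neighbour-contagion process —
so every stage of the pipeline can be validated against known ground
truth.

## Worked example

```r
library(vernarch)
cfg <- run_config(world = world_config(n_societies = 120, n_families = 12,
                                       n_years = 10, seed = 42), seed = 42)
res <- run_pipeline(cfg)
print(res)
#> pipeline_result: 120 societies
#>   ground_plan    n =  120  models 320 (320 converged)  acc 0.808 (modal 0.683, chance 0.500)
#>   floor_level    n =  120  models 320 (320 converged)  acc 0.725 (modal 0.450, chance 0.333)
#>   wall_material  n =  120  models 320 (320 converged)  acc 0.717 (modal 0.392, chance 0.250)
#>   roof_shape     n =  120  models 320 (320 converged)  acc 0.667 (modal 0.517, chance 0.333)
```

Each line is one house feature: `n` societies entered the analysis, 320
nested models were fitted and averaged, and the averaged model's accuracy
is compared with the modal-category and chance baselines (here it beats
both for every feature, as expected for a world generated with real
climate effects). Individual analyses expose the full detail:

```r
print(res$analyses$floor_level$averaged)
#> averaged_model for 'floor_level': 320 converged models, n = 120
#>   accuracy = 0.725 (chance 0.333, modal 0.450)
#>   relative importance:
#>     temperature_harshness                      1.000
#>     xeric_harshness                            0.981
#>     mountain_dwelling                          0.853
#>     borrowing                                  0.256
#>     settlement                                 0.167
#>     political_complexity                       0.165
#>     language_family                            0.102
#>     temp_harshness_x_political_complexity      0.027
#>     polygyny                                   0.012
```

Floor level in this generated world is climate-driven (the generative
model gives it temperature and precipitation effects only), and the
importance ranking recovers exactly that: the climate composites dominate
while the social decoys and the family random effect stay near zero.

The rotated loadings behind the composite scores:

```r
round(res$composites$loadings, 2)
#>             temperature_harshness mountain_dwelling xeric_harshness
#> temp_mean                   -0.87             -0.31           -0.16
#> temp_var                     0.98              0.08            0.13
#> temp_P                       0.95              0.11            0.19
#> precip_mean                 -0.35             -0.17           -0.92
#> precip_var                  -0.04             -0.14           -0.99
#> precip_P                     0.96              0.07            0.09
#> elevation_m                  0.11              0.76            0.20
#> slope_deg                    0.12              0.78            0.05
```

High temperature harshness means cold (negative loading on mean
temperature) and variable; high mountain dwelling means high, steep
terrain; high xeric harshness means dry. Real data can be analysed the
same way by passing `input = list(society_csv = ..., climate_csv = ...)`
to `run_config()`; see `?read_society_table` for the expected CSV layout.

A thin command-line wrapper with `run` / `simulate` / `fixture` /
`validate` subcommands is installed at
`system.file("scripts", "vernarch-cli.R", package = "vernarch")`.

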