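---
title: "Methods: comparative analysis of vernacular house features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of vernacular house features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `vernarch`: the
models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-world generator does and
does not emulate, and the numerical conventions that make runs exactly
reproducible.

## The question and the data model

The unit of analysis is a *society*: a located, named cultural group with
Ethnographic Atlas style integer trait codes. Four house features are
response variables — ground plan (rounded / angular), floor level
(ground / subterranean / elevated), wall material (thick / wood-bamboo /
fabric-skins / thatch) and roof shape (sloped / rounded-domed / flat) —
and the candidate explanations are grouped into four forces:

* **climate**, summarised into three composite gradients;
* **social organisation**: polygyny (none / occasional / frequent),
  settlement (sedentary / nomadic) and political complexity (ordinal 1-5,
  from acephalous to large state);
* **horizontal transmission**: the borrowing fraction among the 10
  nearest neighbour societies;
* **vertical transmission**: a language-family random effect.

Wall-material codes outside the four mapped classes (notably rare
ice/snow walls) are recoded to `"excluded"` and treated as missing in all
models, so the affected societies drop out of the wall-material analysis
only, not the whole dataset. Political complexity is kept ordinal and
entered as a numeric covariate by default: the hypothesised
climate-by-complexity interaction is a graded trend, and numeric coding
keeps the parameter count of the multinomial models small.

## Climate summaries and Colwell's predictability

For each society with monthly series (years x 12 matrices, degrees C and
mm), the package computes the mean and variance over all year-month cells
and Colwell's predictability decomposition `P = C + M` from a
month-by-state frequency table (see `?colwell` for the entropy formulas;
the `0 log 0 = 0` convention applies, and values within `1e-12` below
zero are clipped to exactly 0).

Colwell's index needs the continuous series discretised into states,
and the binning convention is a genuine free choice. The defaults are:

* `n_states = 10` states;
* temperature: equal-width bins over the society's own observed range;
* precipitation: equal-width bins on `log(1 + mm)`, because monthly
  precipitation is strongly right-skewed and a linear grid would starve
  most states.

Both are configurable. The qualitative ordering of societies by `P` is
insensitive to the state count — the test suite asserts a Spearman
correlation above 0.9 between `P` computed at 8 and at 12 states on
synthetic seasonal series — so downstream results do not hinge on this
convention.

## Environmental composites

Eight variables (temperature mean, variance, P; precipitation mean,
variance, P; elevation; slope) are Box-Cox normalised, centred, scaled,
reduced to three principal components and varimax-rotated. Box-Cox
lambda is found by profile likelihood on a `[-5, 5]` grid with local
refinement; variables containing zeros (precipitation at arid sites,
slope on plains) are shifted by `1 - min(x)` first, and the shift is
recorded.

Rotation and eigenvector signs are not identified by the mathematics, so
the package pins them deterministically. After a normalised varimax
rotation, the component with the largest absolute loading on the
temperature variables is named *temperature harshness* and oriented so
the mean-temperature loading is negative (harsh = cold); the component
dominated by elevation/slope is *mountain dwelling*, oriented positive on
elevation; the remaining component is *xeric harshness*, oriented so the
precipitation-mean loading is negative (xeric = dry). Scores are the
projections of the standardised data on the rotated axes, re-standardised
to mean 0, SD 1.

## Spatial statistics

All distances are haversine great-circle distances on a sphere of radius
6371.0088 km; nothing downstream uses distances beyond ranking and
binning, so an ellipsoid would add complexity without changing results.
Nearest-neighbour ties are broken by society id, lexicographically, which
makes the neighbour graph — and therefore every run — deterministic. The
pairwise-distance kernel differences coordinates in degrees before
converting to radians so that geometrically equal separations are
bit-identical and the tie rule is exact.

The borrowing fraction for a focal society counts, among its k = 10
nearest neighbours with a *non-missing* trait, the share matching the
focal category. Excluding missing neighbours from the denominator keeps
the statistic in `[0, 1]` and retains societies with incomplete
neighbourhoods; the alternative (missing counts as a mismatch) is
available via `missing_as_mismatch = TRUE`.

Residual spatial autocorrelation is screened with Moran's I in 12
equal-width distance classes spanning `(0, max pairwise distance]`, with
binary weights per class and expected value `-1/(n-1)` under no
autocorrelation. For a categorical response the "residual" is not unique;
the package uses the Pearson residuals of the per-category indicator
variables and screens by the largest absolute I across categories, which
is conservative (a flag on any category flags the model) and fully
deterministic. Classes with fewer than 30 pairs are marked unreliable.
Permutation envelopes (seeded, off by default) are available via
`n_perm`.

## Mixed categorical models

House features are modelled with baseline-category logistic regression
(binary responses are the two-category special case). Reference
categories are fixed in configuration: rounded ground plan, ground-level
floor, thick walls, sloped roof. Fixed-effect fits use Newton-Raphson
with step halving, declaring convergence when the maximum absolute score
falls below `1e-6`; any coefficient passing 15 in absolute value flags
(quasi-)separation and the fit is retained but marked non-converged, so
the multimodel layer can exclude it exactly as non-converged nested runs
are excluded.

The random-effect structure is one Normal(0, sigma_j^2) intercept per
language family and non-reference category j, independent across
categories and families (a diagonal covariance). This is the minimal
structure that lets ancestry shift each category's baseline rate
separately while adding only J-1 variance parameters. Estimation is by
joint penalised Newton over the fixed coefficients and the family
intercepts at fixed variances, wrapped in a Laplace approximation to the
marginal likelihood that is maximised over log sigma_j with `nlminb`.
Boundary estimates (sigma -> 0) are allowed and flagged. With the
variances pinned at zero (`fix_sigma = 0`) the fit collapses exactly to
the fixed-effect likelihood. Against `lme4::glmer` on binary data the
fixed effects and variance agree to a few percent — the residual gap is
the difference between joint-mode and profiled Laplace approximations —
and simulation-based parameter recovery (slopes within ~0.1 of truth at
n = 1000, 30 families) is asserted in the test suite. Adaptive
quadrature was rejected because each analysis fits hundreds of nested
models.

AICc uses `K = (J-1)(q+1)` fixed parameters plus, when the random effect
is present, one variance per non-reference category, and `n` = number of
societies. The likelihood entering AICc for mixed fits is the Laplace
marginal likelihood.

## Multimodel inference

The candidate set is every subset of the toggleable terms — the three
composites, three social traits, the temperature-harshness-by-complexity
interaction (only with both mains present), the borrowing fraction and
the language-family random effect — with the intercept always included:
320 models for the default full specification. The borrowing term and
the random effect are toggled like ordinary predictors precisely so that
their relative importance is defined.

All candidates are fitted on one common complete-case dataset (societies
missing any full-model variable are dropped first), so AICc values are
comparable. Akaike weights are renormalised over converged fits only —
the direct reading of excluding non-converged nested runs — rather than
refitting the candidate set. Averaging uses the zero/shrinkage method: a
coefficient absent from a model contributes zero with that model's
weight. This is the convention consistent with treating the averaged
coefficients as estimates under model-selection uncertainty; the
containing-models-only alternative inflates small-importance effects.
Averaged predictions are the weight-averaged probability matrices, and
accuracy is compared against `1/J` and the modal-category share.

Effect profiles (`effect_profile()`) evaluate the averaged model along a
grid of one composite with everything else held at a fixed profile
(composites 0, first-level social categories, borrowing 0.5), optionally
stratified by political complexity 1 vs 5 to display the interaction.
Profile predictions are population-level (family intercept 0).

## The synthetic world

`generate_world()` emulates exactly the statistical structure the
analysis assumes: family seed points uniform on the sphere with societies
scattered around them (tangent-plane Gaussian, scale `family_clustering`
km, default 500 km — tight enough that families are regional, loose
enough that neighbourhoods mix families); temperature built from a
latitudinal gradient (default 40 degrees C equator-to-pole, the observed
span of annual means), a spatially correlated site effect (kernel-mixed
noise with range 2000 km rather than a full Gaussian-process draw, an
O(n^2) construction that is exact enough for rank- and bin-based
statistics), latitude-scaled seasonality (default 15 degrees C
half-range) and interannual noise scaled by `1 - predictability_knob`;
precipitation as the exponentiated analogue, hence positive and skewed.
At `predictability_knob = 1` every year repeats exactly and Colwell's P
is 1 by construction. House traits are drawn from the same multinomial
logit family the models assume, with family intercepts
(`family_sigma`, default 1) and a neighbour-contagion process
(`contagion_eta` times the neighbour share of each category,
`contagion_rounds` sequential redraw passes — a finite-round
approximation of an autologistic field, recorded in the truth object).
All randomness descends from one integer seed through fixed per-stage
offsets, so worlds are exactly reproducible.

What the generator does **not** emulate: continents and coastlines (no
landmass masking), phylogenetic structure within families, correlated
social traits (they are drawn independently of climate), missing data
patterns, and real-world climate regimes beyond the gradient-plus-
seasonality skeleton. One visible consequence: in generated worlds cold,
seasonal sites have *high* temperature predictability (seasonality is
contingency), so the predictability loading on temperature harshness is
positive there, whereas real climates can decouple harshness and
predictability. Passing tests on synthetic worlds therefore validates the
estimation machinery — recoding, composites, borrowing, mixed fits,
averaging, importance — not the substantive claims one would draw from
any particular empirical dataset.

## Problem sizes and determinism

The shipped tests and reference script run at deliberately modest sizes
chosen to exercise every code path while completing in minutes on a
single core: the end-to-end world at 120 societies / 12 families / 8-10
years of monthly climate; parameter-recovery simulations at 1000
societies / 30 families over 20 seeds; importance-separation and
spatial-diagnostic simulations at 200-250 societies. Report bundles are
written with fixed numeric formatting, and identical configuration plus
seed reproduces them byte for byte (the manifest records seed, options
and package version; only its wall-clock timing field varies).

## Known limitations

* The mixed-model likelihood is a Laplace approximation at the joint
  mode; with very few language families (< ~10) or sparse categories the
  variance estimates are noisy, and boundary estimates at zero are
  common — they are flagged, not hidden.
* Unconditional standard errors assume the candidate set spans the
  relevant model space; they do not account for uncertainty in the
  composite scores, which are treated as fixed covariates (as is standard
  for PCA-reduced predictors).
* The borrowing fraction conditions on the *observed* neighbour traits,
  so it is a proxy for horizontal transmission, not a causal estimate;
  in the generator the same quantity drives contagion, which is the
  favourable case.
* Moran screening by the maximum per-category |I| can over-flag
  responses with many rare categories.
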