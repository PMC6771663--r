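# nestdensity

Orang-utan density estimation from line-transect nest counts.

Great-ape abundance is rarely measured by direct sighting: orang-utans
build a fresh sleeping nest almost every day, and nests persist for
months, so walking line transects and recording every visible nest (the
*standing-crop* method) is the standard field protocol. `nestdensity`
implements the full analysis chain for such surveys — binned
distance-sampling detection functions, nest-to-ape density conversion,
parameter-sensitivity grids, habitat comparisons and multimodel covariate
inference — for ecologists estimating primate densities in logged forest,
salvage-logged remnants and oil-palm landscapes.

## The model

Nests are detected with decreasing probability away from the transect
line. A detection function g(x) (uniform, half-normal
`g(x) = exp(-x²/2σ²)`, or hazard-rate `g(x) = 1 - exp(-(x/σ)^-b)`, each
optionally multiplied by a cosine, simple-polynomial or Hermite series
adjustment and rescaled so g(0) = 1) is fitted to perpendicular distances
aggregated into 4 m classes and truncated at w = 40 m, by maximising the
multinomial likelihood of the bin counts. The fitted model (chosen by AIC
among the conventional six key/adjustment pairings, with a chi-square
goodness-of-fit check) yields the effective strip width

    ESW = ∫₀ʷ ĝ(x) dx.

Nest density on a transect of length L km with N nests is then

    D_nest = N / (L · 2·ESW),

and orang-utan density divides out the expected number of standing nests
per individual,

    D_orang = D_nest / (p · r · t),

where p is the proportion of nest-building individuals (default 0.85),
r the nest production rate in nests/individual/day (default 1.00) and
t the nest decay time in days (default 259). Because p, r and t come
from the literature, a 3×3×3 factorial sensitivity grid over published
low/medium/high values (`parameter_grid()`) propagates their uncertainty.
Habitat differences are tested by one-way ANOVA with Tukey HSD (gated by
Shapiro–Wilk and Bartlett checks), and forest-structure covariates are
related to density through all-subsets Gaussian linear models with
Gelman standardisation, collinearity screening (|r| ≥ 0.7, GVIF ≥ 5),
AICc ranking and full (zero-substitution) model averaging with
unconditional confidence intervals.

A survey simulator with known truth (`sim_config()`, `simulate_survey()`,
`simulate_covariates()`) generates Poisson nest counts, distance-dependent
detection thinning, decay classes and covariates, so every stage of the
pipeline is testable against ground truth.

## Worked example

The package bundles a 28-transect survey of a logged-forest / oil-palm
mosaic in Sabah, Borneo (`sabah_survey()`), with per-transect nest
counts and the habitat-pooled effective strip widths (15.5, 14.3 and
14.7 m) from the original detection fits:

```r
library(nestdensity)
sv  <- sabah_survey()
est <- estimate_density(sv)          # p = 0.85, r = 1.00, t = 259
habitat_summary(est)
#> Orang-utan density by habitat (ind/km^2)
#>           habitat n_transects mean   sd   se  min  max
#>     logged_forest          12 2.32 0.84 0.24 1.25 4.52
#>    salvage_logged          10 2.36 0.61 0.19 1.16 2.98
#>  oil_palm_remnant           6 0.82 0.50 0.20 0.09 1.37
#>         landscape          28 2.01 0.93 0.18 0.09 4.52
```

Logged forest and the recently salvage-logged remnants hold similar
densities (≈2.3 ind/km²), while remnant patches inside oil palm hold
roughly a third of that (0.82 ind/km²); the landscape-wide mean is
2.01 ind/km². Individual transects span 0.09–4.52 ind/km²:

```r
est[est$transect_id %in% c("LF1", "VJR_1", "OP07"), ]
#>  transect          habitat nests  km esw_m nests_per_km ind_per_km2
#>       LF1    logged_forest    31 1.8  15.5         17.2         2.5
#>     VJR_1    logged_forest    37 1.2  15.5         30.8         4.5
#>      OP07 oil_palm_remnant     1 1.8  14.7          0.6         0.1
```

How much do the literature parameters matter? With p fixed and t and r
swept over their published ranges, the logged-forest estimates stretch
from 0.46 to 6.90 ind/km²:

```r
sensitivity_summary(est)
#>    subset          habitat   min  max
#> ...
#>   p_fixed    logged_forest 0.462 6.896
```

For a survey with raw perpendicular distances, the detection step runs
first:

```r
b    <- bin_distances(distances_m)          # 4 m classes, 40 m truncation
fits <- fit_detection_set(b)                # the six conventional models
best <- select_best_model(fits)             # min-AIC, monotone, converged
effective_strip_width(best)
```

`run_pipeline()` chains every stage (reading or simulating data,
detection, densities, habitat tests, sensitivity, model averaging) from
one configuration list or YAML file and writes deterministic CSV/JSON
outputs.

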