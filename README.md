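# partmigr

Analysis of **breeding partial migration** from radio-telemetry: some
individuals in a population migrate between a shared wintering area and an
allopatric breeding area while others remain resident year-round. Given
telemetry fixes, bird attributes and nest records, partmigr classifies each
bird's seasonal movements as migratory or resident, asks whether the
decision is state-dependent (body weight × age), how repeatable it is
within individuals, and whether it carries reproductive consequences
(clutch size, nest fate). It is aimed at movement ecologists working with
VHF/GPS-tagged birds, and ships a ground-truthed synthetic-telemetry
generator so the entire pipeline is testable without field data.

## Methods at a glance

* **Classification.** Seasonal activity centers (nest-weighted in summer)
  are compared between consecutive seasons. With circular home-range
  baselines of area 4.08 km² in winter (radius r_w = 1140 m, from 95%
  minimum convex polygons of GPS tracks) and 0.058 km² in summer
  (r_s = 136 m, the median summer MCP), two ranges overlap iff the centers
  are within r_w + r_s = 1276 m; a displacement d > 1276 m is classified
  *migrant*, otherwise *resident*. GPS tracks are first cleaned by a
  single-pass spike rule (fix t is an outlier iff
  d(t−1, t) > 2·d(t−1, t+1)).
* **Repeatability.** For birds with ≥ 2 observed decisions, a
  one-random-intercept linear mixed model on log movement distance is
  fitted by REML and repeatability is
  R = σ²_α / (σ²_α + σ²_ε), with a percentile parametric-bootstrap 95% CI
  (n = 1000). *Agreement* R uses an intercept-only fixed part; *adjusted*
  R adds age class.
* **Candidate models.** First-spring analyses ranked by
  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) with Akaike weights: binomial GLM for
  the migratory decision (weight × age), Gaussian model for log distance,
  mean-parameterized Conway–Maxwell–Poisson regression for (typically
  underdispersed) clutch size, and a binomial GLM for nest fate.

See `vignettes/partmigr-methods.Rmd` for the full model descriptions,
parameter defaults, and numerical conventions.

## Worked example

```r
library(partmigr)

range_baseline()
#> Circular home-range baseline
#>   winter: 4.080 km^2 (radius 1140 m)
#>   summer: 0.058 km^2 (radius 136 m)
#>   migration threshold: 1276 m

sim <- simulate_population(sim_config())    # 100 birds, 5 years, seeded
cl  <- classify_migration(sim$fixes, sim$nests)
cl$summary
#> # A tibble: 6 × 5
#>   year  residents migrants total pct_migrants
#>   <chr>     <int>    <int> <int>        <dbl>
#> 1 2015          3       14    17           82
#> 2 2016          3       15    18           83
#> 3 2017          4       20    24           83
#> 4 2018          5       14    19           74
#> 5 2019          6       16    22           73
#> 6 Total        21       79   100           79

rep_res <- agreement_and_adjusted(cl$transitions, sim$birds,
                                  n_boot = 1000, seed = 1)
rep_res$agreement
#> agreement repeatability: R = 0.732, 95% CI = 0.646-0.795 (parametric bootstrap, n = 1000)
#>   456 observations of 78 individuals

cs <- run_candidate_sets(cl$transitions, sim$birds, sim$nests)
cs$migration$table
#>                         model k  AICc delta_AICc  weight cum_weight
#> 1 Weight + Age + Weight x Age 4  95.6       0.00 0.85189      0.852
#> 2                Weight + Age 3 100.4       4.76 0.07898      0.931
#> 3                      Weight 2 101.2       5.57 0.05250      0.983
#> 4                   Intercept 1 104.8       9.23 0.00842      0.992
#> 5                         Age 2 104.9       9.29 0.00821      1.000
```

Reading the output: the per-year table counts each bird's first
winter→summer decision (79% of the simulated birds migrated — the
generator's logistic rule produces a migrant majority); repeatability
R = 0.73 says that ~73% of the variance in log movement distance lies
*between* individuals, i.e. migration is close to a fixed individual
strategy; and the AICc table ranks the weight × age interaction model
first (weight 0.85), recovering the juvenile-only weight effect that the
generator built in.

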