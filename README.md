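# pgsmap — spatially weighted polygenic score association mapping

Polygenic scores (PGS) are usually evaluated with a single
population-level regression coefficient. `pgsmap` asks a finer question:
**where, within a study region, does a PGS predict a trait more or less
strongly?** It is aimed at epidemiologists and statistical geneticists
working with geocoded cohorts who want to map local gene–environment
interplay rather than assume a spatially constant genetic effect.

The pipeline:

1. **Scores** — weighted allele-count PGS from genotype dosages and GWAS
   summary statistics at several p-value thresholds
   (`score_participants()`, strict `p < t` inclusion), z-standardised;
   the best threshold is picked by adjusted R² of the unweighted
   covariate-adjusted model (`select_best_threshold()`).
2. **Grid** — a regular hexagonal lattice of analysis locations clipped
   to the study polygon (`build_hex_grid()`), with hex-edge adjacency.
3. **Maps** — at every grid node x, the covariate-adjusted model
   `y_i = α(x) + β(x)·PGS_i + γ'·covariates_i + ε_i`
   is fitted by weighted least squares with inverse-distance weights
   `w_i(x) = 1 / max(d_i, d_min)^p` (default power p = 0.5, so every
   participant contributes everywhere and estimates are smoothed toward
   the population mean). The fitted β(x) surface is the
   *genetic-influence map* (`map_associations()`).
4. **Comparison** — maps are compared to each other and to environmental
   surfaces with Lee's bivariate spatial association statistic L, which
   blends Pearson correlation with Moran-type spatial smoothing, under a
   Monte-Carlo permutation null (`lee_statistic()`, `moran_i()`,
   `lee_permutation_test()`, `compare_maps()`); two-tailed p-values with
   floor 2/(M+1).

Because cohorts of this kind are managed-access, the package ships a
first-class synthetic-data generator (`simulate_cohort()`) that plants a
known spatially varying coefficient surface, correlated environmental
surfaces, and optional PGS-linked attrition, so every stage can be
validated against ground truth.

## Worked example

```r
library(pgsmap)

cfg  <- simulation_config(seed = 42)          # 5,000 participants, linear beta gradient
sim  <- simulate_cohort(cfg)
grid <- build_hex_grid(cfg$region, target_n = 300)

sel <- select_best_threshold(sim$cohort, cfg$thresholds,
                             model_spec("trait", "pgs_0.5"))
sel$table
#>   threshold    n         r2     adj_r2 delta_adj_r2
#> 1     5e-08 5000 0.03778391 0.03720612   0.01992666
#> 2     1e-05 5000 0.03778391 0.03720612   0.01992666
#> 3     5e-01 5000 0.04594625 0.04537336   0.02809390

map <- map_associations(sim$cohort, grid, weight_kernel(),
                        model_spec("trait", sel$best_column))
map
#> <local_fit_map> 312 nodes (312 converged), n = 5000 participants
#>   beta: median 0.3577, range [0.2282, 0.4034]

W   <- contiguity_weights(grid)
env <- simulate_env_surfaces(grid, sim$truth, cfg)
compare_maps(map, env, W, M = 999, seed = 1,
             value_b = "sunshine_hours", scheme = "one")
#> Lee's L Monte-Carlo permutation test (one scheme)
#>   maps: trait~pgs_0.5 vs sunshine_hours
#>   transforms: identity / identity
#>   L = 0.4452, M = 999 permutations, two-tailed p = 0.002
#>   permutation null: mean 0.001664, sd 0.05552
```

Reading the numbers: the permissive threshold (p < .5) explains the most
trait variance, so its map is carried forward. The fitted node
coefficients run from 0.23 to 0.40 trait units per SD of PGS — the
planted west-to-east gradient, smoothed toward the population mean by
the flat distance kernel (the correlation between fitted and true node
coefficients here is 0.84). The sunshine-hours surface was generated at
ρ = 0.5 with the true coefficient surface, and the Lee test detects that
co-patterning (L = 0.45, p = .002 at M = 999; the one-variable
permutation scheme is the calibrated choice for map–environment
independence testing — see the vignette).

File-driven runs (`run_simulate()` → `run_map()` → `run_compare()`, or
the `inst/cli/pgsmap` wrapper) write all artefacts as delimited text and
GeoJSON with a seed-and-checksum manifest.

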