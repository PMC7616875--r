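---
title: "Mapping spatial variation in polygenic score associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spatial variation in polygenic score associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Polygenic scores (PGS) summarise the common-variant genetic liability an
individual carries for a trait. Their predictive strength is usually
reported as a single population-level regression coefficient, but there is
no reason to assume that coefficient is constant over space: local
environments can draw out or mask genetic effects
(gene–environment interaction and correlation). pgsmap estimates *where*,
within a single study region, a PGS predicts a quantitative trait more or
less strongly, and asks whether the resulting map of local coefficients
co-patterns with environmental surfaces such as population density,
deprivation, or sunshine hours.

## The model

At every node $x$ of a regular hexagonal grid laid over the study region,
we fit the covariate-adjusted linear model

$$ y_i = \alpha(x) + \beta(x)\,\mathrm{PGS}_i + \gamma_{\mathrm{sex}}(x)\,\mathrm{sex}_i + \gamma_{\mathrm{age}}(x)\,\mathrm{age}_i + \varepsilon_i $$

by weighted least squares, where every participant contributes with the
inverse-distance weight

$$ w_i(x) = \frac{1}{\max(d_i, d_{\min})^{p}}, $$

$d_i$ the Euclidean distance (planar metres) from participant $i$'s
residence to the node. The fitted $\hat\beta(x)$, in trait units per SD of
PGS, is the node's *genetic influence*; the collection over nodes is the
genetic-influence map. The default power $p = 0.5$ is deliberately flat:
every participant contributes to every node, so local estimates are
smoothed towards the population mean, trading spatial resolution for
stability. Larger powers localise more aggressively (the test suite
verifies that the separation of two planted cluster effects is
non-decreasing in $p$ over $\{0.25, 0.5, 1, 2\}$).

Three numerical conventions are worth stating because the method itself
does not force them:

* **Distance floor.** $d_{\min}$ defaults to 50 m, of the order of the
  radius of a small residential postcode zone, so a participant sitting
  exactly on a node has finite weight. Estimates are invariant to the
  overall scale of the weights, so the floor matters only through the
  relative up-weighting of very close participants. Configurable via
  `weight_kernel()`.
* **Standard errors.** Weights are treated as precision weights:
  $\widehat{\mathrm{Var}}(\hat\beta) = (X'WX)^{-1} \hat\sigma^2$ with
  $\hat\sigma^2 = \sum_i w_i e_i^2/(n-p)$. Per-node SEs of this kind
  understate the effective dependence between nodes (neighbouring nodes
  share almost all of their data) and are reported as a diagnostic, not
  as inferential intervals.
* **Complete cases.** Rows missing any model column are dropped once,
  globally, before mapping, so every node sees the same participants.

## Polygenic score construction

Scores are weighted allele counts: for threshold $t$,
$s_i = \sum_{j : p_j < t} \hat\beta_j g_{ij}$ with $g_{ij} \in \{0,1,2\}$
the dosage of the effect allele and $\hat\beta_j$, $p_j$ the discovery-GWAS
effect and p-value. Inclusion is strict ($p_j < t$), so SNP sets are
nested across thresholds. Scores are z-standardised over the analysed
sample. The default threshold set is $\{5\times10^{-8}, 10^{-5}, 0.5\}$;
`select_best_threshold()` fits the unweighted covariate-adjusted model per
threshold and picks the largest adjusted $R^2$. Two conventions:

* Adjusted $R^2$ is taken from the **full** model (trait on PGS plus
  covariates). Because the covariates are shared across thresholds, the
  full-model ranking is monotone-equivalent to ranking by the increment
  over a covariates-only model; both are reported, the full-model value
  decides.
* Exact ties (within $10^{-12}$) break towards the **smaller** threshold:
  parsimony, and determinism across platforms. This matters in practice
  because null SNPs with zero reported effect add nothing to a score, so
  adjacent thresholds can produce identical score vectors.

Dosages are assumed pre-aligned to the GWAS effect allele.
`reconcile_alleles()` is provided for real data (sign-flip on reversed
pairs, drop strand-ambiguous A/T and C/G SNPs); the simulator emits
aligned dosages and bypasses it. No LD clumping is implemented: the
synthetic SNPs are independent, and for real data a pre-clumped SNP list
can be passed by subsetting the summary statistics.

## Comparing maps: Lee's L and its permutation null

Two maps aligned on the same grid are compared with Lee's bivariate
spatial association statistic

$$ L = \frac{n}{\sum_i \left(\sum_j v_{ij}\right)^2}
  \cdot \frac{\sum_i \left[\sum_j v_{ij}(x_j - \bar x)\right]
  \left[\sum_j v_{ij}(y_j - \bar y)\right]}
  {\sqrt{\sum_i (x_i - \bar x)^2}\sqrt{\sum_i (y_i - \bar y)^2}}, $$

which blends Pearson correlation with Moran-type spatial smoothing; with
self-only (identity) weights it reduces exactly to Pearson's $r$, and on
a row-standardised weight matrix it is bounded by 1 in absolute value.
The weight matrix $v_{ij}$ is first-order hex-edge contiguity,
row-standardised — the canonical neighbour definition on a regular grid.
Positively skewed environmental surfaces (population density,
deprivation indices) are log-transformed before comparison.

Inference is by Monte-Carlo permutation with two schemes:

* **Joint** (default): pairs $(x_i, y_i)$ are permuted together across
  locations, preserving the aspatial correlation and destroying the
  spatial arrangement. This is the convention of classical
  spatial-statistics software for the bivariate statistic, and its null
  is "no spatial co-patterning beyond what the pair correlation implies
  under random arrangement". It is exact when the observed pair
  arrangement is exchangeable — e.g. when both surfaces are themselves
  spatially unstructured.
* **One-variable** (`scheme = "one"`): only $y$ is permuted. When the
  null hypothesis is *independence* of $y$ from an autocorrelated map
  $x$, and $y$ carries no residual spatial structure of its own, this
  test is exact conditionally on $x$, whatever the autocorrelation of
  $x$. The joint scheme is not calibrated for that null: shuffling a
  smooth $x$ shrinks the variance of its spatial lag, so the permutation
  distribution of $L$ is too narrow and the test over-rejects. For
  testing whether an environmental surface with node-level noise aligns
  with a fitted (hence smooth) genetic-influence map, use
  `scheme = "one"`; the package's validation suite does exactly that,
  and verifies both its level at $\rho = 0$ and its power at
  $\rho = 0.9$.

The two-tailed p-value doubles the smaller one-sided tail with
tie-inclusive counting, $\hat P = (1 + \#)/(M+1)$, capped at 1. With
$M = 10{,}000$ the smallest reportable p is $2/10{,}001 \approx
2.0\times10^{-4}$. A Bonferroni helper flags $p < \alpha/k$; with the
conventional $\alpha = .05$ and $k = 15$ map–environment tests the
threshold is $.05/15 \approx .003$.

## The synthetic-data generator

Real cohorts with geocoded residences and genotypes are managed-access,
so the generator plants a fully known ground truth instead:

* **Geography.** A 30 km × 30 km planar region with six Gaussian
  settlement clusters (SD 2.5 km), emulating a city region with
  satellite towns; 5,000 participants by default, matching the
  4,000–8,000 scale of a single-city birth-cohort analysis.
* **Genotypes.** 200 independent SNPs, MAF ~ Uniform(0.05, 0.5), dosages
  Binomial(2, MAF). No LD — which is why no clumping stage exists in the
  synthetic pipeline.
* **Summary statistics.** 10% of SNPs carry true effects,
  Normal(0, 0.06) per allele. The reported effect column equals the
  generative effect; discovery noise enters through the p-value, via
  $z = \beta/\mathrm{se}(\mathrm{MAF}, N_{\mathrm{GWAS}}) + N(0,1)$ with
  $N_{\mathrm{GWAS}} = 20{,}000$. Null SNPs therefore have effect 0 and
  uniform p-values, and threshold sets differ only through which true
  effects have reached significance — a clean planted structure for
  threshold-selection tests.
* **Trait.** $y = 3 + \beta(s)\,\mathrm{PGS} + 0.5\,\mathrm{sex} +
  0.2\,\mathrm{age} + N(0, 2^2)$, with sex ~ Bernoulli(0.5) and age ~
  Normal(10.7, 0.12) (an age-10 assessment window). The default
  coefficient surface is the linear gradient $\beta(s) = 0.1 +
  2\times10^{-5} x$, i.e. 0.1 to 0.7 trait units per SD of PGS across
  the region. This is deliberately at the upper end of what is
  realistic for questionnaire traits, so that planted structure is
  recoverable with conventional cohort sizes; the trait is continuous by
  default, with an optional rounding/clamping to bounded questionnaire
  scales (0–10, 0–24) that is off because the fitted model is linear
  either way.
* **Environmental surfaces.** Each surface is a transform of
  $\rho z_\beta + \sqrt{1-\rho^2} g$ with $z_\beta$ the standardized
  coefficient surface at the nodes and $g$ iid node-level Gaussian
  noise. The five defaults emulate the usual suspects: two log-normal
  (population density, deprivation), two smooth continuous
  (qualification level, sunshine hours), one 3-level categorical
  (urbanicity; the tertile cut attenuates realized correlation by a
  factor of about 0.89). The node-level-noise choice keeps the realized
  rank correlation within ±0.15 of $\rho$ on grids of 300+ nodes — a
  smooth residual field would not — and makes the $\rho = 0$ case a
  clean independence null.
* **Attrition.** Retention probability
  $\mathrm{logit}^{-1}(\lambda_0 + \gamma\,\mathrm{PGS})$, with
  $\lambda_0$ solved so expected retention hits the configured target;
  $\gamma < 0$ reproduces the reported pattern of higher hyperactivity
  polygenic burden predicting drop-out. Off by default
  (target 1).

What the generator does *not* emulate: LD structure, imputation
uncertainty, ancestry stratification (PC columns pass through as
covariates but are not simulated with structure), measurement
floor/ceiling effects, or non-random geocoding error. Passing tests
therefore demonstrate correctness of the estimation machinery under the
planted model, not robustness to those real-data complications.

Every stage derives its own RNG stream from the config seed, so each
operation is individually reproducible and a full run is byte-identical
under a fixed config.

## Validation problem sizes

The package's test suite validates, among other properties: exact
agreement of Lee's L and Moran's I with an independently coded
direct-formula oracle (50+ random instances, $10^{-8}$); the analytic
limits (Pearson reduction, Moran permutation-null mean $-1/(n-1)$,
WLS-to-OLS collapse); calibration of the joint permutation test under a
bivariate iid null (400 replicates, 100 nodes, $M = 199$); recovery of a
planted coefficient gradient (5,000 participants, 300 nodes); and
level and power of the one-variable map–environment test (50 end-to-end
cohort replicates; 8 null surfaces each for the level check,
$M = 999$). These sizes were chosen to make sampling bounds tight enough
to be meaningful while keeping the full suite around a minute of compute.

## Worked example

```{r example}
library(pgsmap)

cfg <- simulation_config(seed = 42)
sim <- simulate_cohort(cfg)
grid <- build_hex_grid(cfg$region, target_n = 300)

sel <- select_best_threshold(sim$cohort, cfg$thresholds,
                             model_spec("trait", "pgs_0.5"))
map <- map_associations(sim$cohort, grid, weight_kernel(),
                        model_spec("trait", sel$best_column))

W <- contiguity_weights(grid)
env <- simulate_env_surfaces(grid, sim$truth, cfg)
compare_maps(map, env, W, M = 999, seed = 1,
             value_b = "sunshine_hours", scheme = "one")
```

The file-driven equivalent (`run_simulate()`, `run_map()`,
`run_compare()`, or the `inst/cli/pgsmap` wrapper) writes every artefact
as delimited text or GeoJSON together with a manifest of seeds and
checksums, so a run is auditable and exactly repeatable.

## Known limitations

* Per-node SEs are descriptive; no map-wide confidence bands are
  provided (a bootstrap over the whole map is the natural extension).
* The local model is linear in the PGS; non-linear or interaction
  surfaces are out of scope.
* The joint permutation scheme, kept as the default for compatibility
  with established software, answers a co-patterning question — it
  should not be read as an independence test between autocorrelated
  surfaces (use `scheme = "one"` for that, with the caveat that the
  permuted variable should itself be spatially unstructured under the
  null).
* Environmental surfaces are taken as known node values; attaching
  zone-valued real data to grid nodes (containment or nearest-centroid
  joins) is the user's responsibility and its error is not propagated.
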