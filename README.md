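# nichecast

Climate niche modelling for invasive-species risk assessment: an
L1-regularized maximum-entropy presence-background model with bootstrap
ensembling, scenario projection, and the standard companion analyses —
spatial thinning of occurrence records, correlation-based variable pruning,
habitat-suitability classification with climate-unit overlap tables,
MESS extrapolation surfaces, and identity-line regression tests of
distribution change under future climates.

The package is aimed at ecologists who model species distributions from
presence-only records (e.g. GBIF downloads) against bioclimatic raster
stacks, and who need the whole workflow to be scriptable, seeded, and
testable. A synthetic-world generator with a known suitability truth makes
every stage verifiable without external downloads.

## The model

Given presence records and a background sample of `N` landscape cells with
feature vectors `f(x)` (linear, quadratic, product, and hinge expansions of
the scaled bioclimatic variables), the niche model is the Gibbs
distribution over the background

```
q_lambda(x) = exp( sum_j lambda_j f_j(x) ) / Z(lambda)
```

whose weights minimize the L1-regularized negative mean presence
log-likelihood

```
log Z(lambda) - mean_presence[ sum_j lambda_j f_j ] + sum_j beta_j |lambda_j|
```

— the maximum-entropy solution under relaxed feature-expectation
constraints. At the optimum the KKT conditions pin every feature's moment
gap: `| mean_presence f_j - E_q f_j | <= beta_j`. Raw weights are mapped to
occurrence probabilities with the logistic transform
`p = e^H raw / (1 + e^H raw)` (`H` = entropy of the background
distribution), classified as unsuitable (`p < 0.1`), moderately suitable
(`0.1 <= p <= 0.5`), or highly suitable (`p > 0.5`). An ensemble of 100
bootstrap replicates (75% training resamples, out-of-bag testing by
Mann-Whitney AUC) is integrated by cellwise averaging; change under a
scenario is tested by regressing future on current probabilities at
10,000 random coordinates against the theoretical identity line
(`beta0 = 0`, `beta1 = 1`, Student's t).

## Worked example

```r
library(nichecast)

# a synthetic study system with known truth: 50 x 50 cells, 6 layers,
# 200 presences sampled proportional to a logistic suitability surface
w <- synthetic_world(nrows = 50, ncols = 50, n_presences = 200, seed = 42)

occ <- thin_buffers(w$occurrences, radius_km = 2.5, seed = 1)
sum(occ$retained)
#> [1] 123

vals <- extract_values(w$current, occ[occ$retained, ])
sel  <- select_variables(spearman_matrix(vals))
retained_variables(sel)
#> [1] "env1" "env6"

ens <- run_ensemble(occ, w$current,
                    config = ensemble_config(n_runs = 10, n_background = 2500),
                    seed = 2, variables = retained_variables(sel))
ens
#> <cnm_ensemble> 10 run(s) (10 converged), mean test AUC 0.787 (SE 0.00662)

class_fractions(classify_habitat(ens$integrated))
#> # A tibble: 1 x 3
#>   high_pct moderate_pct unsuitable_pct
#> 1     17.6         70.4           12.0

s <- scenario_summary(ens, w$futures[["2081-2100 SSP8.5"]],
                      label = "2081-2100 SSP8.5")
s$fractions
#> # A tibble: 1 x 3
#>   high_pct moderate_pct unsuitable_pct
#> 1     56.5         41.6           1.88
round(s$negative_overlap_pct, 2)
#> [1] 2.41

change_table(ens$integrated, list(`2081-2100 SSP8.5` = s$prob),
             n = 5000, seed = 3)[, c("beta0", "beta1", "r_squared")]
#> # A tibble: 1 x 3
#>   beta0 beta1 r_squared
#> 1 0.193 0.994     0.881
```

Reading: after 2.5-km buffer thinning, 123 of 200 records remain; two of
six correlated layers carry the model; the bootstrap ensemble discriminates
presences from background (AUC 0.79); under the warmest end-of-century
scenario the highly suitable fraction rises from 17.6% to 56.5% while only
2.4% of suitable habitat falls in climatically novel (negative-MESS) areas;
the change regression sits above the identity line (`beta0 > 0`), the
signature of range expansion.

The same workflow runs from a single configuration with
`run_pipeline(pipeline_config(...), out_dir)`, which writes probability /
class / MESS grids, the selection, decile, scenario, zonal-overlap and
change-test tables, and a manifest with seeds and output fingerprints.
File-based inputs (occurrence CSV plus raster layers per scenario) are
supported through the same entry point.

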