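---
title: "Methods: presence-background niche modelling with nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche modelling with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nichecast)
```

## The modelling problem

Presence-only occurrence records tell us where a species has been seen,
never where it is absent. The presence-background approach treats the
species' distribution as an unknown probability distribution over the
landscape and estimates it by contrasting the environments at presence
points against a random sample of the whole study region (the
*background*). Among all distributions whose feature expectations match the
presence sample, the maximum-entropy principle selects the least committed
one — a Gibbs distribution

$$q_\lambda(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)},$$

with $Z$ summing over the background cells. `nichecast` implements this
estimator from first principles, together with the surrounding workflow a
climate-niche study needs: record cleaning and spatial thinning,
correlation-based variable pruning, bootstrap ensembling with AUC
validation, suitability classification, climate-novelty (MESS) screening,
and regression tests of distribution change under future-climate
scenarios.

## Occurrence handling

Records arrive as delimited text with decimal-degree coordinates
(`decimalLongitude`/`decimalLatitude` by default). Cleaning proceeds in
three stages, each leaving an audit trail in the `drop_reason` column
rather than deleting rows:

1. **Ingestion** drops unparsable or out-of-range coordinates.
2. **Urban filtering** flags records on cells of a caller-supplied urban
   mask, removing presences that may reflect human interventions (watered
   gardens, roadsides) rather than climate.
3. **Buffer thinning** (`thin_buffers()`) draws a 2.5-km circular buffer
   around every record and keeps exactly one record per group of
   overlapping buffers, controlling duplicate sampling of the same
   climate pixel. Two design choices deserve note. *Grouping*: overlap is
   transitive chains — we take connected components of the overlap graph
   (distance < 2 × radius, strictly), because a greedy pairwise rule
   would depend on record order. *Tie-breaking*: the survivor is drawn
   uniformly with a seed derived from the global seed plus the sorted
   member ids, so the result is identical under any row permutation.
   Thinning is idempotent, and all retained pairs are at least 5 km
   apart (great-circle distance on a 6371-km sphere; at a 2.5-km scale
   the spherical approximation errs well under 0.5%).

## Variable selection

Redundant bioclimatic variables inflate niche models. `spearman_matrix()`
computes pairwise-complete Spearman correlations at the presence points;
`select_variables()` builds a redundancy graph with an edge wherever
$|\rho| > 0.60$ and iteratively retains the variable with the most
redundancy links (ties broken alphabetically), dropping its neighbours
until no edges remain. The retained set is therefore always an independent
set of the threshold graph — no surviving pair exceeds the threshold. Two
readings of the underlying heuristic exist (one global pass vs. the
iterative rule); we implement the iterative one because it alone
guarantees a redundancy-free result. The absolute value is used because a
strong negative correlation is exactly as redundant as a positive one;
both the threshold and the absolute-value behaviour are arguments.

## The maximum-entropy core

**Features.** Variables are affinely scaled to $[0,1]$ by their training
(background) min/max. Feature classes are linear, quadratic, pairwise
product, and hinge ($\max(0, (x-k)/(\max-k))$ at 10 equally spaced knots);
with fewer than 80 presences only linear and quadratic features are built,
mirroring the auto-feature convention of the reference MaxEnt
implementation. Presence cells are included in the background
("presence-background" convention); the background is 10,000 cells drawn
without replacement, or every valid cell when fewer exist.

**Regularization.** Each feature carries an L1 penalty
$\beta_j = r \cdot c(\text{class}) \cdot s_j/\sqrt{m}$ with $m$ the
presence count, $s_j$ the feature's presence standard deviation, class
constants 1.0 (linear/quadratic/product) and 0.5 (hinge), and $r$ the
user's regularization multiplier (default 1). This is a deliberately
simplified form of the published default tables; the constants are
configurable.

**Optimization.** The objective
$\log Z(\lambda) - \overline{f\lambda}_{\text{presence}} + \sum_j \beta_j|\lambda_j|$
is convex. We minimize it with FISTA (accelerated proximal gradient with
soft-thresholding, backtracking line search, monotone restarts),
interleaved every 25 iterations with an orthant-wise Newton refinement on
the active set: signs are fixed, a damped Newton step is taken on the
smooth part plus the signed penalty, sign flips are projected back to
zero, and the step is accepted only if the full objective decreases.
Convergence is declared when the maximum KKT violation —
$|\overline{f_j} - E_q f_j| \le \beta_j$, with signed equality where
$\lambda_j \ne 0$ — falls below `tol` ($10^{-5}$ by default, `max_iter`
500). Converged fits in the test suite certify this condition feature by
feature. The unconstrained (zero-feature) model is returned in closed form
as the exactly uniform distribution.

**Outputs.** `predict_raw()` gives Gibbs weights summing to one over the
background; `to_logistic()` applies the logistic transform
$p = e^H r/(1+e^H r)$ with $H$ the background entropy, so a
"typical" presence scores about 0.5 and the uniform model scores exactly
0.5 everywhere. The classification thresholds 0.1/0.5 below apply to this
logistic scale (the transform is monotone, so AUC is unaffected by the
choice). The training gain is
$\overline{\log(N\,\text{raw})} - \sum_j \beta_j |\lambda_j|$: zero for
the uniform model, the regularized improvement in mean presence
log-likelihood otherwise.

## Ensemble, validation, importance

`run_ensemble()` fits 100 bootstrap replicates by default: each run
resamples the training presences with replacement (75% of the presence
count) and tests on the out-of-bag records against the background using
the Mann–Whitney AUC (ties counted half). A plain random-split mode
(`replicate_mode = "subsample"`) is available since published workflows
are often ambiguous between the two. One background sample is shared by
all replicates, which fixes the feature expansion across runs; this
matches running replicates against a fixed background file and makes the
integrated grid — the cellwise mean of the replicate logistic grids —
well defined. Non-converged replicates are excluded from integration and
flagged, never silently retried.

Variable importance is reported two ways. *Permutation contribution*
permutes one variable across the pooled presence + background points,
rebuilds features, and measures the AUC drop (floored at zero, normalized
to percentages); we use it instead of the reference implementation's
path-dependent gain attribution, which is optimizer-specific and not
reproducible across implementations. *Jackknife gains* fit, per variable,
a with-only and a without model and report training gains next to the
full-model gain; with no regularization the nested-model inequality (no
with-only gain above the full gain) is asserted in the test suite.

## Scenario analysis

`project_ensemble()` projects every converged replicate onto a scenario
stack with its own training scalers (no refitting) and averages.
`classify_habitat()` cuts probabilities at 0.1 and 0.5; both boundary
values are assigned to the moderate class ("between 0.1 and 0.5" read
inclusively). `class_fractions()` and `zonal_overlap()` report percent
cover globally and per climate unit; rows always sum to 100 over valid
cells.

**MESS.** For each cell and variable, with $f$ the percentage of reference
values strictly below the cell value $p$ and $[\min,\max]$ the reference
range, the similarity is $100(p-\min)/(\max-\min)$ if $f=0$; $2f$ if
$0<f\le50$; $2(100-f)$ if $50<f<100$; $100(\max-p)/(\max-\min)$ if
$f=100$; the cell's MESS is the minimum over variables, negative exactly
when some variable leaves its reference range. Strict "below" counting is
used (so the reference minimum itself scores 0, not negative). The
reference set is each replicate's training presences plus the shared
background (`presences_only` is available); per-replicate MESS grids are
integrated by cellwise mean, and a cell is classified climatically novel
when the mean is strictly negative (a zero mean counts as non-negative).
The suitable-vs-novel overlap is the percentage of moderately-plus-highly
suitable cells with negative integrated MESS — the reliability screen for
each scenario.

## Change regression

`pair_probabilities()` draws 10,000 random coordinates uniformly over the
jointly valid cells (cell-uniform, then jittered within the cell) and
extracts current and future probabilities, so pairs are complete by
construction and `n` stays exact. One seeded point set is reused across
the 12 scenarios of a report for comparability. `ols_fit()` is ordinary
least squares of $P_f$ on $P_c$; `test_against_theory()` runs two-sided
Student t-tests of $\beta_0 = 0$ and $\beta_1 = 1$ at $\alpha = 0.05$ on
$n-2$ degrees of freedom, flags "expansion" when the fitted line lies
above the identity line at the mean of $P_c$ with a positive intercept,
and withholds decisions (with a flag) when the residual scale is
degenerate — e.g. when the two grids are identical. No multiple-testing
correction is applied across scenarios, matching common practice for this
design; the table reports raw p-values. Type-I error of the slope test is
checked by simulation in the test suite (200 identity-null replicates at
$n = 10{,}000$, noise sd 0.05; empirical size within $[0.03, 0.07]$).

## The synthetic world

Real bioclimatic rasters and occurrence downloads are deliberately outside
the package. `synthetic_world()` builds a complete study system with known
truth instead:

* **Fields**: Gaussian white noise convolved with an isotropic Gaussian
  kernel (length-scale 8 cells by default, truncated at 3 scales,
  reflective boundaries), standardized per layer; optional mixing against
  a shared latent field induces cross-layer correlation.
* **Truth**: a logistic suitability surface
  $\text{plogis}(\beta_0 + \sum \beta_i z_i)$. The default —
  intercept $-5$, $+3$ on `env1`, $-3$ on `env2`, four uninformative
  layers — describes a species occupying roughly 15% of a 100 × 100
  landscape with a sharply climate-determined niche, the regime of an
  aggressive invader that a well-calibrated niche model resolves with
  AUC near 0.9.
* **Presences**: 300 cells drawn proportional to suitability, jittered
  within cells — the inhomogeneous point-process sampling that
  presence-background maximum entropy assumes.
* **Scenarios**: the standard 3 periods × 4 forcing pathways
  (2.6/4.5/7.0/8.5 W m⁻²) as additive shifts whose intensity grows with
  period and forcing (default 0.3 spatial standard deviations per unit
  intensity, toward the niche optimum), giving a monotone favourable
  ladder; zones are a Voronoi partition; the urban mask flags 2% of cells.

What the generator does *not* emulate: the actual definitions of the 19
bioclimatic variables, realistic geography or spatial sampling bias, and
non-additive climate change. Passing recovery tests therefore demonstrate
the correctness of the estimator and pipeline plumbing under the assumed
sampling model — not robustness to the biases of real occurrence data.

## Reproducibility and numerical choices

Every stochastic stage takes a seed derived as
`derive_seed(master, stage_name, index)` — a polynomial hash folded into
31 bits — so inserting a new stage never reshuffles existing streams, and
`run_pipeline()` reruns are byte-identical (asserted in the tests by
comparing output files of two runs). Grid I/O uses 17 significant digits
in ESRI ASCII and 64-bit IEEE floats in GeoTIFF so write→read round-trips
are exact. Degenerate inputs have defined behaviour throughout: constant
variables are dropped from expansions with a warning, constant reference
variables make MESS error out, zero-variance predictors make the change
regression error out, empty zones are flagged rather than divided by
zero.

## Validation design and problem sizes

The test suite checks each component against an independent oracle at
small sizes: brute-force all-pairs counting for AUC, a naive per-cell
loop for MESS, a one-dimensional Newton solver of the Gibbs moment
equation for single-feature fits, closed-form moment formulas for the
regression, and exhaustive component enumeration for thinning. The
end-to-end recovery check runs the full estimator on ten default
100 × 100 worlds with six-replicate ensembles and requires the median
Spearman correlation between the integrated prediction and the truth, and
the median out-of-bag AUC, to reach 0.85; the determinism check reruns a
30 × 30, five-replicate, 12-scenario pipeline twice. The acceptance
script scales the same design to 25 replicates. These sizes are the
package's validation design: large enough that the ensemble statistics
stabilize, small enough to run routinely.

## Known limitations

* Logistic output (with prevalence 0.5) rather than the newer cloglog
  transform; the choice is configurable in spirit but the thresholds
  0.1/0.5 are interpreted on the logistic scale.
* The regularization constants are a simplified stand-in for the
  published interpolation tables.
* No reprojection: all grids must share one lon/lat lattice.
* Plain OLS for the change test — no spatial autocorrelation correction,
  matching the design it mirrors.
* Random points are cell-uniform in lon/lat, not area-weighted; at
  mid-latitudes the cell-area distortion is accepted and documented.
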