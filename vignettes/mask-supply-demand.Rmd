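---
title: "Small-area supply and demand of a rationed good: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area supply and demand of a rationed good: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a rationing episode — the motivating case is Taiwan's 2020 real-name
surgical-mask rationing, where adults could buy nine masks per two weeks
through registered pharmacies — health authorities need to know *where*
supply failed to meet demand at a fine administrative scale. Supply is
observable only indirectly: pharmacies publish their stock level every ten
minutes, not their sales. Demand is only available as census population at
the village level. The two sides live on different spatial supports (store
points versus village polygons), and the ratio of interest, relative risk
of supply, needs uncertainty attached before a village is flagged as
undersupplied.

`maskgap` implements the full chain: inventory preprocessing, change of
support, expected counts, and four Bayesian hierarchical count models with
posterior undersupply probabilities. Because the source inventory archive
is not redistributable, the package ships a synthetic-data generator that
emulates every layer of the data-generating process; all tests and the
acceptance experiments run against it.

## From inventory traces to customers served

For each store the 10-minute stock series is aggregated to one value per
clock hour — the *last* observation in the hour, matching stock-level
semantics (the series is a level, not a flow; the hourly aggregation rule
is a design choice, since only "every hour" is inherent to the procedure).
Consecutive hourly differences are computed; for each calendar date the
sales figure is the sum of absolute *negative* differences. Restocks
(positive jumps) are ignored, but a restock landing in the same clock hour
as sales partially cancels them in the net change; the procedure knowingly
understates sales in that case and no correction is attempted. Average
daily sales over the observed days divided by the ration quota (nine masks
per purchase) gives average customers served per day. `T`, the averaging
denominator, counts calendar days with at least one observation rather
than the full study window, so stores whose feed starts late are not
diluted; with complete feeds the two coincide.

## Change of support

Store-level customer counts are spread over villages in two steps.

1. **Voronoi service areas.** Every point of the study region is assigned
   to its nearest store (Euclidean distance in projected metres). Cells
   are clipped to the rectangular study region so that outer cells are
   bounded and area ratios exist. Stores at identical coordinates are
   merged with their counts summed.
2. **Areal interpolation.** Under homogeneous density within a cell, a
   village receives `count_cell × area(cell ∩ village) / area(cell)` from
   every cell it intersects. When the villages tile the region, total mass
   is conserved exactly; the package asserts this to 1e-9 relative
   tolerance. Degenerate zero-area cells donate their count to the village
   containing the generator point.

The interpolated counts are fractional. Count likelihoods need integers,
so the model uses the half-to-even rounding of `Y_raw` and keeps the
unrounded value alongside; whether the original analysis rounded or used a
continuous approximation is unknowable from the outside, and at a median
count of roughly a hundred customers the difference is immaterial.

Geometry is deliberately minimal: both tessellations in play (Voronoi
cells, and the synthetic villages, themselves Voronoi cells of random
points) are convex, so a Sutherland–Hodgman convex clip computes every
intersection exactly. Tolerances: boundary contact for queen contiguity
uses 1e-6 of the region diagonal; intersection slivers below 1e-9 m² are
dropped.

## Expected counts and relative risk

The demand benchmark is `E_i = r · Pop_i`, with `r = ΣY_i / ΣPop_i` the
overall service rate, so `ΣE = ΣY` by construction and the E-weighted mean
raw relative risk is exactly one. `ρ_i = Y_i / E_i` above one means
oversupply, below one undersupply. Villages with zero population have an
undefined log-offset; they are excluded from the likelihood (and `r` is
computed after the exclusion, preserving the identity), then reported
separately. Finer demand models — indirect standardization by age and sex
— would slot in as alternative `E_i` but are out of scope.

## The four hierarchical models

With `Y_i` the village supply count and `E_i` its offset:

* Poisson: `Y_i ~ Poisson(λ_i = E_i ρ_i)`
* Negative binomial: mean `λ_i`, variance `λ_i + λ_i²/ϑ` (the Poisson is
  the `ϑ → ∞` limit)
* `log ρ_i = b0 + b1 x1 + … + b6 x6 [+ u_i + v_i]`

The six covariates are the pharmacy count, log median income, and the
business / residential / mixed / school land-use fractions — raw, not
standardized, so coefficients stay on the interpretable scale. The spatial
variants add the Besag-York-Mollie pair: `u` an intrinsic CAR field whose
conditional for village *i* is normal around the mean of its queen
neighbours with variance `σ_u²/N_i`, and `v` iid `N(0, σ_ν²)`. Queen
contiguity (a shared boundary point suffices) is the disease-mapping
default and is what "contiguity" is taken to mean here. The CAR mean is
centred at zero; identifiability against the intercept comes from a
sum-to-zero constraint. Islands have no CAR conditional, so their `u_i` is
pinned at zero and their `v_i` absorbs residual variation.

Priors: `N(0, 1000)` on each fixed effect (a concrete reading of "default
vague priors"; with data of this size the likelihood dominates and the
exact choice is immaterial, though sensitivity is cheap to check by
refitting), `Gamma(0.0001, 0.0001)` on both precisions `1/σ_u²` and
`1/σ_ν²`, and `Gamma(0.01, 0.01)` on `ϑ` — weakly informative with
positive support, chosen where the model statement is silent.

### Sampling

Inference is MCMC, written for exactly this model family (the sampler
lives in compiled code; CARBayes-style single-site Metropolis within
Gibbs):

* fixed effects move as one block with a Haario-style adaptive multivariate
  random-walk proposal (adaptation runs during burn-in only and is then
  frozen); covariates are mean-centred internally and the intercept
  transformed back afterwards;
* `u` and `v` move site by site with per-site proposal scales adapted in
  batches toward 0.44 acceptance;
* both precisions are conjugate Gamma draws (the ICAR quadratic form uses
  the rank of `D − A`: non-islands minus components);
* `ϑ` walks on the log scale.

Three structural moves make desk-scale chains mix where plain single-site
updates take tens of thousands of iterations:

1. an exact per-site Gibbs swap `u_i += t, v_i −= t` (the likelihood sees
   only the sum, and the conditional of `t` under the two priors is
   Gaussian), which equilibrates the structured/unstructured variance
   split;
2. an exact Gibbs interweave `b_j += δ, v −= δ x_j` along the
   likelihood-flat direction (Gaussian conditional from the `v` prior),
   breaking the confounding of fixed effects with the iid field;
3. the same interweave against the ICAR field, with the `D − A` quadratic
   form supplying the Gaussian conditional.

The ICAR field is recentred to mean zero every iteration with the shift
absorbed into the intercept — exact on an island-free connected graph,
which the generator guarantees; with islands present the recentring is
skipped and identification rests on the proper intercept prior (flagged
through the reported diagnostics rather than silently). A caveat learned
the hard way and worth recording: *global* directional swaps between the
two fields (moving `u` along its own direction) let the chain fall into
the degenerate ICAR funnel (`u → 0`, `τ_u → ∞`) that vague Gamma priors
leave open, so the package deliberately confines the swap to per-site
moves, which do not reach it.

Defaults are 4 chains × 5000 iterations (half burn-in); the recovery
experiments below use 2 chains × 4000 with 2000 burn-in, which suffices
after the structural moves (split-R-hat on fixed effects typically below
1.05). Chains start from jittered Poisson GLM estimates. Convergence is
summarized with split-chain R-hat and effective sample size; any fixed
effect above 1.1 triggers a warning and a flag on the fit object, never a
silent result.

### Exceedance probabilities

`Pr(ρ_i < 1)` is the fraction of posterior draws of `ρ_i` below one — the
probability a village is undersupplied, the quantity a health authority
would rank by. It is monotone in the threshold by construction.

## Model comparison and diagnostics

* **DIC** in its conditional form: the plug-in deviance is evaluated at
  the posterior means of *all* parameters including random effects, the
  convention of hierarchical-model MCMC software. **WAIC** uses the
  per-observation log-predictive matrix. Which variant the original
  software reports is not knowable; *rankings*, not absolute values, are
  the portable quantity, and the tests assert rankings only.
* **MAPE / MSE** compare posterior-mean relative risks with the raw
  `Y_i/E_i`, on the relative-risk scale: the magnitudes reported for this
  model family (MSE of order 0.002–1.7) are incompatible with count-scale
  errors at a median count of ~10², so the RR scale is the recorded
  assumption, and the count-scale analogues are emitted alongside. MAPE
  skips villages with raw RR of zero and reports how many were skipped.
* **VIF** for each covariate from OLS of that covariate on the other five
  plus an intercept, `1/(1 − R²)`, with the usual below-10 screen.

## What the generator emulates — and what it does not

The generator reproduces the statistical structure the pipeline assumes:
villages as Voronoi cells of uniform points in a square (guaranteeing a
tiling and a connected contiguity graph); adult populations lognormal
around a median of 4268; covariates with the observed marginal shapes
(store counts as a capped Poisson(1.1); income lognormal around 439
thousand NTD with sdlog 0.25; land-use fractions as Dirichlet shares with
concentration (0.4, 1.6, 1.3, 0.25, 4.0) for business, residential, mixed,
school and an unmodelled remainder — so the four shares never exceed one
jointly and the school share is rare and skewed, matching its published
quartiles); inventory as piecewise-constant traces with Poisson daily
sales spread multinomially over 09:00–21:00 selling bins and restocks as
random positive jumps; and counts from the exact model above, with the
ICAR field drawn by eigendecomposition of `D − A` with the null space
removed (sum-to-zero per component by construction). Fixed-effect truth
defaults to the Poisson-spatial posterior means of the motivating study
(intercept 3.702; store 0.124; log-income −0.565; business 0.559;
residential −2.821; mixed −0.990; school 0.467), with precisions 0.497 and
6.380, service rate 0.033, a 49-day window and quota 9.

It does **not** emulate: real road networks or travel behaviour (service
areas are Euclidean), commuting in/out-flows, inhomogeneous within-village
population density, children's masks, or the logistics patterns of real
restocking (restock frequency is a free knob, defaulting to 0.3/day, and
placement can be confined to off-hours for clean oracle tests). Passing
tests therefore certify the *methods* under the model's own assumptions,
not the behaviour of any real retail system.

## Numerical and design choices worth knowing

* Problem sizes in the shipped experiments are the package's own choices
  for a desk run: the recovery experiment uses 20 replicates of 1000
  villages at 2 chains × 4000 iterations; the analysis scripts run a
  400-village region. Full scale (1488 villages, 1774 stores) runs in
  minutes, not hours, thanks to the compiled sampler.
* One global seed drives a named RNG stream per sub-generator, so
  regenerating one artefact never shifts another; a fixed seed fixes every
  output bit for bit.
* Boundary stores are counted in exactly one village (the id that sorts
  first) — an arbitrary but deterministic tie-break.
* Zero-sales stores yield flat traces and zero customers; both are legal
  inputs downstream.
* Aspatial variants drop `u` and `v` entirely (fixed effects only), so
  they are the plain Bayesian GLMs the spatial models are benchmarked
  against.

## Known limitations

The restock-within-hour cancellation biases extracted sales low by
construction; the generator can quantify it (compare the ledger with the
extraction under `restock_bins = "any"`) but the pipeline does not correct
it. The homogeneous-density assumption of areal interpolation is the
standard first-order choice; dasymetric refinement would need ancillary
data the pipeline does not model. The u/v variance split in the BYM model
is only weakly identified at vague priors — fixed effects and relative
risks are the robust outputs, and the precisions should be read with their
wide intervals, not as point estimates. Store-level sampling variance of
average daily sales is not propagated into the village counts.
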