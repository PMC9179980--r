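# maskgap

Small-area estimation of the gap between supply and demand of a rationed
good — the motivating case is adult surgical masks sold through pharmacies
under Taiwan's 2020 real-name rationing system (nine masks per person per
two weeks). The package takes the three raw ingredients of that problem —

1. per-store inventory levels at 10-minute resolution,
2. store locations, and
3. village polygons with adult population and socio-economic covariates,

and produces village-level posterior relative risks of supply with
uncertainty, flagging villages likely to be undersupplied.

## Method

**Supply.** For each store, hourly net stock changes are extracted from the
inventory trace; the daily sales figure is the sum of the negative changes,
and dividing the per-day average by the ration quota (9) gives average
customers served per day. Store-level customers are spread over villages by
Voronoi service areas and areal interpolation (area-weighted under
homogeneous density), yielding the village supply count `Y_i`.

**Demand.** `E_i = r · Pop_i` with `r = ΣY_i / ΣPop_i` the overall service
rate, used as the model offset.

**Model.** Four Bayesian hierarchical count models of the relative risk
`ρ_i`:

```
Y_i ~ Poisson(λ_i = E_i ρ_i)        or  NegBin(mean λ_i, var λ_i + λ_i²/ϑ)
log ρ_i = b0 + b1·stores_i + b2·log(income_i) + b3·business_i
            + b4·residential_i + b5·mixed_i + b6·school_i  [+ u_i + v_i]
```

The spatial variants add the Besag–York–Mollié pair: `u` an intrinsic CAR
(ICAR) field on the queen-contiguity graph — `u_i | u_-i ~
N(mean(u_neighbours), σ_u²/N_i)` with a sum-to-zero constraint — and `v_i ~
N(0, σ_ν²)` unstructured. Priors: `N(0, 1000)` on fixed effects,
`Gamma(1e-4, 1e-4)` on both precisions, `Gamma(0.01, 0.01)` on `ϑ`.
Inference is MCMC (compiled single-site Metropolis-within-Gibbs with exact
interweaving moves; see the methods vignette). Outputs per village: the
posterior of `ρ_i` and the undersupply probability `Pr(ρ_i < 1)`. Models
are compared by DIC, WAIC, and MAPE/MSE of fitted versus raw relative
risks; covariates are screened by variance inflation factors.

Because the source inventory archive is access-restricted, the package
ships a synthetic-data generator (`synth_config()`, `generate_villages()`,
`generate_inventory()`, `simulate_counts()`) that emulates every layer of
the data-generating process at the study's published parameter values, so
the whole pipeline is testable end to end.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
stage reads the previous stage's files under `results/run/`:

```sh
Rscript analysis/01_simulate.R     # synthetic region + inventory traces
Rscript analysis/02_preprocess.R   # traces -> customers served per store
Rscript analysis/03_allocate.R     # Voronoi + areal interpolation -> Y_i
Rscript analysis/04_fit_models.R   # E_i, adjacency, four model fits
Rscript analysis/05_evaluate.R     # DIC/WAIC/MAPE/MSE + VIF
Rscript analysis/06_maps.R         # RR and Pr(RR<1) choropleths
```

A 400-village / 300-store / 14-day run prints, in order:

```
Simulated 400 villages (median adult pop 3983) and 300 pharmacies over a 25 km square.
Preprocessed 300 stores: 3780941 of 3827431 ground-truth sales recovered (98.79%).
Mass conservation relative error: 7.27e-16 (tolerance 1e-9).
Overall service rate r = 0.0147; raw RR: median 0.984, range 0.042-9.741.
Queen contiguity: 1127 edges, 1 component(s), 0 island(s).
```

and the model comparison

```
           model   dic  waic   p_dic  p_waic   mape      mse
         poisson 22233 22708   7.231 431.195 0.9657 1.935499
          negbin  4318  4320   7.448   9.047 1.4342 1.752618
 poisson_spatial  3143  3033 386.159 199.171 0.0251 0.001097
  negbin_spatial  3954  3792 473.966 240.939 0.1715 0.060879

Lowest DIC: poisson_spatial; lowest WAIC: poisson_spatial.
```

The 98.79% sales recovery reflects restocks that land inside selling hours
and cancel sales in the net hourly change — a documented property of the
extraction procedure, not an error. The spatial Poisson model dominates on
every criterion, and its predictive error against the raw relative risks
(MAPE 0.025, MSE 0.0011) is orders of magnitude below the aspatial fits —
the expected behaviour when the supply surface carries spatial structure.
`06_maps.R` then renders the relative-risk choropleths (diverging scale
anchored at RR = 1) and `Pr(RR < 1)` maps, and reports e.g. `190 of 400
villages have Pr(RR < 1) > 0.8 under the Poisson spatial model.`

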