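# rrpersist

Longitudinal genetic analysis of multi-harvest clone trials, for breeders
of perennial crops (elephantgrass and similar biomass grasses) who need to
know not just which clones yield, but which clones *keep* yielding across
growth seasons.

The package fits random regression (RR) mixed models by REML: each clone's
yield trajectory over harvest days is a random polynomial on the
normalized Legendre basis,

    y_ijk = R_k + Σ_m β_m φ_m(t*) + Σ_m α_im φ_m(t*) + Σ_m p_ikm φ_m(t*) + e_ijk

with genotype coefficients α_i ~ N(0, K_g), plot permanent-environment
coefficients p_ik ~ N(0, K_p), and residuals with a homogeneous,
per-harvest diagonal, or unstructured covariance. On top of the fit it
provides:

* **model selection** over polynomial orders and residual structures by
  BIC = −2logL + p·ln(n − rank X), with likelihood-ratio tests of each
  random term (`scan_models()`);
* **covariance-function extraction**: genetic / permanent-environment /
  phenotypic variance and heritability trajectories, genetic values for
  every clone on every day (including harvests with no data), prediction
  accuracy r = sqrt(1 − PEV/σ²g), and eigenfunctions of K_g with their
  proportional eigenvalues (`trajectories()`, `genetic_values()`,
  `accuracy()`, `eigenfunctions()`);
* **a genotype–ideotype persistence index**: the ideotype is the per-day
  maximum genetic value; each clone is scored by the normalized reciprocal
  of its integrated squared deviation from it,
  Persistence_i = 100·(1/D_i)/Σ(1/D_i), D_i = Σ_j (ĝ_ij − max ĝ_j)²
  over every integer day of the evaluation range
  (`persistence_index()`);
* **a synthetic trial generator** with known truth
  (`simulate_trial()`, `elephantgrass_config()`) and an end-to-end
  pipeline (`run_pipeline()`), plus a thin CLI at `inst/cli/rr-persist.R`.

The REML kernel is compiled (RcppArmadillo) and exploits the
block-diagonal structure of the marginal covariance over genotypes,
caching one Cholesky factor per distinct observation pattern — a 12-model
scan over a 1000-record trial takes seconds.

## A worked example

```r
library(rrpersist)

cfg <- elephantgrass_config()        # 100 clones x 2 reps, 5 measured harvests
sim <- simulate_trial(cfg, seed = 1)

run <- run_config(sim$table, cfg$schedule, seed = 1,
                  control = reml_control(n_starts = 1))
report <- run_pipeline(run)
report
#> Longitudinal genetic analysis report
#>   chosen model: Leg3.1.D
#>   h2 range over days: 0.348 - 0.716
#>   eigen-proportions (%): 83.98, 12.88, 3.15
#>   top persistence: G070 (76.40%)
```

Reading the output: the scan preferred a third-order genetic regression
with one residual variance per harvest (`Leg3.1.D`); day-wise heritability
spans 0.35–0.72, so selection is worthwhile at every harvest but weakest
where the environment dominates; ~84% of genetic variation sits in a
constant-over-days eigenfunction (a "general merit" mode), the rest in
season-crossing modes that drive re-ranking; and clone G015 tracks the
per-day best genetic value most closely, taking the largest share of the
persistence index. `accuracy(report$fit, 1090)` gives the prediction
accuracy at the harvest with no field data (mean 91.2% across clones in
this run).

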