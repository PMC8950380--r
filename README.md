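# synsurv

Synthetic cohorts and Bayesian relative survival for cancer-registry data.

## The problem

Population-based cancer registries report survival indicators — relative
survival, conditional relative survival, excess mortality, crude
probabilities of death — stratified by age, stage and treatment factors.
With a few thousand patients, age-by-stage strata quickly become too
small for stable estimates. `synsurv` implements a pipeline that
addresses this for discrete annual follow-up data (the setting of a
breast-cancer registry cohort of women on adjuvant endocrine therapy,
followed 1–10 years):

1. **Probabilistic graphical modeling.** The joint distribution of the
   categorical cohort variables (age group, stage, HER2 status,
   treatment adherence, follow-up year, vital status) is modeled with
   decomposable log-linear graphical models selected by backward
   stepwise edge elimination under the penalized likelihood
   `H(j, k) = -2 log L(j) + k z(j)`, with `z(j)` the model dimension.
   Four criteria are fitted: `k = 1` (GMK1), `k = 2` (GMAIC),
   `k = log N` (GMBIC), and per-edge likelihood-ratio testing at
   α = 0.05 (GMTEST). Missing adherence is imputed from each fitted
   conditional distribution, and a large synthetic dataset (SynD) is
   drawn from each model by junction-tree forward sampling.
2. **Subset selection by integrated Brier score.** The cohort and every
   SynD are partitioned into L = (age groups) × (stages) strata. Each
   cohort stratum is scored against the Kaplan–Meier curve of every
   SynD's matching stratum with the censored
   (inverse-probability-of-censoring weighted) Brier score integrated
   over 0–10 years, `IBS = (1/t*) ∫ BS(t) dt`. The per-stratum argmin
   subsets are merged into one combined synthetic cohort.
3. **Bayesian relative survival.** From annual death counts `O(T)`,
   at-risk counts `Y(T)` and expected deaths `E(T)` (general-population
   life-table rates applied to the at-risk person-time), the observed
   hazard is smoothed with a first-order autoregressive Poisson model
   `O(T) ~ Poisson(Y(T) e^{δ_T})`, `δ_T ~ N(δ_{T-1}, 1/0.001)`, sampled
   by Metropolis-within-Gibbs. Per posterior draw the package derives
   `OS`, `ES`, `RS = OS/ES`, `CRS(T) = RS(T+5)/RS(T)`, `EM = 1 − CRS`,
   and the crude probabilities of death from cancer (`PCa`) and other
   causes (`POC`), reported as medians with 95% credible intervals.

A seeded registry simulator (`registry_config()`, `generate_cohort()`,
`generate_lifetable()`) provides cohorts with known ground truth —
Gompertz population mortality plus configurable stage- and
adherence-specific excess hazards — so the whole pipeline is testable
without any registry access.

## Worked example

```r
library(synsurv)
cfg    <- registry_config(n_patients = 2297, seed = 909)
lt     <- generate_lifetable(cfg)
cohort <- generate_cohort(cfg, lt)

series <- hazard_series(cohort, lt)
fit    <- fit_ar1_poisson(series, n_draws = 2000, n_warmup = 2000,
                          chains = 2, seed = 9)
ind    <- survival_indicators(fit)
```

`series` holds the annual counts the model sees, e.g. (seed 909):

```
    T  O     E    Y lambda_O lambda_P
1   1 73 12.61 2297  0.03178  0.00549
...
10 10 55 19.85 1597  0.03444  0.01243
```

73 deaths were observed in year 1 against 12.6 expected from population
mortality — a clear excess hazard, as configured in the simulator. The
posterior summaries (proportions; multiply by 100 for percent):

```
   indicator  T    median      lo95      hi95
          OS 10 0.7412561 0.7236180 0.7592772
          RS 10 0.8076394 0.7884217 0.8272744
          EM  5 0.1013018 0.0843059 0.1187335
```

Ten-year observed survival is 74.1% against 91.8% expected, giving a
relative survival of 80.8%; the five-year conditional excess mortality
of 10.1% (95% CI 8.4–11.9) says this simulated cohort still dies faster
than the general population after surviving five years. Contrasting
adherence groups:

```r
os10 <- function(sub, seed) {
  f <- fit_ar1_poisson(hazard_series(sub, lt), n_draws = 2000,
                       n_warmup = 2000, chains = 2, seed = seed)
  s <- survival_indicators(f)$summary
  s[s$indicator == "OS" & s$T == 10, ]
}
a <- os10(subset(cohort, adherence == "yes"), 3)
b <- os10(subset(cohort, adherence == "no"),  4)
group_difference(a, b)
#> [1] 14.3
```

Adherent patients show 14.3 percentage points higher 10-year survival —
the simulator's adherence-dependent excess hazards, recovered by the
model.

The full pipeline (four graphical models → imputation → four SynDs →
IBS selection → combined cohort → Bayesian fit) is one call:

```r
pc <- pipeline_config("cohort.csv", "lifetable.csv", out_dir = "out",
                      synd_n = 50000, seed = 11)
res <- run_pipeline(pc)
res$scores          # 9 x 4 IBS matrix with per-stratum selection
res$indicators      # posterior indicators from the combined cohort
```

A command-line front end with the same stages lives at
`inst/cli/synsurv.R` (subcommands `simulate-cohort`, `fit-gm`,
`simulate-syn`, `combine`, `relsurv`, `pipeline`).

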