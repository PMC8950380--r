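---
title: "Methods: synthetic cohorts and Bayesian relative survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts and Bayesian relative survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsurv)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the numerical conventions, what the
synthetic-registry generator does and does not emulate, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. Setting and data model

The package targets population-based cancer-registry cohorts with
**discrete annual follow-up**: each patient contributes an age at
diagnosis (26–74 years, grouped `<=49 / 50-59 / 60-74`), stage
(I/II/III), HER2 status, adherence to endocrine therapy (proportion of
days covered > 80% over five years; possibly missing), a follow-up time
in whole years 1–10, and a vital status. Administrative censoring occurs
at 10 years. A general-population life table supplies the annual
mortality hazard per (age, calendar year); lookups beyond the covered
age range clamp to the nearest covered age, the usual convention for
open-ended terminal age groups.

Everything downstream lives on the annual grid. This is a deliberate
restriction: it matches the data's resolution, makes the product-limit
estimators exact finite computations, and lets the Bayesian hazard model
work directly with yearly counts.

## 2. Decomposable graphical models

The joint distribution of the six categorical variables (age group,
stage, HER2, adherence, follow-up year, vital status — 720 cells) is
modeled by log-linear models whose interaction structure is encoded by
an undirected graph: an interaction term is present exactly when its
variables form a clique. The class is restricted to **decomposable**
(chordal) graphs, for two structural reasons:

* the maximum-likelihood fit is the closed-form junction-tree
  factorization, which iterative proportional fitting (IPF) reaches
  exactly when cliques are visited in running-intersection order — the
  package iterates to a joint-change tolerance of `1e-10`, so clique
  marginals of the fit match the observed ones to numerical precision
  (a tested invariant);
* synthetic records can be drawn *directly* by forward sampling over the
  junction tree, without MCMC.

The model dimension is
`z(j) = Σ_cliques Π levels − Σ_separators Π levels − 1`, separators
counted with multiplicity (an empty separator between disconnected
components contributes 1).

**Search.** Backward stepwise elimination starts from the saturated
(complete) graph. At each step every edge whose deletion keeps the graph
chordal is evaluated; in penalty mode the deletion that most decreases
`H(j,k) = −2 log L + k·z(j)` is taken (stopping when none decreases it),
in test mode the deletion whose deviance increase is least significant
against a χ² with df equal to the dimension drop (stopping when all
remaining deletions are significant at α = 0.05, no multiplicity
correction). Four criteria are exposed: `k = 1`, `k = 2` (AIC),
`k = log N` (BIC), and the test. Ties break on the lexicographically
smallest edge; the comparison is done in difference form so the
degenerate penalties behave correctly (`k = 0` returns the saturated
model, `k = ∞` the empty graph — both tested).

**Age resolution.** The graphical model uses the three-level age group,
not single-year age: with ~1,200 complete cases, 49 age levels would
give an untenably sparse 11,760-cell table. When a synthetic record
needs an exact age (for life-table lookup), it is re-sampled within its
age group from the cohort's empirical within-group (age, diagnosis-year)
distribution.

**Imputation.** Missing adherence is filled by a single seeded draw per
record from the fitted conditional given the record's other five
variables; a zero-probability covariate pattern falls back to the
marginal (counted and reported). After imputation the pipeline *refits*
each model on the completed data before simulating — the refit uses the
full cohort's information, which is why the post-imputation adherence
distribution can differ slightly between criteria.

**Zero cells** are left alone: IPF propagates structural zeros, and the
junction-tree sampler can never reach a zero-probability separator
configuration by construction.

## 3. Scoring synthetic data: censored Brier score and IBS

Synthetic datasets are judged by how well their stratum-level
Kaplan–Meier curves predict the *cohort's* observed outcomes. With
`Ŝ(t)` the predicted survival and `Ĝ` the cohort stratum's censoring
distribution (reverse Kaplan–Meier), the censored Brier score at `t`
averages, over cohort subjects:

* dead by `t`: `Ŝ(t)² / Ĝ(t_i⁻)`;
* under follow-up past `t`: `(1 − Ŝ(t))² / Ĝ(t)`;
* censored exactly at `t`: `(1 − Ŝ(t))² / Ĝ(t⁻)`;
* censored strictly before `t`: 0.

The third category is a boundary decision worth spelling out. A subject
censored at `t` is *known alive* at `t` (censoring means alive at last
contact), and at the administrative horizon `Ĝ(10) = 0`, so the usual
"under follow-up past t" category is empty at `t = 10`. Omitting these
subjects would leave only the deaths in `BS(10)`, making an "everyone
dies" prediction look optimal there; including them with the
left-limit weight keeps the score proper at the horizon. Two further
numerical guards: weights are truncated where `Ĝ` falls below `1e-8`
(heavily censored tails), and at tied times deaths leave the risk set
before censorings in both product-limit estimators.

A formulation note: the score is occasionally typeset with both terms
divided by `Ĝ(t)`; the standard construction (implemented by default)
weights deaths by `1/Ĝ(t_i⁻)`. The uniform-weight variant remains
available via `weighting = "printed"` for sensitivity checks — it
double-counts late censoring and is treated as a typesetting loss, not
a method.

The integrated Brier score is the uniform time average
`(1/t*) ∫₀^{t*} BS(t) dt`, computed by the trapezoidal rule on the
annual grid (the Stieltjes form with weight `W(t) = t/t*` is the same
integral). The Brier curve is evaluated on the annual grid because that
is the data's resolution; a finer grid would only interpolate.

Selection is the row-wise argmin over the L × M score matrix (ties to
the first model in the fixed order GMK1, GMTEST, GMAIC, GMBIC); strata
empty in a synthetic dataset are never selectable, and strata empty in
the cohort are skipped and reported. The winning subsets are merged with
per-record provenance.

## 4. Bayesian relative survival

From the cohort and life table the package builds, for `T = 1..10`:
`Y(T)` subjects entering interval `T`, `O(T)` deaths in `T`, and
expected deaths `E(T) = Σ rate(age_dx + T − 1, year_dx + T − 1) × w`,
with `w = ½` for subjects exiting (death or mid-study censoring) within
the interval and `w = 1` otherwise — Ederer-II-style person-time.
Survivors reaching the administrative horizon are observed for the whole
final year and get `w = 1`; halving them would halve `λ_P(10)` and
fabricate last-year excess hazard, breaking the package's own
null-excess recovery tests.

The observed hazard is smoothed with the autoregressive Poisson model

    O(T) ~ Poisson(μ_T),  log μ_T = log Y(T) + δ_T,
    δ_1 ~ N(0, 1/0.001),  δ_T ~ N(δ_{T−1}, 1/0.001)

i.e. a Gaussian random walk whose *precision* is 0.001 (variance 1000 —
the WinBUGS parameterization; an essentially flat prior that shares
information across adjacent years without forcing a shape). The sampler
is component-wise random-walk Metropolis-within-Gibbs (compiled),
adapted toward 44% acceptance during warmup, frozen afterwards; defaults
are 4 chains × 5,000 draws after 5,000 warmup (tests use fewer — a
run-time choice, stated where made). Split-chain R̂ and effective sample
sizes are computed for every δ; R̂ > 1.05 or ESS < 400 raises a warning
and flags the fit, never silently.

Per draw, with `λ_O(T) = e^{δ_T}` and fixed `λ_P(T) = E(T)/Y(T)`:

* `OS(T) = exp(−Σ λ_O)`, `ES(T) = exp(−Σ λ_P)`, `RS = OS/ES`;
* `CRS(T) = RS(T+5)/RS(T)` for `T = 0..5` (`RS(0) = 1`), `EM = 1 − CRS`
  — with 10-year follow-up these exist only up to `T = 5`;
* crude probabilities by annual quadrature
  `PCa(T) = Σ_u ŌS(u) λ_X(u)`, `POC(T) = Σ_u ŌS(u) λ_P(u)`, where
  `λ_X = λ_O − λ_P` and `ŌS(u) = OS(u−1)(1 − e^{−λ_O(u)})/λ_O(u)` is
  the exact within-interval average of OS under a constant interval
  hazard (limit `OS(u−1)` as `λ_O → 0`).

The quadrature was chosen to make `PCa(T) + POC(T) = 1 − OS(T)` an
*exact* per-draw identity rather than an approximation, and
`EM = 1 − CRS` holds exactly by construction; both are asserted at
`1e-10` in the acceptance suite. Relative survival may exceed 1 and
excess mortality may be negative — nothing is clipped. Point estimates
are posterior medians with 2.5/97.5-percentile credible intervals;
group contrasts are differences of medians in percentage points, rounded
to one decimal with halves away from zero (the convention matching every
printed registry percentage checked).

## 5. The synthetic registry: what it emulates, what it does not

`registry_config()` states a world once and the tests live in it:

* covariate mix approximating a Catalan breast-cancer registry cohort —
  age groups 32.7/29.6/37.7%, HER2+ 24.4%, stage given HER2 from the
  observed two-way counts, adherence 75% in every (age, stage) cell,
  adherence missing completely at random at 45.9%;
* population mortality `λ_P(age) = a·e^{b·age}` with `a = 1.3e-5`,
  `b = 0.10` — a Gompertz curve giving ≈ 0.002 at age 50 and ≈ 0.01 at
  age 70, the order of magnitude of southern-European female mortality;
* constant annual excess hazards per (stage, adherence):
  0.004/0.015/0.050 for adherent stages I/II/III, 0.015/0.045/0.100
  when nonadherent. These were chosen once so that stage-III ten-year
  survival lands broadly in the 30–70% range a registry reports and
  adherence roughly halves the excess hazard, and are not revisited;
* annual dropout hazard 0.01 (registry follow-up is nearly complete),
  administrative censoring fixed at 10 years;
* simulation is discrete-time on the annual grid: per year the death
  probability is `1 − exp(−λ_P(attained age) − λ_X)`, dropout is an
  independent annual draw, deaths win same-year ties. The *latent*
  adherence drives the hazard; the reported value may be missing.

Not emulated: tumor biology, recurrence, treatment switching,
structural (pre-2007) missingness of adherence, regional life-table
detail, and continuous event times. Consequently a green test
establishes that the *pipeline machinery* is correct (distributions are
reproduced, identities hold, known parameters are recovered at stated
Monte-Carlo tolerances) — it does not validate any clinical claim about
real registry populations, which would require the original cohort and
its life tables.

## 6. Degenerate inputs and tie-breaks (summary)

* Every stochastic step takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed and records them in a manifest,
  so stages are independently rerunnable and reruns are identical.
* Empty cohort → explicit errors everywhere; `n = 0` simulation returns
  an empty, correctly typed frame.
* `Y(T) = 0` is rejected by the hazard model; `λ_O = 0` in the
  indicator quadrature uses its analytic limit.
* Non-decomposable candidate graphs are rejected with instructions, not
  silently triangulated.
* All tie-breaks (stepwise edges, IBS selection) are deterministic and
  documented at the call site.

## 7. Known limitations

* The AR(1) smoothing shares strength across years but cannot extrapolate
  beyond year 10; conditional indicators stop at `T = 5`.
* The expected-death convention (half-interval for mid-year exits) is
  one of several defensible person-time rules; it is configurable only
  in the sense of being isolated in `hazard_series()`.
* IBS comparisons use one KM curve per stratum; within-stratum covariate
  structure (e.g. HER2) influences selection only through the graphical
  models, not the score.
* With very small strata the censoring distribution `Ĝ` is noisy and the
  IBS ranking between near-identical candidates is not meaningful; the
  package reports the scores so the user can see how close they are.
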