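---
title: "Somatic alteration burden stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic alteration burden stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nagburden)
```

## The problem

In early-stage non-small cell lung cancer (NSCLC), the total burden of
somatic alteration — not just mutations in driver genes — carries prognostic
information. The working hypothesis behind this package is that counting the
number of *genes* carrying at least one somatic alteration (non-synonymous
mutation, copy-number gain, or copy-number loss) within a prognostic panel
is a more robust burden measure than counting individual variants, and that
a high burden within the right panel marks tumors with *better* outcome:
heavily altered tumors are more likely to present neoantigens and to carry
deleterious hits in genes their cells still need.

The package implements that analysis end to end:

1. **Alteration calling.** A gene is "altered" in a patient if it has at
   least one non-synonymous variant, or its gene-level copy-number log-R
   ratio (LRR) exceeds 0.5 (gain) or falls below −0.5 (loss). Both
   inequalities are strict; an LRR of exactly ±0.5 is neutral. Genes altered
   in fewer than two patients are removed before modelling.
2. **Panel selection.** The binary patient × gene matrix is fitted to
   overall survival (truncated at 5 years) with an elastic-net penalized Cox
   model at mixing parameter α = 0.1; the model maximizing the deviance
   ratio along the λ path defines the panel as the genes with nonzero
   coefficients.
3. **NAG scoring.** Each patient's burden score is the Number of Altered
   Genes (NAG) within the panel, dichotomized at the first quartile (ties to
   "low"; an externally supplied absolute cutoff uses score ≥ cutoff as
   "high").
4. **Expression proxy signature.** Genes differentially expressed between
   NAG groups (|fold change| > 2 on the linear scale and Welch t-test
   p < 0.05 on the asinh scale) are refitted to survival by 5-fold
   cross-validated elastic-net Cox; the resulting linear predictor is the
   expression risk score, thresholded at its third quartile (score ≥ cutoff
   is "high-risk", the direction associated with low NAG). The combined
   classifier labels a patient "better" when NAG is high OR the risk score
   is low.
5. **Immunogenicity.** Each missense variant is applied to its protein;
   all 8–11mer windows covering the altered residue are scored for HLA-A
   binding through a pluggable affinity backend. A peptide is *antigenic*
   if its predicted IC50 is strictly below 500 nM against both patient
   alleles, and *immunogenic* if additionally its source gene and the
   patient's HLA-A gene are expressed strictly above the cohort medians
   (raw RSEM-like scale). A patient with ≥ 1 immunogenic peptide is
   immunogenic, giving the three-way stratification low-NAG /
   high-NAG-non-immunogenic / high-NAG-immunogenic.

## The penalized Cox engine

`encox()` minimizes, over a decreasing λ grid,

$$-\tfrac{1}{n}\,\ell(\beta)\;+\;\lambda\left[\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2\right],$$

where $\ell$ is the Breslow partial log-likelihood for right-censored
survival. Features are standardized internally to unit variance
(coefficients are reported on the original scale); the grid starts at the
smallest λ whose solution is all-zero and descends geometrically over 100
points (ratio 10⁻⁴ when n > p, else 10⁻²). Each λ is solved by an outer
iteratively-reweighted least-squares step (diagonal Hessian of the partial
likelihood) and an inner cyclic coordinate descent with soft-thresholding,
warm-started from the previous λ. The inner loop uses covariance updating —
X′WX is formed once per reweighting, making each coordinate update O(p) —
which is what keeps the pure-R implementation fast at the matrix sizes this
analysis meets (hundreds of patients × tens-to-hundreds of genes).

Numerical choices, all configurable: convergence when the largest
coefficient change in a sweep falls below 10⁻⁷ (standardized scale), a
10⁵-sweep budget per λ, Breslow handling of tied event times, weights
floored at 10⁻¹⁰ where the diagonal Hessian vanishes. `check_kkt()`
verifies the Karush–Kuhn–Tucker conditions of the convex problem at every
λ; the test suite holds them to 10⁻⁶ and additionally checks the solver
against an independent implementation (glmnet) and, in the single-covariate
unpenalized limit, against Newton–Raphson `coxph`.

Two selection rules are provided, matching the two uses of the engine:
`select_by_deviance_ratio()` (maximum fraction of null deviance explained,
ties to the larger λ, i.e. the sparser model) for panel discovery, and
`cv_encox()` (5-fold event-stratified cross-validation of the
Verweij–van Houwelingen partial-likelihood deviance, folds reproducible
from a seed) for the expression signature. On a training path the deviance
ratio is nondecreasing as λ falls, so deviance-ratio selection picks the
least-penalized model of the grid; with α = 0.1 that model is sparse only
insofar as the L1 component zeroes genuinely uninformative genes, which is
the behavior the panel definition relies on.

## Survival statistics

Kaplan–Meier curves, log-rank tests and (multivariate) Cox fits are
delegated to the `survival` package behind thin wrappers that fix the
conventions used everywhere in this analysis: Breslow ties (Efron
optional), events before censorings at tied times, 95% Wald intervals
exp(β ± 1.96 se), and administrative truncation of overall survival at 5
years (an event exactly at the horizon is kept). For a binary covariate the
Cox score test at β = 0 equals the two-group log-rank statistic — the test
suite verifies this identity numerically, and checks log-rank p-values
against a 10,000-draw permutation null.

## The synthetic cohort generator

`simulate_cohort()` draws complete cohorts with known ground truth. It is
not a sequencing simulator: it generates the *statistical* structure the
analysis assumes, so that every stage can be validated against what was
planted.

- **Alterations.** A latent group of patients (default 25%, matching the
  quartile dichotomization) alters the planted panel genes at a low rate
  (0.15) and the remainder at a high rate (0.60); background genes alter at
  0.08 everywhere. The two rates produce the clearly separated burden
  groups the quartile split assumes. Altered gene–patient pairs carry a
  missense variant, a copy-number event (|LRR| drawn in 0.6–2), or both;
  unaltered LRRs stay within ±0.4.
- **Survival.** Exponential event times with hazard
  0.15 · exp(β · (burden − E[burden])) per year (β = −0.05 per altered
  panel gene by default; centring keeps the marginal event rate at the
  baseline regardless of β), independent exponential censoring at 0.05/yr,
  administrative censoring at 10 years. These values give roughly 60%
  events by the 5-year analysis horizon, a realistic figure for untreated
  early-stage disease.
- **Expression.** Gene baselines are drawn on the asinh scale and mapped
  through sinh to a nonnegative RSEM-like scale; the planted signature
  genes are shifted by 2 noise-SD between burden-quartile groups. An HLA-A
  row is always present.
- **Immunogenicity.** A chosen number of high-burden patients (default 8)
  each receive one variant peptide placed on the surrogate affinity
  backend's strong-binder list, with the source gene and HLA-A expression
  forced above the cohort medians — those patients are immunogenic by
  construction, and (because unplanted surrogate affinities never fall
  below 600 nM) nobody else is.

All draws come from R's default Mersenne–Twister stream seeded from the
configuration, so identical configurations are bit-identical, including
after a `write_bundle()`/`read_bundle()` round trip (numerics are written
with 17 significant digits).

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: mutation-calling error, segment-level
copy-number structure and X/Y handling, correlated gene–gene alteration
patterns beyond the single latent group, platform effects and batch
structure in expression, real peptide–MHC binding chemistry (the surrogate
backend is a hash, deliberately void of biology), and any confounding
between clinical covariates and burden (covariates are independent by
default, making multivariate adjustment a null check).

## Verification problem sizes

The shipped checks run at sizes chosen to make each property decidable
quickly while keeping the planted effects in the regime the analysis
targets: window enumeration is exhaustive for proteins up to 40 residues;
KKT verification uses 30 × 50 problems over full 100-point paths; panel and
signature recovery use three 350-patient cohorts through the whole
discovery workflow; the protective-burden detection rate uses 50
default-configuration cohorts (n = 300, β = −0.05); null calibration uses
200 effect-free cohorts of 100 patients. `scripts/acceptance.R` recomputes
all of them from scratch at any seed.

## Design decisions worth knowing about

- **Boundary conventions** are uniformly literal: LRR ±0.5 neutral, NAG
  ties at Q1 low, absolute NAG cutoff ≥ high, risk score ≥ cutoff
  high-risk, affinity strictly < 500 nM, expression strictly above medians.
- **Quantiles** use the type-7 (linear interpolation) convention
  throughout.
- **Fold changes on the linear scale, t-tests on the asinh scale** —
  common expression-analysis practice; raw p-values by default with a
  Benjamini–Hochberg flag available.
- **One binary feature per gene** enters the panel regression (mutation
  and copy-number events are OR-ed), keeping the burden definition and the
  regression features identical.
- **The affinity predictor is configuration, not code**: a precomputed
  table backend reproduces an external predictor's workflow; the surrogate
  exists for verification. The HLA-A supertype map ships as an editable
  TSV covering common alleles, with unmapped alleles flagged
  "unclassified" rather than guessed.
- **Homozygous HLA genotypes** reduce the dual-allele condition to a
  single test, by construction of the per-allele lookup.
- **Validation never refits**: `run_validation()` takes a frozen panel,
  frozen coefficients and frozen cutoffs; refitting a signature on a new
  cohort is an explicit separate call to the discovery machinery.

## Limitations

The solver targets the dense-n, moderate-p regime of gene-level burden
panels; very high-dimensional problems (tens of thousands of features)
would want the compiled implementations this package deliberately mirrors.
DFS endpoints are constructed from follow-up records but not simulated.
MHC class II, HLA-B/C, proteasomal processing and clonality modelling
beyond a scalar VAF per variant are out of scope.
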