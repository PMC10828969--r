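---
title: "Sibling-design heritability under the liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sibling-design heritability under the liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibherit)
```

## The model

A binary phenotype `y ∈ {0, 1}` is modeled as the indicator that a latent
standard-normal liability exceeds a threshold: `y = 1` iff `y* > t`. The
threshold encodes prevalence, `P(y = 1) = 1 − Φ(t)`. For a sibling pair the
two liabilities are bivariate standard normal with correlation ρ, and the
ACE decomposition writes each liability as

    y* = a·A + c·C + e·E,   a² + c² + e² = 1,

with additive-genetic factor A (correlated k_A between siblings: 0.5 for
full siblings, 0.25 for half siblings), shared environment C (correlation 1
for siblings reared together, regardless of sibling type), and unique
environment E (independent). The implied latent pair correlation is
therefore structural:

    ρ_stratum = k_A · a² + c².

Fitting a² and c² jointly to full- and half-sibling strata identifies the
decomposition precisely because k_A differs between the strata; with a
single stratum the likelihood is flat along `k_A·a² + c² = constant`
(`fit_biometric()` refuses such a request, and the flatness is asserted
numerically in the tests). The AE model fixes c² = 0. The liability-scale
heritability is a².

Key assumptions inherited from this formulation: normally distributed
liabilities, no dominance or epistatic variance, equal shared-environment
sharing for full and half siblings, no assortative mating, and a threshold
common to both pair members except for the birth-year trend described
below.

## Pair selection

Registry data give parent links, from which `sibling_clusters()` builds
family clusters as connected components of the relation "shares at least
one parent". Clusters are heterogeneous (a mixed cluster may contain
mutually full siblings), so the analysis selects exactly one pair per
cluster (`select_study_pairs()`):

* **full-only clusters** — a uniformly random index person, and a uniformly
  random full sibling as partner;
* **mixed clusters** — the index is drawn uniformly among members having at
  least one half-sibling (a member without one could not form a half pair),
  and the partner uniformly among the index's *paternal* half-siblings if
  any exist, otherwise among the maternal ones. Paternal priority boosts
  the paternal stratum, which is the more numerous half-sibling type in
  general populations.
* twin partners (`is_twin` flag and the index's birth year) are never
  selected.

One pair per cluster keeps pairs vertex-disjoint and statistically
independent across clusters; a single seeded RNG stream consumed in
cluster-id order makes selection reproducible. Selection depends on the
input row order only through cluster membership, so permuting input rows
under the same seed may change which pair is drawn (documented behavior).

## Tetrachoric likelihood

With member order unobserved, a stratum collapses to counts
`(n11, n10, n00)` and the exchangeable multinomial likelihood

    L(t, ρ) = n11·log P11 + n10·log 2P10 + n00·log P00,
    P11 = P(X > t, Y > t; ρ),  P10 = (1 − Φ(t)) − P11,
    P00 = 1 − 2(1 − Φ(t)) + P11.

`orthant_upper()` evaluates the orthant probability with the deterministic
bivariate algorithm of `mvtnorm::pmvnorm()` (absolute error well below
1e-10); the degenerate cases ρ = ±1 use closed forms. Since the model has
two parameters and the collapsed table two degrees of freedom, the MLE is
saturated when interior: the fitted threshold equals the probit of the
observed member prevalence, and ρ solves `P11 = n11/n`. The optimizer
(Nelder-Mead on `(t, atanh ρ)`, relative tolerance 1e-10, multistart from
ρ ∈ {0, ±0.3}) is retained rather than the fixed-point form because it
generalizes unchanged to the covariate-adjusted and joint models, and the
saturation identity then serves as an internal consistency test. Standard
errors come from the numerically differentiated observed information;
`se(ρ)` is mapped from the `atanh` scale by the delta method. An
all-unaffected table returns ρ at the lower boundary flagged
non-converged; other single-cell tables are rejected.

`fit_tetrachoric_adjusted()` replaces the common cutoff by
`t_i = β0 + β1·(year_i − reference_year)` and maximizes the pair-level
likelihood with member-specific cutoffs. Identical `(year1, year2,
outcome)` rows are aggregated first, so the cost scales with the number of
distinct year combinations rather than pairs. When prevalence trends over
cohorts and siblings are born close together, the trend masquerades as
within-pair correlation in the unadjusted fit; the adjusted fit removes
that bias (demonstrated by simulation in the tests). With no birth-year
variation the slope is non-identifiable and the function falls back to the
unadjusted fit with a warning. The reference year defaults to 1980, the
midpoint of the default 1950–2010 range; it only re-anchors β0.

## Joint biometric fit

`joint_neg_loglik()` sums the stratum likelihoods with ρ replaced by
`k_A·a² + c²`, sharing one threshold model `(β0[, β1])` across strata — a
single prevalence process for all siblings, which matches how the strata
are drawn from one population. `fit_biometric()` maximizes it with
variance components constrained nonnegative (L-BFGS-B with box bounds,
multistart a² ∈ {0.1, 0.3, 0.6}, followed by a Nelder-Mead polish;
infeasible regions — implied ρ at 1 or a nonpositive cell probability —
return a large sentinel). Confidence intervals are delta-method intervals
from the inverse observed information evaluated at the constrained optimum
*without* re-imposing the bounds: a component estimated on the boundary
(typically c² = 0) then shows a lower bound slightly below zero, the
conventional presentation of biometric software. `e² = 1 − a² − c²` always,
with its variance from the summed covariance. `likelihood_ratio()`
compares AE within ACE; since c² sits on the boundary under the null, the
chi-square p-value is conservative.

On full siblings alone, AE reduces to the saturated tetrachoric fit with
a² = 2ρ̂ — an identity used as a cross-check in the tests.

## What the synthetic generator emulates

`simulate_registry()` draws family clusters and children whose liabilities
have exactly the assumed covariance structure: additive values built by
parental transmission (`A_child = (A_mother + A_father)/2 +` Mendelian
deviation of variance ½, so sibling additive correlations are exactly
0.5/0.25), shared environment drawn once per cluster, and a
birth-year-linear threshold. Defaults describe a rare-trait registry study:
baseline prevalence 0.0017, a² = 0.29, c² = 0, birth years uniform on
1950–2010 (weights configurable to mimic cohort skew), 16% of clusters
mixed with 66% of those paternal — ratios matching the stratum proportions
of the bundled study — and cluster sizes 2–4 from a truncated geometric
distribution. The size distribution is a convenience: only pair counts, not
sibship sizes, are known for the bundled study, so it is exposed in the
configuration and makes no claim of realism.
`simulate_pair_phenotypes()` is the fast path for fitter validation: it
draws correlated liability pairs directly and collapses them, bypassing
pedigree structure.

The generator deliberately omits features of real registry data: mortality,
emigration and diagnosis-date censoring; sex-specific prevalence; twins;
dominance variance; assortative mating; and ascertainment artifacts.
Passing simulation tests therefore demonstrates correctness of the
estimators under the model's assumptions — not robustness to those
violations in real data.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:

* the tetrachoric MLE against an exhaustive `(t, ρ)` grid search at 1e-3
  resolution on random small tables, where the oracle computes orthant
  probabilities by an unrelated route (cumulative integration of the
  bivariate density over ρ, via the Plackett identity);
* concordance and prevalence arithmetic against the bundled study tables;
* parameter recovery of the AE fitter on 20 replicates simulated at the
  bundled study's stratum sizes (1,748,528 / 117,298 / 226,196 pairs,
  prevalence 0.0017, a² = 0.29) with mean error required below 0.03, and
  null (a² = c² = 0) ACE recovery with mean estimates below 0.02 on 10
  replicates;
* registry-path recovery on one million simulated full-sibling pairs,
  checking the fitted ρ against the structural value ½a²;
* pipeline determinism byte-for-byte under fixed seeds.

Monte-Carlo assertions use 3-standard-error bands (or the fit's own
standard error) under fixed seeds.

## Known limitations

* Exact reproduction of a published joint heritability estimate from
  collapsed tables alone is not generally possible when the original
  analysis adjusted thresholds for birth year at the individual level: the
  collapsed tables no longer carry that information. The package fits both
  the crude and the adjusted forms; on the bundled collapsed tables the
  joint AE estimate is higher than the published birth-year-adjusted one,
  as expected from this information loss.
* Half-sibling strata of rare traits are extremely sparse (single
  concordant pairs); their tetrachoric standard errors are several times
  the full-sibling one, and c² is weakly identified in ACE fits.
* The chi-square reference for the AE-vs-ACE likelihood ratio ignores the
  boundary constraint and is conservative.
* Delta-method intervals on the variance-component scale can extend
  outside [0, 1] for sparse data; they are reported as computed.
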