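---
title: "Methods: ranking antihyperglycemic regimens with balance-regularized propensity networks and Bayesian NMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking antihyperglycemic regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycorank)
```

This vignette is the package's account of the statistical machinery:
what each stage assumes, which knobs matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## 1. From event histories to analysis snapshots

The unit of analysis is a **snapshot**: a pair of consecutive HbA1c lab
events for one patient. The first (index) lab must read ≥ 9% — the
population of interest is poorly controlled type-2 diabetes — and the
observation period between the labs must be 90–365 days, long enough for
HbA1c (a ~90-day average of glycemia) to respond to a regimen and short
enough that the attributed regimen plausibly explains the change. Both
endpoints of the window are inclusive; shorter or longer gaps, single-lab
patients, and sub-9% index values are dropped and counted in a filter
log.

The exposure is the **treatment regimen**: the set of antihyperglycemic
drug classes with a prescription satisfying
`fill_day <= day < fill_day + days_supply + 30`, the 30-day grace period
absorbing imperfect refill adherence. Regimens are identified at the
class level and represented canonically as the sorted `+`-join of class
names, so set equality is string equality. The snapshot's regimen is
attributed at the **terminal** lab: if treatment changed during the
observation period, the change in HbA1c is credited to the new regimen.
The regimen covering the index lab defines `prior_regimen` and insulin
status. Untreated snapshots are excluded (the comparison of interest is
between active regimens). Duplicate same-day HbA1c values keep the last
recorded, with a warning — an arbitrary but deterministic tie-break.

Patient-level exclusions (type-1 diabetes, age under 18, gestational
diabetes, ketoacidosis history, cystic fibrosis, solid-organ transplant)
remove patients whose glycemic management follows different rules. The
ten clinical cohorts A–J partition snapshots by insulin status at index,
age (< 65 vs ≥ 65 at the index lab, computed as
`(index_day - birth_day)/365.25`), and the unweighted Charlson
comorbidity count (distinct categories ever diagnosed up to the index
day). The partition is total: every valid snapshot maps to exactly one
label.

Confounders are measured at the index day: Charlson category indicator
flags, the most recent EGFR and creatinine (unbounded lookback — no
recency window is imposed, because the generator and typical claims data
record these sparsely), age, sex, area-level income and race-fraction
proxies, and the index HbA1c itself. Missing numeric values are imputed
to the **within-cohort training-set mean**, with a 0/1 missingness
indicator appended per affected field so that informative missingness
remains adjustable-for. Age and sex are structural and never imputable.
The train/test split is snapshot-level at 80/20 by default; a
patient-level option exists because snapshot-level splitting lets one
patient span both sets, which slightly flatters held-out evaluation.

## 2. Balance-regularized propensity scoring

Each case–comparator study fits a propensity network minimizing

$$L_{TOTAL} = L_{BCE} + \nu\,\mu\,L_{BIAS},$$

where $L_{BCE}$ is the mean binary cross-entropy of predicting the arm
and $L_{BIAS}$ is the mean over covariates of the squared
IPTW-weighted standardized mean difference (SMD). The squared SMD is
differentiable and dimensionless, which is why it is the balance
penalty. $\mu = L_{BCE}/L_{BIAS}$ is recomputed each epoch and treated
as a constant in the gradient, so the two terms enter at comparable
magnitude and the single dimensionless knob $\nu$ (default 1) sets the
user-facing trade-off; $\nu = 0$ recovers a plain cross-entropy
propensity classifier.

Architecture and training are deliberately small: one hidden layer
(width 32 by default), ReLU activation, sigmoid output, full-batch Adam
(learning rate 0.01, 200 epochs), covariates standardized internally.
At the scale of a per-cohort pairwise study (hundreds to a few thousand
snapshots, a few dozen covariates) this trains in well under a second
per study and is exactly reproducible given the initialization seed.
The returned model is the epoch checkpoint with the **most balanced
covariates** (|weighted SMD| below the 0.1 threshold — the conventional
balance criterion in standardized-difference units), ties broken by
lower $L_{BCE}$. Because the initial state is itself a candidate,
training can never select a checkpoint with worse balance than epoch 0.

Numerical choices: propensities are clipped to [0.01, 0.99] before
weighting to bound IPTW variance; inside the balance loss they are
softly bounded to [0.005, 0.995] with the gradient masked where the
bound binds; zero-variance covariates get SMD 0 by convention and are
excluded from the balance gradient. Arms with fewer than 2 snapshots
are refused (a typed condition that `run_all_pairs()` records as a
skipped study); arms below 36 snapshots fit but are flagged, since the
evidence-network stage excludes them anyway.

## 3. IPTW effects and the bootstrap

The ATE on ΔHbA1c is the Hájek (normalized-weight) difference of
weighted arm means — bounded and standard for IPTW, unlike the
Horvitz–Thompson form. Uncertainty comes from resampling snapshots with
replacement **within each arm** (so no replicate loses an arm), B = 200
by default. The default replicate re-uses the fitted propensity scores
and recomputes weights and weighted means ("weights" mode); a full
BCAUS refit per replicate is available by configuration. The re-use
mode treats the propensity model as fixed, which is fast and
*conservative*: estimated-propensity IPTW has smaller true sampling
variance than fixed-weight IPTW when the outcome depends on the
balanced covariates, so re-use-mode intervals tend to over- rather than
under-cover in that regime. The package's coverage experiment therefore
uses a design in which the outcome's covariate dependence is weak, where
the mode is correctly calibrated; the conservatism elsewhere is a known
property, not a defect the tests hide.

## 4. Network meta-analysis and SUCRA

Per cohort, regimens with **more than 35** training snapshots become
nodes; every completed pairwise study whose covariates all balanced
becomes an edge (unbalanced studies are trimmed — their effect estimates
are not confounder-adjusted in the intended sense). If trimming
disconnects the graph, only the component containing the baseline is
analyzed and the rest reported as excluded. The baseline is metformin
monotherapy, the consensus first-line therapy; if it is absent from the
retained nodes the largest-arm regimen substitutes, and the substitution
is recorded.

The random-effects model for edge $e$ between case $a$ and comparator
$b$ is

$$ate_e \sim N(\theta_e,\ se_e^2), \qquad
  \theta_e \sim N(d_a - d_b,\ \tau^2),$$

with basic parameters $d_k$ (ΔHbA1c vs baseline, $d_{baseline} \equiv
0$), priors $d_k \sim N(0, 10^2)$ and $\tau \sim$ HalfNormal(5) on the
%-HbA1c scale — wide relative to any plausible glycemic effect, i.e.
uninformative in context. The implementation marginalizes the per-edge
random effect analytically ($ate_e \sim N(d_a - d_b, se_e^2 + \tau^2)$):
the posterior is identical, but the hierarchical form funnels as
$\tau \to 0$ and mixes pathologically under Gibbs sampling, while the
marginal form is well behaved. Sampling uses JAGS with 4 chains, 2,000
warmup and 2,500 retained iterations per chain, each chain seeded
deterministically. (Shorter 1,000/1,000 runs were considered but leave
$\tau$'s split-chain diagnostic above threshold on sparse three-edge
networks.) Convergence is judged by split-chain potential scale
reduction ≤ 1.05 on every free parameter; unconverged posteriors are
returned but `sucra_ranks()` refuses them unless forced.

Ranking: for each posterior draw, a predictive ATE vs baseline is
sampled for each regimen — $d_k$ plus, by default, a new-study
heterogeneity draw $N(0, \tau^2)$; whether ranking draws should include
$\tau$ is genuinely open, so a `include_tau = FALSE` mode ranks on
$d_k$ draws directly. The baseline's ATE is identically 0. Regimens are
ranked ascending (most negative = rank 1), exact ties averaged
(measure-zero in practice), and SUCRA is the normalized mean rank
$(T - \bar r_k)/(T - 1)$: 1 means always best, 0 always worst, and
SUCRA scores sum to $T/2$ exactly.

## 5. Ranking validation

Concordance splits a cohort's snapshots by whether the prescribed
regimen equals (set equality) one of the top-3 ranked regimens;
regimens absent from the ranking (below the node cutoff) are
non-concordant. Group means of ΔHbA1c are compared by a Welch
(unequal-variance) two-sample t-test — the safer default when group
sizes and variances differ — at α = 0.05 with no multiplicity
correction across cohorts; a correction option exists but is off by
default to match the gate as specified. Only when the gate passes is a
confounder-adjusted study run, with concordance as the binary
"treatment", reporting the IPTW ATE and bootstrap CI. Rankings are
always fit on training snapshots; test snapshots are evaluated against
the train-derived ranking. The tiered sensitivity analysis (ranks 1–3 /
4–10 / 11 and below, unranked regimens falling in the bottom tier)
reports top-vs-bottom and middle-vs-bottom adjusted ATEs; with fewer
than 11 ranked regimens tiers truncate with a warning and empty
comparisons are skipped with a reason. Rank-trajectory descriptives
summarize treatment switching across a patient's consecutive snapshots:
switch incidence, fractions of switches improving/worsening rank, and
mean rank movement.

## 6. The synthetic-data generator

The generator produces the four-table claims schema (labs,
prescriptions, diagnoses, demographics; dates as integer day offsets
from a simulation epoch, avoiding calendar arithmetic) with a known
causal structure:

- **Assignment** is multinomial logistic over six standardized
  covariates (age, sex, comorbidity count, log income, EGFR, index
  HbA1c) with coefficients drawn once per simulation from
  $N(0, \text{confounding\_strength}^2)$ — simple, and invertible for
  propensity-recovery tests since the true pairwise propensity between
  two regimens is available in closed form from the stored
  coefficients.
- **Outcome**: terminal HbA1c = index + true regimen effect + linear
  covariate terms (scale `outcome_confounding`, default 0.3) + Gaussian
  noise (`outcome_noise_sd`, default 0.8 percentage points, in the
  range of residual HbA1c variability over ~6 months). Effects are
  additive with no effect modification, so the true ATE between two
  regimens is exactly their effect difference.
- **Defaults**: 12 regimens spanning 1–5 classes with true effects
  −2.2 to −0.8 points; index HbA1c uniform on [9, 12.5]; 2–4 labs per
  patient at 90–365-day gaps (every candidate pair duration-valid, so
  attrition comes from the index-value rule, matching the observation
  that most patients contribute about one snapshot); Charlson-category
  prevalences between 1% and 30%; 10% missingness in EGFR/creatinine
  and 5% in area income; adult ages 21–85. Prescription fills are
  placed so the assigned regimen covers exactly its terminal lab, and a
  prior fill covers only the first index lab (fixing insulin status at
  the first index).

What it does **not** emulate: realistic ICD/NDC coding (diagnoses are
abstract category codes — the analysis only consumes category flags),
billing or procedure claims, realistic census geography (income and
race proxies are scalar draws), non-adherence, effect modification, or
unobserved confounding. Consequently, passing tests demonstrate that
the pipeline recovers known effects *when its assumptions hold*; they
say nothing about unconfoundedness in real claims data.

## 7. Problem sizes and determinism

The test suite and `scripts/acceptance.R` size their simulations for a
desk machine: recovery experiments use cohorts of roughly 1,500–2,600
patients (2,000–4,000 snapshots) over 20 seeds, coverage experiments
200 replications of n = 400 with B = 100, the end-to-end ranking
experiment one 12-regimen population with a 66-study evidence network,
and the null-calibration experiment 100 seeds of small cohorts. Studies
within the test suite shrink the propensity network (width 8–16, 40–150
epochs) — balance quality at these sizes is verified by the tests
themselves. Every stochastic component (generator, weight
initialization, bootstrap, MCMC chains, ranking draws) takes an
explicit seed; the pipeline derives fixed per-stage substreams from one
global seed, so stages are independently rerunnable and artifacts are
byte-reproducible.

## 8. Known limitations

- Pairwise studies within a cohort share snapshots, so the edge ATEs
  fed to the NMA are correlated and network-synthesized variances are
  likely understated; no cross-study correlation correction is
  attempted.
- Multi-arm propensity in a single model, doubly-robust estimators and
  matching are out of scope; each comparison is an independent binary
  study.
- NMA inconsistency diagnostics (node splitting) are not implemented;
  the tests check consistency only on simulated consistent networks.
- Rankings are point-estimate orderings over posteriors with
  overlapping uncertainty; SUCRA scores should be read with their
  credible intervals, not as a definitive hierarchy.
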