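---
title: "Dynamic, model-based case ascertainment from administrative claims"
author: "CaseLoDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic, model-based case ascertainment from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaseLoDA)
```

## The problem

Administrative health data — physician billing claims and hospital discharge
abstracts — are routinely used to identify chronic disease cases for
surveillance and research. The standard tool is a *deterministic case
definition*: a fixed rule such as "one hospitalization, or two physician
visits 8 weeks to 2 years apart, with a relevant ICD code". For episodic
diseases such as juvenile arthritis (JA), where periods of intense healthcare
use alternate with periods of apparent health, summary rules of this kind can
misclassify, and they only deliver a verdict once the whole observation
window has elapsed.

`CaseLoDA` implements the alternative this package is about: *model-based
dynamic classification* by longitudinal discriminant analysis (LoDA).
Group-specific statistical models of annual healthcare utilization are fitted
to gold-standard cases and controls; each new individual's accumulating
utilization history is then scored after every measurement occasion, and the
individual is assigned to the case or control group — or deliberately left
*indeterminate* — as soon as the evidence suffices. The package also
implements the deterministic comparator and a cross-validated evaluation
harness, all driven by a synthetic claims generator so every component is
testable end to end.

## Data model

Follow-up spans birth to the 16th birthday (the diagnostic age limit for JA)
on 15 measurement occasions: ages [0, 2) form one merged occasion, because
disease-specific utilization is sparse in infancy, and ages [j, j+1) for
j = 2..15 are annual occasions. Four utilization markers are measured per
occasion:

| marker | type | definition |
|---|---|---|
| `ja_contact` | binary | any JA-related diagnosis code (ICD-9 categories 696, 713, 714, 716, 720; ICD-10 M05–M09, M45) on a claim or hospital abstract |
| `gp_visits` | count | ambulatory general-practitioner visits |
| `specialist_visits` | count | ambulatory specialist visits |
| `hospitalization` | binary | any non-newborn hospitalization |

A cohort is stored as a `UtilizationCohort`, a `SummarizedExperiment` with
the four markers as assays (occasions × individuals), covariates and the
gold-standard group label in `colData`, and the occasion grid in `rowData`.
Claim-level data are a plain table of dated records (physician claim or
hospital abstract, provider class, ambulatory/inpatient setting, ICD version,
diagnosis codes, newborn flag).

## The group-specific models

For group $g$ (case or control) and marker $r$, observation $Y_{irj}$ of
individual $i$ at occasion $j$ follows a generalized linear mixed model

$$h_r^{-1}\{E(Y_{irj} \mid b_{ir})\} = \mathbf{x}_{ij}^\top
\boldsymbol\alpha_r^g + b_{ir}, \qquad b_{ir} \sim N(\mu_r^g, \sigma_r^{g2}),$$

with a logit link for the binary markers (Bernoulli) and a log link for the
counts (Poisson), dispersion fixed at 1. Fixed covariates are sex (male
indicator), region of residence at birth (urban indicator) and age, coded as
the occasion's representative year (1 for the merged first occasion, else the
year itself; the original analysis treats age as continuous but does not
state its coding, so this single-representative-year coding is our choice).
No exposure offset is used for the two-year first occasion — the longer
period is absorbed by the model, consistent with treating the merge as a
sparsity fix rather than an exposure change. Random intercepts are
independent across markers (only per-marker intercept SDs are identified by
the reported summaries; no cross-marker correlations), so the multivariate
model factorizes over markers given the covariates, and the random-effects
distribution has a single normal component (`nMixtureComponents = 1`; the
mixture interface is reserved but deliberately unimplemented).

Two specifications are bundled: the *JA utilization model*
(`mglmmSpec("ja_utilization")`: the single `ja_contact` marker) and the
*full model* (all four markers).

### Priors and estimation

Priors are weakly informative on the link scale: fixed effects and the
random-intercept mean $\mu$ are $N(0, 10^2)$; the random-intercept SD
$\sigma$ is half-normal with scale 5. Estimation is by MCMC
(`fitMglmm()`): the random intercept is integrated out of each individual's
likelihood by *adaptive* Gauss–Hermite quadrature (15 nodes by default,
recentred at the conditional mode and rescaled by the curvature — plain
quadrature fails badly once a subject's accumulated counts make the
conditional posterior of $b$ much narrower than $N(\mu, \sigma^2)$), and the
resulting 5-parameter marginal posterior per marker is sampled with a kernel
that mixes an independence proposal (multivariate $t_{15}$ centred at the
Laplace mode with 1.1× Laplace covariance; acceptance is typically 0.7–0.85
because the posterior is near-Gaussian at these sample sizes) with
random-walk moves (10%, Robbins–Monro scale adaptation during burn-in).
Because covariates enter only through the male/urban indicators and the
occasion ages, each likelihood evaluation collapses onto sufficient-statistic
profiles and is independent of raw cohort size.

Sampler defaults follow the study protocol: 10 000 iterations per chain,
first 1000 discarded as burn-in, thinning 1:100, two chains (so the
Gelman–Rubin diagnostic is computable; `psrfTable()` reports the
Brooks–Gelman point estimate and upper limit, with upper < 1.02 as the
operational convergence criterion). The protocol's own accounting of
"9000 samples used for inference" versus 1:100 thinning is internally
inconsistent; here burn-in and thinning are independent knobs and the kept
count is `(iterations − burn-in) / thin` per chain.

### Model fit

`penalizedExpectedDeviance()` compares specifications on the same data:
expected marginal deviance plus an optimism penalty, lower is better. The
penalty uses the asymptotic approximation $p_{\mathrm{opt}} = 2 p_D$ (twice
the effective number of parameters) computed from pooled chains rather than
the exact cross-chain importance-sampling estimator; with a single chain it
degrades to a DIC-style penalty $p_D$ with a warning.

## Group-membership probabilities

Given fitted case and control models, Bayes' theorem gives, for each
posterior draw $m$ and occasion $j$,

$$\mathcal{P}^{(m)}_{\mathrm{case}}(j) =
\frac{\pi_{\mathrm{case}} f^{(m)}_{\mathrm{case}}(\mathbb{Y}_{i,1:j})}
{\pi_{\mathrm{case}} f^{(m)}_{\mathrm{case}}(\mathbb{Y}_{i,1:j}) +
 \pi_{\mathrm{control}} f^{(m)}_{\mathrm{control}}(\mathbb{Y}_{i,1:j})},$$

with naive priors $\pi = (0.5, 0.5)$ by default. The predictive density
$f_g$ of the accrued history comes in three flavours
(`computeProbabilitySeries()`):

* **marginal** — random intercept integrated out (Gauss–Hermite, 31 nodes
  by default; adaptive for Poisson markers);
* **conditional** — likelihood evaluated at $\hat b$, the per-draw posterior
  mean of the intercept given the accrued history ($\hat b$ is computed
  exactly from the same quadrature rule rather than by 1-D optimization plus
  a Laplace correction; a posterior-mode estimator is available via
  `bEstimator = "mode"`);
* **random effects** — the density $\varphi(\hat b; \mu, \sigma)$ of the
  estimated intercept under the group's random-effects distribution.

All density work is in log space — a history of 15 Bernoulli/Poisson terms
underflows linear space — and each draw's own parameters produce its own
probability (fully Bayesian propagation), so the per-draw distribution of
$\mathcal{P}_{\mathrm{case}}$ yields a meaningful credible interval
(equal-tailed, 99% by default, following earlier work on CrI-based
allocation). Case and control draws are paired by index; both fits are
truncated to the smaller draw count.

## Dynamic classification

`selectCutoff()` chooses the probability threshold minimizing
$d^2 = (1-\mathrm{Sens})^2 + (1-\mathrm{Spec})^2$ — the ROC point nearest
the top-left corner — over the midpoints of adjacent sorted unique
probabilities plus {0, 1}; ties break toward 0.5. In cross-validation the
cutoff is selected per fold on the *training* individuals' final-occasion
point estimates (the original report does not say which occasion's ROC was
used; final-occasion probabilities are the most informative and keep the
test fold untouched).

`classifySequential()` scans occasions in order. Under the CrI scheme an
individual is allocated to the case group as soon as the whole credible
interval lies strictly above the cutoff, to the control group when it lies
strictly below, and otherwise stays indeterminate; intervals touching the
cutoff remain indeterminate (boundary behaviour is unstated in the source
analysis; strictness is the conservative choice). The first allocation
freezes: later occasions never revise it. The decision age is the upper age
bound of the deciding occasion (occasion 1 → 2 years, occasion 15 → 16
years), which makes "mean classification time" the mean of decision ages
over classified individuals; never-classified individuals are excluded from
that mean and reported separately. The point scheme (`scheme = "point"`)
allocates on the point estimate alone and never abstains.

## The deterministic comparator

`caseDefinitionRule()` encodes the validated claim-level definition: within
the age window, one or more non-newborn hospitalizations with a relevant
code (ICD-9 714, 720; ICD-10 M05, M06, M08, M45 — note this is a *narrower*
set than the contact-marker set), or two or more physician visits with a
relevant diagnosis such that *some* pair (not necessarily consecutive) of
visit days is 56–730 days apart, both bounds inclusive ("at least eight
weeks", "no more than two years"). Any relevant code qualifies a visit; the
two visits need not carry the same code. `windowedRules()` adds the two
restricted windows — ages [0, 2) and [14, 16) — used as sensitivity analyses
for settings where only short data windows exist.

## The synthetic-data generator

`generateCohort()` emulates the structure of the linked registry/claims
cohort the methods assume: 797 children by default, 48.4% cases, 65% female,
57.2% urban, income quintile uniform on 1..5 (descriptive only — it is not a
model covariate). Marker values are drawn from the group-specific GLMMs
above; the default generating parameters are the full-model posterior means
reported for the Manitoba JA setting (e.g. case-group `ja_contact`:
male −0.59, urban −0.24, age +0.21, intercept mean −1.77, SD 1.60; control
intercept mean −4.74), which reproduce the qualitative cohort patterns —
JA-contact prevalence rising with age among cases (~14% early to ~65% at the
last occasion) while staying rare among controls, and GP/specialist/
hospitalization intensity declining from an infancy peak.

`generateClaims()` inverts the measure definitions, emitting dated claim
records exactly consistent with each annual measure row: ambulatory GP and
specialist claim counts equal the respective measures; a JA-related code is
present iff `ja_contact = 1`; a non-newborn hospital record exists iff
`hospitalization = 1`; claim days are uniform within the occasion's day span
(365.25 days per year; day→occasion mapping is `floor(day/365.25)` with
years 0–1 merged). Claim-placement choices the measures do not pin down are
explicit parameters: a JA code lands on a specialist rather than GP visit
with probability 0.8 (rheumatology contacts are specialist contacts), each
further ambulatory claim in a contact year also carries a JA code with
probability 0.5 (active disease years produce repeated coded visits — the
pattern the deterministic definition's spaced-pair arm is built around),
the code rides on a hospital record with probability 0.2 when one exists,
and when an
occasion has a JA contact but no ambulatory claim and no hospital record it
is emitted as an in-hospital/ER physician claim — which feeds the contact
marker but neither the ambulatory counts nor the hospitalization marker, so
the round trip stays exact. JA codes are drawn over the category roots with
most mass on juvenile/rheumatoid arthritis (714 / M08), so most but not all
JA contacts also satisfy the deterministic definition's narrower code set.
Physician claims are always ICD-9 (ambulatory billing predates the ICD-10
transition); hospital records carry either version, and the version is a
per-record field because the synthetic world has no calendar. A newborn
birth record (probability 0.9) is emitted with non-JA codes only.

What the generator deliberately does *not* emulate: calendar/fiscal-year
structure, migration and loss to follow-up (the study design requires
continuous coverage), real ICD dictionaries beyond the listed categories,
within-year clustering of visits (days are uniform in the span), and
correlation between markers beyond what the shared covariates induce
(random intercepts are independent across markers). Passing tests therefore
demonstrate the pipeline's internal correctness and its behaviour under the
assumed data-generating process — not performance on real claims, where
marker dependence, coding drift and referral patterns are richer.

## Evaluation harness

`runCrossValidation()` performs five-fold cross-validation: simple random
fold assignment (sizes within one of each other), per fold fitting both
group models on the training folds, scoring the held-out individuals at
every occasion, selecting the training-fold cutoff, classifying
sequentially, and tabulating a confusion matrix that keeps the indeterminate
category. Sensitivity and specificity are reported both over the entire
cohort (`all_data`: indeterminates count against the classifier) and over
classified individuals only; PPV and NPV never include indeterminates in
their denominators. Fold metrics are averaged unweighted, and
pooled-confusion metrics are also reported. Binomial interval estimates use
the Wilson score method (small fold denominators make Wald intervals
degenerate; the interval method is not stated in the source analysis). AUC
is the rank-based (Mann–Whitney, ties averaged) area computed from
final-occasion point probabilities of all individuals — including those
frozen earlier. The per-occasion evolution table propagates the frozen
decisions, so the proportion unclassified is non-increasing by construction.

## Numerical choices and degenerate inputs

* Quadrature: 31 Gauss–Hermite nodes for prediction, 15 for fitting;
  Poisson integrands use the adaptive recentring described above, which
  matches dense-grid integration to better than $10^{-6}$ relative error on
  small instances (tested).
* $\sigma \to 0$ collapses the marginal density onto the likelihood at
  $b = \mu$ exactly (the quadrature is bypassed).
* Draws where both group densities underflow to zero are skipped and
  counted per entry (`n_draws`).
* Degenerate priors (0 or 1) short-circuit Bayes' rule to their limit.
* Empty claim tables classify as control; empty cohorts generate empty
  objects; zero-denominator rates are reported as `NA`, never silent zeros.
* All randomness flows from explicit seeds: identical configurations give
  bit-identical cohorts, claims and posterior draws.

## Problem sizes used by the test suite

The bundled tests exercise the pipeline at sizes chosen to make Monte-Carlo
properties sharp while staying desk-scale: parameter recovery uses 20
replicate cohorts of n = 800 with 2 chains × 3000 iterations (thinning 1);
the convergence criterion (PSRF upper limit < 1.02 on every parameter) is
checked at the full inference protocol of 10 000 iterations; end-to-end
cross-validation checks run at n = 800 and n = 400 with 200 kept draws.
`scripts/acceptance.R` runs the complete analysis at the cohort's reference
size of 797.

## Known limitations

* The random-effects distribution is a single normal component per marker;
  misspecification (e.g. a true mixture) is not detectable within the model.
* The conditional approach is computed but, as in the source analysis, not
  used for model selection (it tracks the marginal approach closely).
* Classification updates are annual and frozen; individualized, event-driven
  updating schedules are out of scope.
* The deterministic definition's performance on synthetic cohorts depends on
  the claim-placement parameters (notably the JA code-category weights);
  these are fixed defaults chosen once for realism, not fitted quantities.
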