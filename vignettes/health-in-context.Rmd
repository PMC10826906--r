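---
title: "Screening prenatal substance exposure associations in environmental and genetic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening prenatal substance exposure associations in environmental and genetic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psecontext)
```

## The problem

Retrospectively reported prenatal substance exposure (PSE) — caffeine,
alcohol, tobacco and marijuana — co-occurs strongly with environmental and
genetic risk factors: mothers who used one substance tend to have used
others, and exposure propensity is tied to birth circumstances, family
socioeconomics, neighborhood conditions and familial psychiatric liability.
Any exposure–outcome association estimated without attention to this context
may simply re-describe the context. `psecontext` implements a four-stage
screening design for two-wave child cohorts (roughly ages 9–10 at baseline
and 11–12 at follow-up, clustered in families within ~22 study sites):

1. **Context association**: derive exposure variables and composite context
   risk scores; quantify exposure–context co-occurrence.
2. **Health association**: screen each exposure against an outcome battery
   with linear mixed models under FDR control, then refit jointly with all
   exposures and all four context scores; associations that survive are
   *robust*, those that do not are *confounded*.
3. **Developmental patterns**: among robust associations, compare baseline
   and follow-up effect sizes with a cluster-bootstrap confidence interval on
   their difference, labelling each association *persistent*, *transient*,
   *late-onset* or *unclassified*.
4. **Pathways**: longitudinal mediation of follow-up outcomes by baseline
   brain measures, and moderation of exposure effects by context scores, with
   bootstrap inference.

Every stage is exercised against a synthetic cohort generator with known
ground truth, so the package ships parameter-recovery and error-control
evidence rather than assumptions.

## Exposure derivation

A child is *exposed* when use was reported either before or after the mother
learned of the pregnancy; if both report fields are missing the exposure is
missing, otherwise unexposed. The three-level timing variable distinguishes
no exposure, exposure before knowledge only, and exposure after knowledge
(with or without earlier use). Caffeine is a single yes/no report: its
before/after split is typically not collected, so it has no timing variable.

Pregnancy-total consumption scales reported rates over a 40-week pregnancy
with knowledge assumed at gestational week 8 (instruments rarely record
timing; the week is a `threshold_set()` parameter). Units are cups
(caffeine), drinks (alcohol) and instances (tobacco, marijuana). Use
patterns cross light/heavier use — totals against cutoffs of 36 drinks
(alcohol) and 200 instances (tobacco), configurable because the literature
cutoffs they follow are instrument-dependent — with
reducing/stable/increasing use, where *stable* means the after-knowledge
total is within 10% of the before-knowledge total (also configurable; no
canonical band exists). The two axes collapse to five patterns for alcohol
and tobacco; caffeine uses reported frequency (daily/weekly/monthly) and
marijuana a single `any` level, since daily marijuana use is already heavy
use.

## Context scores

Each of the four contexts — birth, family, society, genetic — is a signed
sum of min–max-normalized components declared in the data dictionary: risky
components are added, protective components (e.g. prenatal vitamins, planned
pregnancy, breastfeeding duration, parental education, neighborhood safety,
educational-attainment polygenic score) are subtracted, so higher always
means riskier. Normalization bounds are computed on the analysis sample;
scores are therefore cohort-relative, which matches how such scores are
typically built and keeps them invariant to affine rescaling of any raw
component. A child missing any component has a missing score — no partial
sums — consistent with complete-case model fitting. Three-level yes/no/
unknown birth variables are encoded 1/0/0.5 before normalization; treating
"unknown" as the midpoint avoids discarding those children while not
committing to either answer. The educational-attainment polygenic score is
treated as protective (subtracted); the choice is a package decision where
conventions differ, and reversing it only flips the sign of that component's
contribution.

## The association model

Each exposure–outcome–wave cell is fit by REML as

```
z(outcome) ~ exposure + sex + race/ethnicity + z(age)
             [+ z(ICV)]                  # volumetric outcomes
             [+ z(motion) + z(quality)]  # functional-connectivity outcomes
             + (1 | site) + (1 | family within site)
```

The outcome and all continuous predictors are z-scored on the per-fit
complete-case sample; binary exposures stay 0/1, so the coefficient is a
standardized effect in outcome-SD units. P-values are large-sample Wald
tests; no small-sample df correction is applied by default because the
clusters number in the thousands. Site and family-within-site random
intercepts absorb the two dependence levels; if the full model fails to
converge the model falls back to a single family intercept, then to OLS with
family-cluster-robust (sandwich) standard errors, and the fallback used is
recorded in every result row.

FDR is controlled by Benjamini–Hochberg within each exposure ×
outcome-domain × wave family (domains: behavioral, mental, cognitive, brain
structure, brain function). The family boundary is a design choice — the
alternative global family would couple unrelated batteries — and it keeps
families the same size across exposures, so reduction percentages are
comparable.

In `context_adjusted` mode all four exposures enter one model per outcome
together with the four context scores. An association is **robust** when
FDR-significant in this adjusted screen, **confounded** when significant
only unadjusted; the per-exposure percent reduction in significant
associations summarizes how much of an exposure's apparent health signature
the context explains.

## Developmental patterns

For each robust association the package bootstraps
`beta_year2 - beta_baseline`: families are resampled with replacement within
site strata (the family is the strongest dependence unit and resampling it
keeps both waves of each child paired; sites are design strata, not
exchangeable units), both wave models are re-estimated per replicate, and
the 95% percentile interval is taken. Point estimates come from the REML
fits; inside replicates the coefficient is recomputed by least squares on
the resampled design. Cluster resampling already carries the dependence and
the fixed-effect estimator is unbiased under the random-intercept model, so
this choice trades a negligible efficiency difference for the ability to run
10,000 replicates in seconds. The percentile interval (rather than BCa) is
used because nothing beyond a bootstrap percentile CI is required of it.

Labels follow the rule table: significant at both waves → *persistent*
(no CI condition is imposed); significant only at baseline **and** CI
excluding zero in the attenuating direction (relative to the baseline effect
sign) → *transient*; significant only at follow-up **and** CI excluding
zero in the growing direction → *late-onset*; otherwise *unclassified*.
The CI conditions implement "significantly reduced/increased" literally and
are sign-symmetric, so protective (negative) associations classify the same
way as risk associations.

Dose–response models use `log1p` of the pregnancy-total consumption
(z-scored, unexposed children at 0): totals are strongly right-skewed by
construction, and the log1p transform keeps zeros meaningful. The raw-scale
alternative is available by supplying a pre-transformed column.

## Pathways

Mediation uses one randomly selected child per family (removing the sibling
dependence), baseline mediator and covariates, year-2 outcome, and site as
fixed dummies: `a` from the mediator regression, `b` and `c'` from the
outcome regression, indirect effect `a*b` with a percentile bootstrap over
children. For nested linear models on one sample, total = indirect + direct
is an exact identity, checked to 1e-8 in the tests. The mediated proportion
`100*indirect/total` is reported as-is, including negative values
(suppression).

Moderation fits the standard mixed model with an exposure × moderator
interaction (moderator at baseline, z-scored). Alongside the Wald and
family-bootstrap p-values for the interaction, the package reports an
attenuation index

```
vr2 = 1 - (slope_favorable / slope_reference)^2
```

where `slope_reference` is the conditional exposure effect at the moderator
mean and `slope_favorable` the effect one SD toward the direction that
weakens the association, clipped to [0, 1]. **This index is a
reconstruction**: attenuation indices of this kind are reported in the
moderation literature without a settled definition, and this one reads as
the proportion of the squared exposure effect removed by a favorable context
(a reference slope of 0.10 attenuated to 0.073 gives vr2 of about 0.47). It
should be reported with that caveat, and is undefined (NA) when the
reference slope is zero.

## The synthetic cohort generator

`generator_spec()` encodes the study conditions: 9,838 children by default,
22 sites, sibling fraction 0.19 (families of at most two children — higher
sibships are rare enough at this scale to omit by default), marginal
exposure prevalences 59.8/25.7/13.2/5.6% for caffeine/alcohol/tobacco/
marijuana, and outcome variance components site 0.02, family 0.20, residual
0.78. The components sum to 1 so the standardized coefficient estimated by
the mixed model targets the generator's `beta` directly; the family share of
0.20 is typical of sibling designs for behavioral outcomes.

Exposures are drawn from a Gaussian copula — a latent 4-variate normal
thresholded at prevalence-matching quantiles — because it matches marginal
prevalences and pairwise co-occurrence with six interpretable parameters.
The default latent correlations (strongest 0.45 for tobacco–marijuana) are
free parameters chosen to mimic strong co-occurrence; the source cohort's
full matrix is not published. Confounding adds a latent-context term to an
exposure's latent variable *and* to every outcome; thresholds account for
the inflated latent variance, so marginal prevalences are preserved exactly
under confounding (tested). Context-score components are noisy affine
transforms of the latent contexts (noise SD 0.2), making built scores sharp
proxies — adjustment in the fitted models can therefore actually remove the
planted confounding. Exposed mothers always report use before knowledge;
continuation after knowledge is Bernoulli with substance-specific
probability (alcohol 0.2, tobacco 0.5, marijuana 0.4), echoing the
pre/post-knowledge drop that is most pronounced for alcohol.

What the generator does **not** emulate: correlation among outcomes beyond
shared exposure/context/cluster effects (outcomes are conditionally
independent), more than two waves, higher-order sibships, attrition and
informative missingness, and real instrument distributions (outcomes are
Gaussian). Passing tests therefore demonstrate estimator correctness under
the stated dependence and confounding structure, not robustness to every
property of real cohort data.

`scenario_library()` fixes the ground truths used across the test suite:
`null`, `confounded` (family context → alcohol logit 0.5 and → outcomes 0.3,
implying a spurious standardized effect near 0.2–0.3, detectable at the test
sizes and removable by adjustment), `persistent` (β = 0.05 at both waves),
`transient` (0.08 → 0), `late_onset` (0 → 0.08), `mediated` (a = 0.5,
b = 0.4, c' = 0.3 with residual variances set so mediator and outcome have
unit variance, hence indirect 0.20 and mediated proportion 40%),
`moderated` (main effect 0.10, family-context interaction 0.04) and
`dose_response` (slope 0.05 on the z-scored log1p total).

## Numerical and testing choices

* All randomness flows from one master seed through `child_seed()`, a string
  hash that spawns per-stage seeds below 2^31; identical (config, seed)
  reproduce byte-identical cohorts, manifests and reports.
* Outcomes sharing a complete-case sample and covariate set within a screen
  reuse one fitted mixed model via response refitting, which is exact and
  makes 50-outcome batteries cheap.
* Degenerate inputs fail loudly with typed conditions: constant outcomes or
  predictors and under-clustered designs are design errors; constant vectors
  are min–max-normalization domain errors; misaligned robustness inputs are
  contract errors. Battery screening converts per-cell failures into NA rows
  rather than aborting.
* The test suite runs the published-scale checks where the cost is one model
  fit per replicate (parameter recovery: 100 replicates at n = 9,838; FDR
  control: 50 replicates of 50 outcomes at n = 2,000, as stated) and
  documented reduced scales elsewhere: confounding detection at n = 4,000
  (effect sizes unchanged; the implied spurious effect is detected with
  overwhelming power already at this size), bootstrap-delta checks with
  300–1,000 replicates instead of 10,000, and mediation coverage with 50
  replicates of 500 bootstrap draws at n = 4,000.

## Limitations

Outcomes are modelled as continuous throughout (no binomial/ordinal mixed
models); diagnostic instruments are out of scope. The pipeline consumes
precomputed brain metrics and polygenic scores as columns — no imaging or
genotype processing. Exposure timing finer than the before/after-knowledge
split (e.g. trimester) is not modelled because the emulated instruments do
not collect it. The `vr2` attenuation index is a documented reconstruction,
and the heavier-use cutoffs are placeholders to be replaced per study.
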