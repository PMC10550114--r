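---
title: "Emulating target trials from veterinary EHR cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating target trials from veterinary EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetemulate)
```

## The scientific problem

Most dogs presenting to primary-care practice with acute diarrhoea recover
within days, yet a large fraction receive antimicrobials at first
presentation. Because prescribing is not randomised — sicker-looking dogs
(pyrexia, haematochezia, concurrent vomiting) are more likely to be
treated — a naive comparison of outcomes between treated and untreated dogs
confounds treatment effect with baseline severity. Target trial emulation
addresses this by specifying the randomised trial one would ideally run
(eligibility, treatment strategies, follow-up, estimands) and then
analysing the observational cohort to mimic that protocol, using inverse
probability of treatment weighting (IPTW) to stand in for randomisation.

`vetemulate` implements the full emulation pipeline for a canine
acute-diarrhoea cohort with two exposures of interest — antimicrobial
prescription and gastrointestinal nutraceutical prescription — and two
outcomes: 30-day clinical resolution (binary; no revisit with ongoing
diarrhoea) and time to treatment escalation (days 0–30, administratively
censored at 30). Because individual-level veterinary EHR data of this kind
are not publicly deposited, the package ships a synthetic cohort generator
with known counterfactual truth; every estimator is validated against that
truth and against independent oracles.

## Eligibility and the emulated protocol

`apply_eligibility()` retains dogs aged at least 3 months (encoded 0.25
years, inclusive) and under 10 years (exclusive), first diagnosed in the
study year, with no diarrhoea history or antimicrobial/nutraceutical
prescription in the preceding 30 days, none of the excluding diagnoses, at
most 7 days of diarrhoea before presentation (7.0 days is retained; only
"greater than 7 days" excludes), and no intravenous fluids,
hospitalisation or death at first presentation. Exclusion reasons are
tallied with a fixed precedence (age, prior diarrhoea, prior exposure,
excluded diagnosis, duration, IV fluids, hospitalisation, death) so that a
record failing several rules is counted once and tallies are
deterministic; the protocol itself does not order its exclusion list, so
the precedence is a reporting convention, not a scientific claim.

## Propensity model and stabilised weights

For each trial the exposure is regressed on the adjustment set with
maximum-likelihood logistic regression. The default model mirrors the
final assignment models of the emulated trials: all baseline covariates
and concurrent treatments, a quadratic age term, and trial-specific
interactions (antimicrobial trial: age×vomiting, haematochezia×pyrexia,
nutraceutical×dietary-advice; nutraceutical trial: age×haematochezia).
Design encoding uses reference coding with the most frequent level as
reference (the source analysis does not state its coding), and the
"not recorded" levels of bodyweight and duration enter as their own
indicator columns — the missing-indicator method, which assumes a
covariate confounds only when observed. Levels with no records are dropped
from the design with a warning rather than producing a degenerate column.

Weights are stabilised: `sw = p_A / e` for exposed and
`(1 - p_A) / (1 - e)` for unexposed dogs, where `e` is the fitted
propensity and `p_A` the crude exposure prevalence (exactly the
intercept-only model's fitted probability). Stabilisation keeps the
pseudo-population near the sample size (`mean(sw)` ≈ 1) and damps extreme
weights; no truncation is applied by default because the emulated design
relied on stabilisation alone. Records with `sw` outside [0.1, 10] are
listed in the weight object for inspection.

Interaction selection follows the emulated design's stated rule —
"included if they improved covariate balance" — which is not a complete
algorithm. We operationalise it as a greedy forward pass over
user-supplied, biologically plausible candidate pairs in their given
order, retaining a candidate if and only if it strictly reduces the
maximum post-weighting standardised mean difference over the adjustment
covariates. Both the ordering and the max-SMD summary are design choices;
the decision log records every candidate's effect so an analyst can audit
or re-order the pass. Instead of visual linearity-to-logit inspection we
expose the fitted model's coefficient table and convergence diagnostics.

## Balance diagnostics

`smd()` computes |m1 − m0| / sqrt((v1 + v0)/2). For binary covariates the
arm variance is p(1 − p); for continuous covariates the weighted variance
uses the frequency-weight convention Σw(x − x̄_w)²/Σw (weighted-SMD
conventions differ between software packages, so this is stated
explicitly). Multi-level categoricals are expanded to level indicators and
summarised per covariate by the maximum over levels, a conservative
choice. A level absent from one arm is flagged degenerate rather than
dropped — it is exactly the positivity warning an analyst needs to see.
The balance threshold is the conventional SMD < 0.1. Effective sample
sizes (Σw)²/Σw² per arm quantify the variance cost of weighting.

## Risk difference with robust variance

The unadjusted estimator reproduces the descriptive-table convention: arm
risks as percentages rounded to one decimal, and the risk difference as
the difference of the rounded risks. The causal estimator fits an
sw-weighted logistic regression of resolution on exposure alone; since
that model is saturated in the exposure, the standardised risks "as if all
dogs treated / untreated" are algebraically the sw-weighted arm means. The
standard error comes from the robust (sandwich, HC0) covariance of the
weighted fit — computed via the `sandwich` package and verified in the
tests against the explicit A⁻¹BA⁻¹ form — propagated to the risk scale by
the delta method, with a 1.96 normal quantile for the 95% interval.
Weights are treated as known, ignoring propensity-estimation uncertainty;
for the risk difference this is typically conservative. The time-to-event
stage's dog-level bootstrap (which does re-estimate weights per replicate)
shows the alternative treatment of that uncertainty.

## Discrete-time survival analysis

Escalation is analysed on a daily grid with the interval convention
"event on day t ⇔ revisit in (t−1, t]"; same-day (day-0) revisits are
assigned to day 1, and dogs never escalating are administratively censored
at day 30. Unadjusted curves and the log-rank test wrap the `survival`
package. The causal analysis expands the cohort to person-day records and
fits an sw-weighted pooled logistic hazard model; standardised event-free
curves are S_a(t) = Π_{u≤t}(1 − ĥ_a(u)) with exposure fixed at a. The
default time form is linear + quadratic in day with exposure×time
interaction — smooth enough for a 30-day horizon with a front-loaded
hazard — while the saturated per-day-indicator model is retained as an
option and as the test oracle: its weighted maximum-likelihood hazards
have the closed form (weighted events)/(weighted at-risk), and with unit
weights its survival curves coincide with Kaplan–Meier, which the tests
assert to 1e−6. A weighted Cox model is deliberately out of scope; the
pooled logistic formulation matches the hazards-model framing of the
emulated analysis and makes standardisation explicit.

Confidence intervals are percentile bootstrap over dogs (default 500
replicates), re-deriving the propensity weights within each replicate so
that weight-estimation uncertainty propagates. Replicates whose resample
loses an arm are discarded and counted, with a warning above 10% discards.
Percentile bounds are widened, if necessary, to contain the point
estimate, keeping the reported bands internally consistent. Bootstrap
results are deterministic given the seed.

## Equivalence design

The sample-size calculation for two proportions on the risk-difference
scale uses n = (z₁₋α + z_power)² [p1(1−p1)/k + p2(1−p2)] / margin², with
ceiling rounding, followed by division by (1 − dropout) and a second
ceiling. The single z_power term (rather than a TOST-specific
z-correction) is the convention of the online calculator the emulated
design cites; with p1 = p2 = 0.95, margin 0.1, one-sided α = 0.05, 80%
power and 25% dropout it reproduces the published 79 dogs per arm
(59 before dropout inflation). `simulate_power()` provides the honest
Monte-Carlo check: it simulates binomial arms and declares equivalence
when the Wald (1 − 2α) interval for the risk difference lies within
±margin (the two-one-sided-tests procedure). At the recruited 79 per arm,
analysed in full, the TOST power is close to the 80% target; at the
un-inflated 59 it is substantially lower, because the single-z formula
approximates each one-sided test separately rather than their
conjunction. Both numbers are computed, not asserted, in
`analysis/01_design_power.R` and the tests.

## The synthetic cohort generator

`default_study_config()` encodes the study conditions: 894 dogs,
antimicrobial prevalence 39.7%, nutraceutical prevalence 66.8%, covariate
category frequencies matched to the published descriptive tables
(including 20.4% "not recorded" bodyweight and 17.7% duration, applied
completely at random, matching the missing-indicator method's
assumption), overall 30-day resolution 0.88, and 30-day escalation 0.11
with a hazard declining ~e^−0.3 per day so that escalations concentrate
in the first few days, as observed. Age is Beta(1.1, 2.2) scaled to
[0.25, 10), giving a right-skewed distribution with median near 3 years.

The generative graph follows the study's causal diagram: covariates drive
both exposures and both outcomes; the nutraceutical decision precedes and
influences the antimicrobial decision (they are negatively associated, as
in the data); concurrent treatments enter the assignment models.
Assignment coefficient directions are informed by the published
between-arm contrasts (e.g. haematochezia and pyrexia strongly increase
antimicrobial prescribing, dietary advice and nutraceutical use decrease
it), with magnitudes bounded so every true assignment probability stays
inside (0.05, 0.95) — positivity holds by construction. Covariate effects
on the outcomes are not reported by any source, so they are plausibility
choices made once: severity markers carry large resolution penalties
(e.g. a pyrexic dog's resolution odds are roughly one fifth of an
afebrile dog's), which produces marked confounding — crude risk
differences of several percentage points under a true null — giving the
weighting stage something real to remove.

Calibration uses root-finding against a large internal reference draw
(20,000 dogs by default): intercepts are solved so the marginal exposure,
resolution and escalation probabilities hit their targets, and the
exposure effect on resolution is solved as a log-odds offset so the
marginal E[Y(1)] − E[Y(0)] equals the configured `true_rd` (tolerance
0.002; an unattainable `true_rd` raises a configuration error). Both
potential outcomes share one uniform draw per dog and both potential
escalation paths share one uniform per dog-day (common random numbers),
so consistency — the observed outcome equals the assigned arm's potential
outcome — holds exactly by construction, and the default null has
y1 ≡ y0. Draws follow a fixed substream order (covariates, exposures,
outcomes, hazards, missingness) with per-block seeds derived from the
root seed; output is byte-identical for identical configurations.

What the generator does not emulate: free-text records and case-finding,
breed-specific prescribing patterns beyond category frequencies,
informative missingness, multi-visit structure, or same-day revisits
(event support starts at day 1). Passing tests therefore demonstrate that
the estimators recover known truth under the modelled confounding
structure — not that any particular real-world cohort satisfies the
identifying assumptions (consistency, no interference, positivity, no
unmeasured confounding).

## Problem sizes and numerical choices

The validation suite balances fidelity against runtime: the
operating-characteristics check runs 500 cohorts of 900 dogs (coverage of
the null, post-weighting balance, weight calibration); bias-dominance of
the crude estimator is checked on cohorts of 4,000 where confounding bias
clearly exceeds sampling noise; the null time-to-event check uses 2,000
dogs with 200 bootstrap replicates; TOST power uses 5,000 Monte-Carlo
replicates. Oracle equivalences (exact standardisation, Kaplan–Meier) are
asserted at 1e−8 and 1e−6. Logistic fits use `stats::glm` with the
quasibinomial family where weights are non-integral; separation is
flagged (fitted probabilities at machine bounds or runaway coefficients)
rather than silently accepted.

## Known limitations

- The sandwich interval treats weights as known; coverage is expected
  slightly above nominal under strong confounding.
- The greedy interaction pass is order-dependent by design and only one
  reading of "improved covariate balance".
- The generator's outcome-side effect sizes are stipulations, not
  estimates; conclusions about estimator behaviour are conditional on
  that generative model.
- Competing risks, recurrent escalations and weighted Cox estimation are
  out of scope.
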