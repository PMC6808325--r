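---
title: "Methods: a Markov cost-utility model of dialysis provision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-utility model of dialysis provision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialcea)
library(dplyr)
```

## The decision problem

End-stage renal disease patients in the Malaysian Ministry of Health
programme receive either in-centre hemodialysis (HD) or continuous
ambulatory peritoneal dialysis (CAPD). The two modalities differ in annual
per-patient cost (RM 39,791 vs RM 37,576 in 2017 Ringgit), in health
utility (EQ-5D-3L index 0.854 vs 0.905), and in survival (registry-based
restricted mean life years over the study horizon: 4.15 vs 3.70). The
policy question is not "which modality for this patient" but "what mix of
incident HD and CAPD patients should the programme steer towards":
the observed 60:40 HD:CAPD mix is compared with 55:45, 50:50 and 70:30
alternatives.

`dialcea` implements the full analysis chain: survival and event-rate
estimation from registry-style records, a three-state Markov cohort
model, incremental cost-effectiveness with dominance analysis, one-way
(tornado) and probabilistic sensitivity analysis, and a synthetic
registry generator that makes every stage testable without access to the
original registry extract.

## Model structure and assumptions

The cohort model has three states — HD, CAPD, Death — with bidirectional
switching between the alive states and Death absorbing. It runs for five
1-year cycles; one transition per cycle. The Markov assumption applies:
transition probabilities depend only on the current state, not on
history, and patient characteristics other than state are held fixed.
Kidney transplantation is not a state (deceased-donor transplantation is
rare in this population) and no age or case-mix stratification is
attempted.

Annual transition rates $r$ (events per patient-year) become per-cycle
probabilities through the constant-hazard conversion
$p = 1 - e^{-rt}$ with $t$ the cycle length in years. Each exit
probability is converted independently and the stay probability is one
minus their sum. This is deliberate: it mirrors the published
calculation, and for the small rates involved (0.007–0.134/year) the
difference from an exact multinomial conversion of a competing-risk rate
matrix is negligible. The matrix builder refuses inputs whose converted
exit probabilities reach 1.

```{r tpm}
params <- default_parameters()
round(build_transition_matrix(params), 6)
```

### Half-cycle correction and discounting

Transitions are assumed to occur, on average, halfway through a cycle.
We implement this as trapezoidal weighting: cycle $k$ contributes the
average of its start- and end-of-cycle occupancy, which is equivalent to
weighting the cycle-boundary occupancies by $(\tfrac12, 1, \dots, 1,
\tfrac12)$. Costs accrue with the same weighting as life years and
QALYs — the dead accrue nothing, and a cohort that dies entirely in its
first cycle accrues exactly half a year.

Discounting uses 3% per year. The published description does not fix the
discount point within a cycle, so the convention is explicit and
switchable: `discount_timing = "end"` (default) divides cycle-$k$
contributions by $(1+d)^k$; `"half"` uses $(1+d)^{k-1/2}$, aligning the
discount point with the half-cycle assumption. The difference is a
uniform factor of about $(1.03)^{1/2}$ on discounted totals and does not
change any ranking.

Scenario results are mixtures of the two pure-start cohorts, because the
occupancy recursion, the trapezoid and discounting are all linear in the
initial vector; `weighted_strategy_result()` exploits this and
`run_scenarios()` therefore runs the engine only twice regardless of the
number of scenarios.

## Survival estimation

Life years come from the Kaplan-Meier product-limit estimator (delegated
to the `survival` package) under intention-to-treat attribution: a
patient keeps their first modality for the whole of follow-up, and a
death after a modality switch still counts against the first modality.
Transplantation, recovery of renal function, loss to follow-up and the
administrative end of follow-up censor. Ties are resolved events-first.
Life years are the area under the survivor step function up to the
horizon (`restricted_mean_survival()`), computed in months internally
and reported in years.

Annual event rates use the registry census convention: events in a
calendar year divided by the mid-year population at risk, averaged over
years with equal weight. "Mid-year population" is the head count on 1
July by default. The obvious alternative — the average of the 1 January
and 31 December counts — is available
(`midyear = "boundary_average"`) but overstates rates by up to ~2% in a
pool that shrinks within the year, so the midpoint count is the default.
Death rates can be attributed to the modality occupied at death
(`attribution = "current"`, the convention for per-modality annual death
rates) or to the first modality (`"first"`, the ITT convention); both
are supported because the published rate table does not say which was
used.

## Cost-utility accounting

QALYs are life years times the utility index. Cost per life year of a
modality is its mean annual treatment cost — sustaining one year of life
on dialysis costs one year of treatment — and cost per QALY is
`annual_cost * LY / QALY`. Reported values follow the printed rounding
convention: life years to 2 decimals, QALYs to 3, Ringgit to whole
units, with the rounded values feeding downstream divisions so that the
published figures are reproduced exactly.

```{r table4}
modality_summary(params)
```

One numerical subtlety: `3.70 * 0.905 = 3.3485` is an exact decimal tie,
and its double representation sits fractionally above it, so naive
`round()` returns 3.349 where the published table has 3.348.
`report_round()` snaps to 12 significant decimal digits before rounding
half-to-even, restoring decimal behaviour.

`icer_ladder()` sorts strategies by effectiveness, flags strict
dominance (more costly, no more effective), removes extended dominance
(a strategy whose incremental ratio exceeds that of the next step up the
frontier, so a mixture of its neighbours is more efficient), and
computes ICERs between surviving neighbours. Extended dominance goes
beyond the published analysis, which only needed strict dominance; a
`strict_only` mode reproduces that behaviour. ICERs are classified
against GDP-based willingness-to-pay thresholds: below RM 40,000 (1x GDP
per capita) very cost-effective, below RM 120,000 (3x GDP)
cost-effective. Dominated strategies get a dominance flag, not an ICER.

### Why the published scenario table is not a target

The published 5-year scenario table reports base-case undiscounted total
life years of 8.005 — impossible for a per-patient expectation bounded
by the 5-year horizon — and discounted values inconsistent with 3%
discounting of the undiscounted ones. The aggregation the original
modelling software applied is not documented and cannot be recovered
from the description. Moreover, with CAPD both cheaper *and* higher
utility while the life-year gap is small, a faithful per-patient model
makes the CAPD-heavier 50:50 mix dominate the 60:40 base case outright,
whereas the published table shows HD-heavier scenarios with more QALYs.
We therefore hold the cohort engine to properties rather than to that
table: exact agreement (1e-10) with an independently coded matrix-power
oracle on random instances, occupancy conservation, monotone death
occupancy, the per-patient horizon bound, and the equivalence between
the sign of net monetary benefit and the ICER-threshold comparison.

## Sensitivity analysis

### One-way (tornado)

Every input — 16 cost components, 2 utilities, 4 transition rates — is
set in turn to its low and high range bound with all else at the mean,
and both compared strategies are rerun. The bar is the incremental net
monetary benefit, $\mathrm{NMB} = \Delta Q \cdot \lambda - \Delta C$, of
the 50:50 strategy against the 60:40 base case at
$\lambda = \mathrm{RM}\,120{,}000$ per QALY (incremental NMB, because
NMB is defined incrementally; the comparison pair and direction are
arguments). Utilities and hospitalization and outpatient costs produce
the widest bars.

Because the two strategies differ only in their initial mix, the
incremental NMB's *sign* is sensitive at utility extremes (at
`uHD = 1.0` the HD-heavy mix gains more QALYs and the bar crosses
zero). The robust finding is at the strategy level: at every endpoint,
every compared strategy's own cost per QALY stays below RM 120,000 —
each tornado entry carries the worst such classification
(`worst_class`), and the acceptance checks assert it.

### Probabilistic (PSA and CEAC)

Second-order Monte Carlo with 1,000 iterations by default. Costs draw
from gamma distributions, utilities and annual rates from betas, fitted
by the method of moments to the printed mean and range, reading the
range as a central 95% interval: $\sigma = (\mathrm{high} -
\mathrm{low})/3.92$ (an $(\mathrm{high}-\mathrm{low})/4$ convention is
available). The fitted mean equals the input mean by construction; a
zero-width range gives a degenerate point mass, so a fully degenerate
configuration makes every PSA iteration reproduce the deterministic run
— a useful machinery check. The zero lower bound on hospitalization
costs poses no problem: the gamma needs only a positive mean.

Draws are independent across parameters (no published correlation
structure) and shared across scenarios within an iteration (common
random numbers), so scenario contrasts are not masked by sampling noise.
Iterations whose drawn rates would push a state's exit probabilities to
1 are redrawn and counted; with the published ranges this essentially
never happens. The CEAC reports, on a RM 0–200,000 grid in RM 5,000
steps, the probability that each scenario attains the maximum
$\mathrm{NMB}(\lambda) = Q\lambda - C$; exact ties split equally.
Discounted and undiscounted variants are both available, mirroring the
two published diagrams.

## The synthetic registry

`generate_registry()` emulates the structure of the registry extract the
survival stage consumes: uniform enrolment over 2011–2015,
administrative censoring at the end of 2016, and competing exponential
clocks for death, modality switch, transplant, recovery and loss to
follow-up, with clocks restarting on switch. Constant hazards are the
minimal model consistent with using single annual rates. Defaults are
the published annual rates (death 0.125/0.134; switch HD to CAPD 0.007,
CAPD to HD 0.067). The censoring hazards have no published values; they
are set once to small rates a nephrologist would recognise for this
population — transplant 0.005/year (deceased-donor transplantation is
rare in Malaysia), recovery 0.002, loss to follow-up 0.01 — and are not
tuned.

What passing recovery tests show: that the estimators are consistent
with their own assumptions (constant hazards, independent censoring,
memoryless switching) at realistic sample sizes. What they cannot show:
robustness to real-registry features the generator omits — time-varying
hazards (early CAPD technique failure, vintage effects), informative
censoring, case-mix differences between modalities, or reporting delay.
Problem sizes used in the tests — cohorts of 5,000 over 20 seeds for
rate recovery, 5,000 for the closed-form life-year comparison, 1,000 PSA
iterations — were chosen to keep Monte-Carlo error well inside the
stated tolerances (3 Monte-Carlo standard errors for rates; 2% for
restricted mean survival against the exponential closed form).

## Degenerate inputs and numerical choices

* Row-stochasticity is enforced to 1e-12; exit-probability sums of 1 or
  more are errors naming the state.
* An all-censored record set yields a flat survivor curve with a
  warning, not an error; extending a restricted-mean horizon past the
  last observed time holds the curve at its final value and warns
  (silently, if that value is already 0).
* The printed CAPD component costs sum to RM 37,576.04 against a printed
  total of RM 37,576.03; totals are validated to 0.5 RM, the slack
  implied by rounding components to whole sen. PSA rebuilds totals from
  drawn components, so the component sum — not the printed total — is
  the operative quantity wherever both exist.
* Cost and effect ties in the ICER ladder are flagged `equivalent` and
  excluded from ICER computation; the ladder output is invariant to
  input order (sorting is stabilised by effect, cost, then label).

## Known limitations

The model inherits the published design: no transplant state, no
covariate adjustment (the survival contrast between modalities is
confounded by selection), homogeneous cohort, constant per-cycle rates
over the 5-year horizon, and costs entering as fixed annual totals
rather than patient-level trajectories. The dominance verdict between
provision mixes rests on the small utility difference between
modalities; the tornado shows it flips within the plausible utility
ranges, so the scenario ranking should be read as fragile even though
every strategy remains cost-effective against the RM 120,000 threshold
throughout.
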