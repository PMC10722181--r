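---
title: "Methods: cost-of-illness modelling for heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-of-illness modelling for heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcoi)
```

`hfcoi` implements a societal-perspective cost-of-illness (COI) analysis for
heart failure with three estimation arms: prevalence-based annual costing of
a patient cohort, an incidence-based lifetime projection with a six-state
Markov cohort model, and a two-part regression relating annual cost to
clinical and demographic covariates. A seeded synthetic-cohort generator
makes every arm testable end to end without patient-level data. This
vignette explains the models, the assumptions behind them, the parameters
that matter, and the numerical choices the implementation makes.

## 1. Prevalence-based annual costing

### Person-month annualisation

Each patient is observed for 2, 4 or 6 months. Observed monthly costs are
averaged over the observed months (the person-month measure) and multiplied
by 12 to give an annual figure. The one exception is inpatient cost: the
hospital admission question covers the whole previous year, so the admission
cost enters the annual treatment component **once**, never times 12, and is
invariant to the follow-up duration. `annualize_direct()` implements exactly
this arithmetic and nothing else, so a patient's annual components are exact
functions of their record.

Direct costs split into four components: medicine, treatment (non-hospital
care plus admissions), diagnostics, and direct non-medical spending.

### Human-capital indirect costs

Indirect costs follow the human-capital approach: lost production is valued
at gross wages. `human_capital_indirect()` computes five components
per patient per year:

| Component | Formula | Applies to |
|---|---|---|
| Absenteeism | days/month x daily wage x 12 | employed only |
| Presenteeism | days/month x (1 - residual efficiency) x daily wage x 12 | employed only |
| Unpaid work | hours/month x shadow wage x 12 | everyone |
| Job change | monthly wage differential x 12 | patients who changed jobs |
| Premature death | PV of annual wages from death to retirement | deceased |

Unpaid work (housework, care-giving, voluntary activity) is valued for every
patient at a replacement (shadow) hourly wage, because non-market production
has value regardless of employment status; in populations dominated by
housewives and retirees it is typically the dominant indirect component.

The premature-death component is the present value of a year's wages over
`max(0, retirement_age - age_at_death)` years with a year-end discounting
convention (`present_value_annuity()`): the default discount rate is 0 — so
the default reproduces a plain summation — with 3% or 5% a configuration
change. Fractional final years contribute proportionally.

Wage parameters live in `wage_config()`: monthly wage (default 10,000,000
Toman, a plausible 2022 gross market wage), 22 working days per month,
unpaid-work shadow wage 50,000 Toman/hour, retirement at 65. The
job-change differential defaults to 0, reflecting measurement of this
component as nil in the motivating cohort.

### Aggregation and shares

`aggregate_breakdown()` reports per-component means and sample SDs (n-1
denominator), totals of means computed before any rounding, and three share
tables: direct vs indirect of the grand total, medicine/treatment/diagnostic
of direct medical cost, and per-NYHA-class means as shares of the class-mean
sum. Shares are kept raw and also rounded **half-up** to integers
(`round_half_up()`), the convention of published cost tables — base R's
round-half-to-even would report 20.5% as 20%. A single-patient cohort has no
sample SD; it is reported as 0 with an explicit degenerate-sample flag and
warning rather than as `NA`, so report layouts never break.

Per-patient additivity is exact, not approximate: `grand_total` is computed
as `direct_total + indirect_total` on the same doubles, so the identity
holds bitwise, and tests assert it with `expect_identical()`.

Toman amounts convert to purchasing-power-parity dollars by division;
the default factor of 11,900 Toman per international dollar is recovered
from the three published Toman/PPP pairs (total, direct, indirect annual
cost), whose implied ratios agree to within about one part in a million
(`hf_reference_ppp_factor()`).

### The published reference table

`hf_reference_costs()` ships the published per-component annual means/SDs of
a 502-patient Iranian heart-failure cohort, and `reference_breakdown()` runs
the package's own aggregation arithmetic over them as a frozen input set.
The source table's printed direct-medical subtotal exceeds the sum of its
three printed components by about 42,610 Toman (an internal rounding
inconsistency of the source); this package always reports component sums and
documents the discrepancy instead of reproducing it.

## 2. Incidence-based lifetime costs: the Markov cohort model

The model has six states: NYHA classes I-IV, death from heart failure
(DeathHF) and death from other causes (DeathOther). Both death states are
absorbing. The cohort occupancy row vector evolves as
$\pi_{t+1} = \pi_t P$ over 25 one-year cycles (configurable), and cycle $t$
accrues, discounted by $(1+r)^{-t}$:

$$c_t \;=\; \sum_{s \in \text{NYHA1..4}} \pi_t[s]\, C_s \;+\;
  \big(\pi_{t+1}[\mathrm{DeathHF}] - \pi_t[\mathrm{DeathHF}]\big)\, C_D ,$$

where $C_s$ is the annual cost of alive state $s$ and $C_D$ a **one-time
entry cost** charged to the mass newly absorbed into DeathHF. Costing death
from heart failure as a one-time entry cost — interpreted as the present
value of earnings lost at death — is the only reading under which a death
state can carry a large share of lifetime cost, and it is how the package
attributes cost to DeathHF. DeathOther accrues nothing. Cost accrual runs at
cycles $t = 0..T-1$ with occupancy evaluated at cycle starts.

Numerical and design choices:

* **Discounting** defaults to 0 (so per-state costs simply add), with any
  rate in $[0,1)$ configurable. Increasing the rate can never increase the
  total, and increasing any cost can never decrease it (tested properties).
* **Half-cycle correction** is off by default; when on, occupancy costs and
  life-years use the average of adjacent cycle-start occupancies. The entry
  cost is untouched, as the entry mass is already an increment over the
  cycle.
* **Validation** (`validate_markov_spec()`) enumerates *all* violations —
  row sums off unity beyond 1e-9, non-absorbing death rows, initial mass on
  death states, negative costs — rather than stopping at the first, because
  transition matrices arrive from hand-edited config files.
* **Attribution completeness**: the five per-state accumulators sum to the
  lifetime total at machine precision by construction.

`life_years()` accumulates alive-state occupancy mass; the DeathHF occupancy
at the horizon is reported as the model's HF-death probability.

### Cross-validation by microsimulation

`microsimulate_markov()` samples individual state trajectories from the same
transition matrix and accrues exactly the same costs per path. It shares no
code with the matrix recursion, so the two validate each other: the suite
checks agreement within three Monte-Carlo standard errors on random
specifications, and against closed forms (absorbing self-loop gives
$T \cdot c$; geometric survival gives
$\sum_{t=0}^{T-1}(1-q)^t$ life-years) at 1e-9.

### Transition probabilities

The transition probabilities used in the motivating study come from
treatment-effectiveness literature and are not published; they are therefore
**config-supplied**, never hard-coded. `default_markov_spec()` ships a
clearly synthetic placeholder matrix (progression-dominated, with
class-increasing HF mortality) so the model runs out of the box, the
published class mix 106/189/88/119 over 502 as the initial distribution, and
the published per-class annual cost means as state costs.
`calibrate_transition_matrix()` is a convenience least-squares search — a
Nelder-Mead fit of next-class-progression and HF-death probabilities (with
fixed background mortality) to target per-state attributed costs — useful
for constructing scenario matrices; it is not a substantive estimation
method. The published per-state lifetime costs are non-monotone in class
(class II's lifetime cost is far below class I's), which cannot be
disentangled into occupancy vs cost effects without the unpublished
probabilities; the package does not guess.

## 3. Two-part regression

Annual cost is semicontinuous: a point mass at zero and a skewed positive
part. The two-part model handles this with

1. a **probit** for $P(\text{cost} > 0)$ on all patients, and
2. a **log-link GLM** for the level of cost among patients with positive
   cost — gamma by default, the standard family for positive right-skewed
   expenditure (a log-scale intercept near 19.6 corresponds to annual costs
   in hundreds of millions of Toman).

The expected cost for covariates $x$ is the product
$\Phi(x\beta_1)\cdot\exp(x\beta_2)$ (`predict_expected_cost()`), and the
cohort-mean prediction is reported next to the observed mean — the
predicted-vs-observed ratio is the headline adequacy check.

Covariates are age (linear), a gender indicator, basic insurance,
comorbidity, and NYHA class entered as a single linear 1-4 term (dummy
coding of class is deliberately not the default: one linear term matches the
single-row reporting convention of published tables). Whether the gender
indicator means female or male is a pure convention that published tables
often leave unstated; it is explicit here (`gender_coding`, default
female = 1) and flipping it only flips the sign of that coefficient.

Estimation details:

* The probit is fitted by IRLS and then polished with Newton steps on the
  exact log-likelihood until the score norm is below 1e-8; non-convergence
  is warned about, never silent. Standard errors come from the **observed
  information**, computed analytically
  ($w_i = y_i\lambda_1(\lambda_1+\eta_i) + (1-y_i)\lambda_0(\lambda_0-\eta_i)$
  with inverse-Mills terms evaluated in log space for tail stability).
* **Separation** (a covariate perfectly predicting the outcome) is detected
  — via the IRLS fitted-probability warning, a numerically perfect binary
  fit, or diverging coefficients — and raised as a classed warning; the
  information matrix is ridge-regularised only in that pathological case so
  a diagnosable fit is still returned. Rank-deficient designs are an error
  that names the collinear columns.
* The GLM converges on a relative deviance change of 1e-10; dispersion is
  estimated by the Pearson method; z statistics use the normal reference.
* The combined log-likelihood is the sum of the two parts' contributions.
  `information_criteria()` reports **every convention explicitly labelled**:
  whole-model `2k - 2ll` / `k ln n - 2ll`, the per-observation `AIC/n` used
  by some econometric packages, and a deviance-based BIC when a deviance is
  supplied. Published two-part tables can mix conventions — a printed
  per-observation AIC together with a log-likelihood pins down the
  estimation sample size, which is how one recovers that a published fit
  used 467 positive-cost observations — so none of the conventions is
  privileged.

The estimator is validated by simulation from a known two-part process
(`simulate_two_part_cohort()`): coefficient recovery within three standard
errors, 95% CI coverage over 200 replicates at n = 5,000, intercept-only
closed forms ($\Phi^{-1}(\hat p)$ and $\ln \bar y$), and brute-force
likelihood-grid domination on tiny datasets. Wald z intervals for a gamma
GLM with shape below 1 are known to undercover slightly in finite samples
(~94% at these settings); the coverage checks are read with that in mind.

## 4. The synthetic cohort generator

`generate_cohort()` draws patient records matching the marginal structure of
the motivating sample: NYHA mix 106/189/88/119 over 502, 61.1% male, 91.2%
basic insurance, 42.4% complementary insurance, 61% comorbidity, 72%
household heads, age normal(63.46, 14.27) truncated to the observed 8-95
range, follow-up equiprobable over {2, 4, 6} months, 60% hospitalised in the
last year.

Cost components are **zero-inflated mixtures**: an exact zero with
probability $p_0$, otherwise a lognormal (default) or gamma draw
parameterised by mean and CV. `calibrate_component_to_marginal()` inverts
the mixture moments so the marginal mean/SD match published targets exactly;
infeasible targets (SD below the Bernoulli floor
$M\sqrt{p_0/(1-p_0)}$) raise an error stating the floor. Zero-cost
prevalences per component are not published; the defaults (5-30% by
component) are assumptions exposed in the config. A caveat worth knowing:
with the CVs implied by the published SDs (~5-6), the lognormal option's
*sample SD* converges very slowly (its fourth moment is enormous), so
moment-fidelity checks at a million draws use the gamma option.

Other generator conditions, chosen once: annual HF mortality 10%;
admission-cost mean set so admissions contribute about 20% of direct medical
cost across the cohort; employment mixture 35% employed / 40% housewife /
25% retired (the motivating population is dominated by housewives and
retirees); indirect-cost drivers (absent days, reduced-productivity days,
unpaid hours) scaled so the implied component magnitudes are of the
published order, with unpaid work dominant. A `p_zero_cost_patient` layer
(default 7%) makes a patient incur no cost at all — the zero part the
two-part regression estimates; published positive-cost counts are consistent
with roughly this rate.

Covariates are drawn independently (the source publishes marginals only);
an optional per-class cost multiplier can induce class-cost correlation.
What passing tests on this generator do **not** show: real cost data have
correlation between components, between covariates and costs, and censoring
by death — none of which the default generator emulates. The generator
validates the *arithmetic and estimators*, not epidemiological realism.

Reproducibility is strict: the same config (including seed) yields a
bit-identical cohort, the caller's RNG state is restored, and the CSV
round-trip is exact (doubles serialised at 17 significant digits).

## 5. Pipeline and problem sizes

`run_pipeline()` chains generate → prevalence → markov → regress from one
`run_config()`, writes every artifact (CSV + markdown report) and returns a
manifest with MD5 hashes; two runs from the same config are byte-identical.
The test suite and the acceptance script size their simulations to be
statistically decisive yet quick: cohorts of 300-502 for pipeline checks
(the motivating sample size), 1e5-1e6 draws for moment checks, 1e5
trajectories for the microsimulation cross-check, and 200 replicates at
n = 5,000 for coverage — a few minutes in total.

## Known limitations

* Independence of covariates and cost components in the default generator
  (above).
* The placeholder transition matrix is synthetic; lifetime-cost levels from
  `default_markov_spec()` are illustrative only.
* Censoring is not modelled in the regression: zeros are structural, not
  censored observations.
* Tariff schedules, claims ingestion and probabilistic sensitivity analysis
  are out of scope.
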