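---
title: "Methods: the cohort model, its distributions and the value-of-information estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cohort model, its distributions and the value-of-information estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfvoi)
```

## The decision problem

Three strategies for managing chronic heart failure are compared: usual
care (UC), nurse telephone support (NTS) and home telemonitoring (HTM).
The payoff is net monetary benefit against usual care at a
willingness-to-pay threshold $\lambda$ (EUR/QALY),
$\mathrm{NMB}_j(\theta,\lambda)=\lambda\,\Delta E_j(\theta)-\Delta
C_j(\theta)$, where $\theta$ collects every uncertain model input. The
package quantifies (i) which strategy maximizes expected net benefit,
(ii) the expected cost of deciding under current uncertainty (EVPI), and
(iii) how much of that cost each parameter group is responsible for
(EVPPI).

## The cohort Markov model

Patients occupy one of five states: NYHA classes I–IV (living, of
increasing severity) and death, which is absorbing. The cohort is
propagated in 4-month cycles over a 20-year horizon (60 cycles), a
lifetime horizon for this population: under the default evidence
essentially the whole cohort has died by the end of the horizon.

* **Transitions.** Each arm has one transition matrix per *trial phase*
  (default `n_trial_phases = 3`, i.e. one year of 4-month cycles). From
  cycle `n_trial_phases` onward the last phase's matrix is held constant —
  the follow-up data end there, so the last observed transition behaviour
  is extrapolated. A `time_homogeneous`-style analysis can be emulated by
  generating evidence with `n_trial_phases = 1` (which pools the phases at
  the evidence level).
* **Rewards.** Per cycle, QALYs are occupancy-weighted utilities times
  1/3 year; costs are occupancy-weighted state costs (resource counts
  dotted with unit costs) plus arm-specific fees. Death carries zero
  utility and zero cost, the conventional absorbing-state treatment.
* **Fees.** The HTM installation fee is charged at cycle 0 and again at
  the start of every replacement interval (default 5 years: cycles 15,
  30, 45), reflecting limited equipment lifetime; the HTM service fee and
  the NTS support cost accrue every cycle. All fees are weighted by the
  alive fraction — dead patients generate no fees.
* **Cycle convention.** Rewards accrue on *cycle-start* occupancy for
  cycles 0..59; the initial distribution is the cycle-0 occupancy. No
  half-cycle correction is applied by default;
  `model_settings(half_cycle_correction = TRUE)` averages start- and
  end-of-cycle occupancy instead, for sensitivity analyses.
* **Discounting.** Compound per-cycle discounting,
  $(1+r)^{-c/3}$ for cycle $c$, with $r = 4\%$/year for costs and
  $1.5\%$/year for effects (the Dutch guideline rates). Per-patient VOI
  itself is undiscounted; discounting enters VOI only through the
  effective population, using the *cost* rate because the payoff is
  monetary.

The engine is a small C++ kernel (`src/cohort.cpp`) evaluating whole
batches of draws, which keeps the nested EVPPI loops tractable; a plain-R
trace implementation (`run_cohort()`) returns the full occupancy trace and
is tested to agree with the kernel to 1e-9, as both are against an
independent loop-based oracle in the test suite.

## The evidence base and its distributions

`generate_evidence()` builds the prior evidence from which all parameter
distributions are constructed:

| Block | Distribution | Evidence |
|---|---|---|
| Transition rows (per arm × phase) | Dirichlet | transition counts |
| Utilities per living state | beta (gamma optional) | mean ± sd, method of moments |
| Resource use per state (2 blocks) | gamma | mean and CV |
| Unit costs per resource type | gamma | mean and CV |
| HTM install / service fee | uniform | lower/upper bounds |
| Initial NYHA distribution | Dirichlet | state counts |

Dirichlet rows use the *counts-as-alphas* convention (no +1 prior); rows
are sampled as normalized gammas, so a row with a single positive count is
exactly degenerate. Utilities default to beta because they live in
[0, 1]; a gamma option exists (`utility_distribution = "gamma"`) since
both parameterizations appear in practice for utility-like quantities.
Infeasible moment combinations (a beta sd too large for its mean) are
rejected at build time, never silently clipped. All parameters are sampled
independently; correlated sampling is out of scope.

The EVPPI-eligible parameters form five groups: `TRANSITIONS`,
`UTILITIES`, `HOSP_ER` (hospitalizations and ER visits),
`CONTACTS_COSTS` (professional contacts and telephone calls *plus all
unit costs* — merging them is the only reading consistent with five
groups when "state-specific costs" and "resource utilization" name the
same money), and `INITIAL_DIST`. Intervention fees belong to no group:
they are resolved only under full EVPI (a diagnostic pseudo-group
`"FEES"` exists for full-conditioning checks).

### What the generator emulates — and what it does not

The generator's defaults describe the study conditions: an initial NYHA
distribution of 19/44/29/8 percent (pseudo-sample 400), 4-month usual-care
transition rows with mortality rising from 3% (NYHA I) to 25% (NYHA IV)
per cycle, pseudo-sample size 100 per row/phase/arm, and mildly protective
telehealth arms — a relative reduction of transition mass to worse states
and death of 12% (NTS) and 20% (HTM), the removed mass staying in the
current state. Utilities (0.85/0.75/0.60/0.45, arm-independent) and
resource use are state-dependent only, because by design only disease
progression is treatment-specific; a `treatment_specific_resource_use`
switch stores per-arm resource evidence instead. Fee defaults (install
€1,500–2,500; service €300–500 per cycle; NTS €150 per cycle) make the
telehealth arms genuinely more expensive, so ICERs are positive and the
frontier has the expected topology: UC at low $\lambda$, NTS in a middle
band, HTM at high $\lambda$.

These are *synthetic magnitudes*, chosen once as clinically plausible;
they are not estimates of any trial's values. Passing tests on this
evidence demonstrates that the machinery is correct and that the
qualitative decision picture (frontier topology, EVPI kinks at the ICERs,
transitions dominating the EVPPI) emerges for evidence of this structure —
not that any specific euro figure applies to real data. Features of real
data the generator does not emulate include parameter correlation,
informative missingness in the underlying trial, time-varying utilities
and background mortality by age.

The generator is deterministic given its configuration (counts are target
probabilities × pseudo-sample size), so a zero-effect configuration gives
byte-identical counts across arms; the seed is recorded in metadata and
consumed only by the optional count jitter. A separate
`arm_shared_transitions` switch makes *sampling* share one drawn matrix
set across arms (it requires identical counts); this is the configuration
in which identical-arm symmetry holds draw-by-draw, used for null-effect
analyses and tests.

## PSA and cost-effectiveness outputs

`run_psa()` (default 2,500 draws) yields per-draw discounted costs and
QALYs per arm. From it: `nmb()` (UC column identically zero), `ceac()`
(probability of attaining the maximal NMB; ties to the lowest arm index so
the degenerate identical-arms case is deterministic), `frontier()` (argmax
of *mean* NMB), and `icer_table()` (ICERs on mean increments — consistent
with frontier switch points — with dominance flags instead of errors).
Note the frontier arm need not have CEAC probability above one half; the
two summaries answer different questions.

## Value of information estimators

**EVPI** is estimated single-loop from the PSA:
$\widehat{\mathrm{EVPI}} = \frac1n\sum_i \max_j \mathrm{NMB}_{ij} -
\max_j \frac1n\sum_i \mathrm{NMB}_{ij}$. It is non-negative up to Monte
Carlo noise, invariant to the baseline arm and to any per-draw constant
added to all arms (both tested to 1e-9).

**EVPPI** uses the two-level scheme without linearity shortcuts
(regression/quadrature approximations are deliberately not the default,
because Markov-model payoffs are nonlinear in their inputs). Outer loop
$k=1..K$: draw the group of interest from its marginal. Inner loop
$j=1..J$: draw the complement conditionally — under independence the
conditional is the marginal — evaluate the model, average NMB per arm.
Then

$$\widehat{\mathrm{EVPPI}} = \frac1K \sum_k \max_j \overline{\mathrm{NMB}}_{jk}
 - \max_j \overline{\overline{\mathrm{NMB}}}_j ,$$

where the baseline (second) term is computed from the pooled $K \times J$
evaluations rather than a separate PSA, so the estimator is
self-consistent at small sizes. Fresh conditional samples are drawn for
every $k$ (inner-loop reuse would correlate outer iterations). With
$J = 1$ the estimator reduces algebraically to single-loop EVPI on the $K$
outer draws.

Because NMB is affine in $\lambda$, one set of $K \times J$ evaluations
stores per-$k$ inner-mean incremental costs and effects and evaluates the
*whole* WTP grid at negligible extra cost; `evppi_per_patient()` therefore
accepts a vector of thresholds.

**Finite-$J$ bias.** The outer max of noisy inner means is biased upward,
so a group with zero true EVPPI shows a positive estimate of order
$\sigma/\sqrt{J}$ (roughly €50–100 at $J$ = 300–500 on the default
evidence) and the nested estimate can exceed the single-loop EVPI. The
exact ordering $\mathrm{EVPPI} \le \mathrm{EVPI}$ is asserted only in
enumeration mode (feeding the estimators the complete discrete support of
a toy model, where they coincide with brute-force enumeration to 1e-12);
on stochastic toys the suite asserts instead that the bias shrinks as $J$
grows.

**Convergence escalation.** `evppi_converged()` evaluates at
$J=K=500, 1000, \dots$ (cap 2,500) and stops when successive values at a
*reference threshold* (default €20,000/QALY, the informal Dutch threshold)
differ by less than 1% relative, with an absolute floor of €1 for
near-zero values; hitting the cap is flagged, not an error. Two practical
consequences of the bias analysis above, observed on the default
evidence: near-zero groups decay like $1/\sqrt{J}$ between steps (20–30%
relative changes) and *never* meet the 1% rule before the cap, and even
the strong transitions signal moves by 2–5% between steps at these sizes.
A fixed-budget run (`evppi_per_patient()` with explicit $J, K$ — the
per-group defaults used by `voi_curves()` are a 2,500 cap for transitions
and 1,000 for the other groups) is therefore the realistic workhorse, and
the escalation rule demonstrably stops early when the payoff genuinely
does not depend on the group (e.g. any group under a null-effect,
fee-free configuration, where EVPPI is exactly zero).

## Population scaling

The yearly number of CHF patients is projected linearly: 160,000 in 2018
growing by 5,000/year (the increment implied by national estimates of
130,000 in 2012 and 195,000 by 2025) to 255,000 in 2037. The effective
population discounts these cohorts at the cost rate with the *first year
undiscounted*:

$$N_\mathrm{eff} = \sum_{t=0}^{19} \frac{I_t}{1.04^{t}} = 2{,}841{,}567
\quad (\textstyle\sum_t I_t = 4{,}150{,}000).$$

The $t=0$ start is the convention that reproduces the published
population figures exactly; the $t=1$ variant (every year discounted,
giving 2,732,276) is available via `first_year_discounted = TRUE`. The
NYHA IV analysis multiplies the reported effective population by the
trial's initial NYHA IV share, 7.32%, giving 208,003 — a direct scaling,
not a separate discounted projection. Population counts are rounded
half-up at the reporting boundary only; internal arithmetic is unrounded.
Population VOI is then per-patient VOI × effective population, applied
identically to EVPI and EVPPI curves.

## Randomness and reproducibility

Every source of randomness derives from one master seed through named
streams (`derive_seed(master, purpose, index, ...)`, a polynomial string
hash into 32-bit range): the PSA, each EVPPI outer iteration's group draw
and inner batch, and each escalation step get distinct streams, so inner
EVPPI sampling is independent across outer iterations yet every result is
bit-for-bit reproducible from (config, seed) — `run_full_analysis()`
writes a manifest of content checksums and identical configs reproduce
identical checksums. Batches are sampled with vectorized RNG calls in a
fixed block order (transitions, utilities, hosp/ER, contacts, unit costs,
fees, initial), so a size-1 batch consumes the stream exactly like a
single draw.

## Problem sizes used by the tests and the acceptance script

The test suite runs the full study sizes where they are cheap (2,500-draw
PSA, 100-draw oracle comparisons) and scaled-down nested loops where they
are not: the group-ranking check uses $J=K=300$ per group (the
transitions-vs-rest margin is an order of magnitude, robust at this
size), escalation mechanics are exercised at step 20/cap 100 on the
default evidence, and the default 500-step rule runs on the null-effect
configuration where it stops at the second step. The acceptance script
uses the full 2,500-draw PSA for both analyses and $J=K=500$ per group
for the EVPPI ranking; it completes in about a minute on one CPU.

## Known limitations

* Cohort-level (second-order) simulation only; no patient-level
  microsimulation, time-varying utilities or age-dependent background
  mortality.
* Independence across parameters; grouped EVPPI inherits whatever bias
  the grouping itself introduces.
* The escalation rule judges convergence at one reference threshold.
* EVSI and structural/methodological uncertainty are out of scope.
* All euro magnitudes on generated evidence are synthetic; only the
  population arithmetic is exact.
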