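---
title: "Model structure, calibration and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdcem)
```

## Scope

`cdcem` implements a two-phase cost-effectiveness model of biologic therapy
in moderate to severe Crohn's disease: a decision-tree induction phase
followed by a Markov cohort maintenance phase on two-week cycles, evaluated
from a societal perspective over a lifetime horizon. Two packaged
comparisons are shipped: ustekinumab versus adalimumab in patients failing
conventional care, and ustekinumab versus vedolizumab in patients failing
TNF-alpha inhibitors.

Several inputs the printed sources do not report — the standard-of-care
transition matrix, post-surgery destinations, background mortality, the
end-of-maintenance calibration targets, adverse-event unit costs, the
standard-of-care drug cost and the surgical complication probability — are
deterministic synthetic stand-ins. Every such field is listed in the input
object's `provenance` record and announced by the command-line tools, so no
run of this package can be mistaken for a reproduction of the published
base-case totals.

## Health states

Disease activity is graded by the Crohn's Disease Activity Index (CDAI)
into remission (CDAI < 150), mild (150–219) and moderate-severe (220–599),
plus a transient surgery state with one-cycle residence and an absorbing
death state. During maintenance each CDAI state is additionally stratified
by treatment status — biologic at standard dose, biologic at escalated
dose, post-biologic, and non-biologic standard of care — giving a
14-dimensional occupancy vector:

```{r}
expanded_states()
```

## Induction phase

All patients enter in the moderate-severe state and receive the first
induction dose. At the first response assessment, responders (rate
$\beta$) split across the CDAI states: remission with probability
$\alpha$, moderate-severe with probability $\beta\gamma$ (the fraction
$\gamma$ of responders who respond without leaving the moderate-severe
band), and mild with the remainder $\beta - (\alpha + \beta\gamma)$.
Non-responders receive a second induction dose and are re-assessed the
same way; final non-responders move to non-biologic standard of care. The
split is feasible only when $\alpha \le \beta(1-\gamma)$, which the input
validator enforces.

```{r}
induction_transition_split(alpha = 0.349, beta = 0.555, gamma = 0.047)
```

Between the two assessments, first-dose responders are already on
maintenance dosing, so the induction accrual includes a pro-rated
"bridge" of maintenance drug (and, for intravenous regimens,
administration occasions) for the responder mass over those weeks.
Induction costs and QALYs are accrued undiscounted and then discounted at
the midpoint of the induction period when combined with the maintenance
results. A one-off induction surgery probability is applied across all
states at the end of the phase.

## Maintenance phase

`run_maintenance()` propagates the cohort to the horizon in two-week
cycles. Within each cycle, events apply in a fixed order:

1. **Treatment stop** — at the first cycle past the treatment duration
   (counted from model entry, so induction weeks consume part of it), the
   biologic strata move to the post-biologic stratum.
2. **Background mortality** — an age-indexed per-cycle probability from
   every alive state.
3. **Surgery** — last cycle's surgical patients exit to the post-surgery
   CDAI distribution on standard of care; a per-cycle probability
   (constant-hazard conversion `1 - (1 - p_annual)^(2/52)` of the annual
   rate) draws new patients from every CDAI state.
4. **Discontinuation** — moderate-severe patients on biologic leave for
   standard of care at a dose-specific per-cycle probability.
5. **Dose escalation** — standard-dose patients escalate at a per-cycle
   probability while treatment continues.
6. **CDAI transition** — each stratum transitions by its matrix: the
   calibrated biologic matrix on treatment, the standard-of-care matrix
   off treatment, and, for the post-biologic stratum, a linear blend of
   the two that reaches the standard-of-care matrix over the treatment's
   convergence period (`blend_matrices()`).

Mass conservation is asserted every cycle at $10^{-9}$.

## Calibration

The biologic transition matrix is not published; it is calibrated so that
propagating the arm's start-of-maintenance CDAI distribution for the
on-treatment cycle count reproduces the arm's end-of-maintenance target
(remission, mild) shares. The objective is the sum of squared deviations
in those two shares. Rows are parameterised by softmax, making the search
unconstrained while keeping every candidate row-stochastic; optimisation
uses Nelder–Mead from multiple seeded restarts, never returns a worse
objective than the supplied start values, breaks ties toward the
higher-entropy (less extreme) matrix, and reports convergence against a
$10^{-8}$ tolerance. Targets generated by forward-simulating known
matrices are recovered to that tolerance in the test suite, and a
0.01-step exhaustive grid search on degenerate two-state instances bounds
the optimiser from below.

```{r}
tg <- calibration_target(c(0.5, 0.3, 0.2), 0.42, 0.27, n_cycles = 26)
m <- calibrate_transition_matrix(tg, n_restarts = 4, seed = 1)
attr(m, "convergence")
```

## Economics

Costing is societal: drug acquisition pro-rated per cycle over the dosing
interval (escalated patients at the escalation cost multiplier, with
concomitant standard-of-care drug for a fraction of biologic patients),
intravenous administration lumped at dosing cycles, health-state direct
and indirect (productivity) two-week tariffs, adverse-event costs and
utility decrements on biologic occupancy, and surgical complication costs
on surgery occupancy. Costs and QALYs accrue on start-of-cycle occupancy
— no half-cycle correction by default, switchable via
`structural$half_cycle_correction` — and discount at
$(1+r)^{-t}$ with $t$ in years from model entry. Incremental analysis
classifies dominance by the sign pattern of the increments and reports an
ICER only when defined; strategies run under different discount settings
or horizons refuse to compare.

## Uncertainty

`run_owsa()` applies named override scenarios (the packaged grid varies
discount rates, horizon, treatment duration, indirect-cost inclusion,
escalation, response criterion and utility sets). `run_psa()` samples
parameters with standard families — beta for probabilities and utilities
(method of moments), gamma for costs, Dirichlet for matrix rows and
targets, lognormal odds for efficacy — at a relative standard error of
10% by default. Each iteration uses the deterministic substream
`(seed * 10007 + i) mod 2147483647`, so any iteration is reproducible in
isolation; draws violating an input invariant are rejected and redrawn
within a bounded budget. `ceac()` counts the fraction of iterations with
strictly positive net monetary benefit per willingness-to-pay value.

## Validation against microsimulation

`microsimulate()` is an independently implemented individual-level
simulation of the maintenance phase — per-state binomial and multinomial
count sampling in the same event order, sharing no propagation code with
the cohort engine. At 100,000 patients over 50 cycles on random
scenarios, cohort occupancies match the microsimulated means within three
Monte-Carlo standard errors in over 99% of (cycle, state) cells; the test
suite and the acceptance script both run this comparison.

## Synthetic inputs: scope and limits

`generate_unpublished_inputs()` fills the unpublished fields with fixed,
seed-independent defaults (a standard-of-care matrix biased toward worse
states than any biologic analogue, Gompertz-shaped mortality for ages
35–110, end-of-maintenance targets preserving the qualitative efficacy
ordering of the trial arms, a 15% surgical complication probability).
These are study conditions, not calibrated quantities: results computed
on them carry the qualitative structure of the model but not the
published magnitudes. `generate_random_scenario()` produces fully random,
schema-valid scenarios for property-based testing.
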