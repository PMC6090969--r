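# cdcem

Cost-effectiveness modelling of biologic therapy in moderate to severe
Crohn's disease.

`cdcem` implements a two-phase health-economic model: a decision-tree
**induction** phase, in which patients respond, remit or fail one or two
induction doses, followed by a Markov cohort **maintenance** phase over
two-week cycles and a lifetime horizon. Disease activity is graded by the
Crohn's Disease Activity Index (CDAI) into remission (< 150), mild
(150–219) and moderate-severe (220–599) states, alongside a transient
surgery state and absorbing death. During maintenance, each CDAI state is
stratified by treatment status (biologic standard dose, escalated dose,
post-biologic, standard of care), giving a 14-state occupancy vector.

Two comparisons from the Swedish setting are packaged: ustekinumab versus
adalimumab after conventional-care failure, and ustekinumab versus
vedolizumab after TNF-alpha-inhibitor failure, with every published
parameter carried verbatim (prices in 2016 EUR, societal perspective, 3%
annual discounting, willingness-to-pay reference of €63,000 per QALY).

The model's headline published totals are **not** reproducible from public
information alone: they depend on unpublished calibrated transition
matrices, mortality tables and standard-of-care inputs. Those fields are
filled with deterministic synthetic stand-ins, every one listed in the
input object's `provenance` record. The package therefore reproduces the
model's *structure*, arithmetic and published parameters exactly, and its
unpublished quantities only qualitatively.

## What the package does

- **Induction tree** — response/remission splits with the feasibility
  constraint α ≤ β(1 − γ); two-dose sequence; bridge dosing between
  assessments; undiscounted accrual discounted at the phase midpoint.
- **Calibration** — the biologic transition matrix is fit by constrained
  least squares (softmax row parameterisation, multi-restart Nelder–Mead,
  10⁻⁸ tolerance, entropy tie-break) so the cohort hits the arm's
  end-of-maintenance remission/mild target after the on-treatment cycles.
- **Markov engine** — fixed within-cycle event order (treatment stop,
  mortality, surgery, discontinuation, escalation, CDAI transition), mass
  conservation asserted every cycle, post-treatment efficacy converging
  linearly to standard of care.
- **Economics** — societal costing (drug, administration, direct and
  indirect state tariffs, adverse events, surgical complications), QALY
  accrual, discounting, incremental analysis with dominance handling.
- **Uncertainty** — scenario/one-way analysis, probabilistic sensitivity
  analysis with per-iteration seed substreams, CEAC and net monetary
  benefit.
- **Validation oracle** — an independent individual-level microsimulation
  of the maintenance phase; cohort traces match it within three
  Monte-Carlo standard errors in > 99% of cells at 100,000 patients.

## Worked example

```r
library(cdcem)

inp <- published_baseline_inputs("conventional_care_failure")
inp
#> <cdcem_inputs>
#>   population: conventional_care_failure
#>   comparison: ustekinumab vs adalimumab
#>   horizon: 60 years; treatment duration: 2 years
#>   synthetic stand-in fields: costs.soc_drug_cost_2wk, costs.surgery_complication_cost, costs.ae_unit_costs, treatments.*.efficacy.CDAI70, treatments.*.convergence_cycles, treatments.*.escalation_cost_multiplier, unpublished

cmp <- run_comparison(inp, n_restarts = 4, seed = 1)
cmp
#> <cdcem_comparison> conventional_care_failure
#>   intervention ustekinumab  cost    335153  QALYs  15.352
#>   comparator   adalimumab   cost    322755  QALYs  15.314
#>   ICER 326911 per QALY

attr(comparison_table(cmp), "incremental")
#>  delta_cost delta_qalys     icer classification
#>    12397.16  0.03792208 326911.4  icer_reported

nmb(cmp$incremental$delta_cost, cmp$incremental$delta_qalys, wtp = 63000)
#> [1] -10008.07
```

These numbers rest on the synthetic stand-ins and are not the published
base case. The published per-arm totals are packaged for worked examples
of the incremental arithmetic only:

```r
pb <- published_base_case()
subset(pb, population == "conventional_care_failure",
       c(treatment, total_cost, total_qalys))
#     treatment total_cost total_qalys
# 1 ustekinumab     232225      14.275
# 2  adalimumab     239209      14.043
```

Sensitivity analyses:

```r
owsa <- run_owsa(inp)                              # packaged scenario grid
psa  <- run_psa(inp, n_iterations = 1000, seed = 1)
head(ceac(psa))                                    # acceptability curve
```

## Command line

An executable wrapper is installed under `inst/cli/cdcem`:

```sh
cdcem run inst/extdata/conventional_care.yaml --out results --seed 1
cdcem owsa inst/extdata/tnf_failure.yaml --out results
cdcem psa inst/extdata/conventional_care.yaml --iterations 1000 --seed 1 --out results
cdcem synth --population tnf_failure --out my_inputs.yaml
```

Every run writes a `manifest.json` with the package version, config file
hash and seed, so outputs are regenerable.

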