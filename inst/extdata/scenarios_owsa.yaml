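# One-way and structural sensitivity scenarios. Each entry overrides the
# base-case inputs at the named parameter paths; the base_case entry has no
# overrides and must reproduce the base run exactly.
- name: base_case
  overrides: {}
- name: discount_costs_0pct
  overrides:
    structural.discount_rate_costs: 0.0
- name: discount_costs_5pct
  overrides:
    structural.discount_rate_costs: 0.05
- name: discount_effects_0pct
  overrides:
    structural.discount_rate_effects: 0.0
- name: discount_effects_5pct
  overrides:
    structural.discount_rate_effects: 0.05
- name: horizon_15y
  overrides:
    structural.horizon_years: 15
- name: horizon_5y
  overrides:
    structural.horizon_years: 5
- name: treatment_duration_5y
  overrides:
    structural.treatment_duration_years: 5
- name: indirect_costs_excluded
  overrides:
    structural.include_indirect_costs: false
- name: discount_both_0pct
  overrides:
    structural.discount_rate_costs: 0.0
    structural.discount_rate_effects: 0.0
- name: discount_both_5pct
  overrides:
    structural.discount_rate_costs: 0.05
    structural.discount_rate_effects: 0.05
- name: no_dose_escalation
  overrides:
    structural.allow_dose_escalation: false
- name: modsev_resource_cost_doubled
  overrides:
    costs.state_direct_2wk.moderate_severe: 216
- name: response_criterion_cdai70
  overrides:
    structural.response_criterion: CDAI70
- name: no_adverse_event_effect
  overrides:
    structural.include_ae_effects: false
- name: utilities_previous_markov_model   # synthetic stand-in utility set
  overrides:
    utilities.state:
      remission: 0.87
      mild: 0.76
      moderate_severe: 0.59
      surgery: 0.59
- name: utilities_sf36_mapped   # synthetic stand-in utility set
  overrides:
    utilities.state:
      remission: 0.78
      mild: 0.67
      moderate_severe: 0.57
      surgery: 0.57
- name: utilities_cdai_mapped   # synthetic stand-in utility set
  overrides:
    utilities.state:
      remission: 0.81
      mild: 0.70
      moderate_severe: 0.52
      surgery: 0.52
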