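# TNF-alpha-inhibitor failure population: ustekinumab vs vedolizumab.
# Published values are carried verbatim from their printed sources (2016 EUR);
# fields listed under `provenance` are synthetic stand-ins for inputs the
# publication does not report.
schema_version: 1
comparison: ustekinumab_vs_vedolizumab
population:
  name: tnf_failure
  mean_age: 37.3
  mean_weight_kg: 69.8
  proportion_female: 0.572
  weight_bands: [0.229, 0.588, 0.184]   # <55 kg, 56-84 kg, >85 kg (printed, rounded)
  gamma_mod_sev_remainder: 0.060
currency:
  code: EUR
  year: 2016
  sek_to_eur: 0.1057
structural:
  cycle_length_weeks: 2
  horizon_years: 60
  treatment_duration_years: 2
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  induction_surgery_prob: 0.02
  annual_surgery_prob: 0.07
  response_criterion: CDAI100
  include_indirect_costs: true
  include_ae_effects: true
  allow_dose_escalation: true
  half_cycle_correction: false
  wtp_reference: 63000
costs:
  iv_admin: 257
  sc_inhospital_admin: 124
  state_direct_2wk:
    remission: 26
    mild: 69
    moderate_severe: 108
    surgery: 7123
  state_indirect_2wk:
    remission: 79
    mild: 281
    moderate_severe: 374
    surgery: 1326
  concomitant_soc_fraction: 0.5
  soc_drug_cost_2wk: 40
  surgery_complication_cost: 9000
  ae_unit_costs:
    serious_infection: 21000
    tuberculosis: 14000
    lymphoma: 30000
    hypersensitivity: 1500
    skin_reaction: 150
utilities:
  state:
    remission: 0.80
    mild: 0.68
    moderate_severe: 0.55
    surgery: 0.55
  ae_disutility:
    serious_infection: -0.52
    tuberculosis: -0.55
    lymphoma: -0.20
    hypersensitivity: -0.11
    skin_reaction: -0.03
treatments:
  intervention:
    name: ustekinumab
    drug:
      pack_mg: 90
      pack_cost: 3546
    induction:
      first:
        route: IV
        weeks: [0]
        weight_band_mg: [260, 390, 520]
      second:
        route: SC
        weeks: [8]
        doses_mg: [90]
      first_assessment_week: 8
      second_assessment_week: 16
    maintenance:
      dose_mg: 90
      interval_weeks: 12
      route: SC
    efficacy:
      CDAI100:
        first: {response: 0.337, remission: 0.185}
        second: {response: 0.411, remission: 0.184}
      CDAI70:
        first: {response: 0.388, remission: 0.185}
        second: {response: 0.473, remission: 0.184}
    ae_cycle_rates:
      serious_infection: 0.0034
      tuberculosis: 0.0
      lymphoma: 0.0
      hypersensitivity: 0.0001
      skin_reaction: 0.0075
    discontinuation_cycle_prob_standard: 0.106
    discontinuation_cycle_prob_escalated: 0.114
    escalation_cycle_prob: 0.02
    escalation_cost_multiplier: 1.5
    convergence_cycles: 26
  comparator:
    name: vedolizumab
    drug:
      pack_mg: 300
      pack_cost: 2334
    induction:
      first:
        route: IV
        weeks: [0, 2, 6]
        doses_mg: [300, 300, 300]
      second:
        route: IV
        weeks: [10]
        doses_mg: [300]
      first_assessment_week: 10
      second_assessment_week: 14
    maintenance:
      dose_mg: 300
      interval_weeks: 8
      route: IV
    efficacy:
      CDAI100:
        first: {response: 0.327, remission: 0.129}
        second: {response: 0.160, remission: 0.068}
      CDAI70:
        first: {response: 0.376, remission: 0.129}
        second: {response: 0.184, remission: 0.068}
    ae_cycle_rates:
      serious_infection: 0.0032
      tuberculosis: 0.0
      lymphoma: 0.0
      hypersensitivity: 0.0
      skin_reaction: 0.0059
    discontinuation_cycle_prob_standard: 0.377
    discontinuation_cycle_prob_escalated: 0.312
    escalation_cycle_prob: 0.02
    escalation_cost_multiplier: 2.0
    convergence_cycles: 13
provenance:
  - costs.soc_drug_cost_2wk
  - costs.surgery_complication_cost
  - costs.ae_unit_costs
  - treatments.*.efficacy.CDAI70
  - treatments.*.convergence_cycles
  - treatments.*.escalation_cost_multiplier
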