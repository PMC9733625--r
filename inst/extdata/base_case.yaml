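# Base-case model inputs: England, 2019 GBP, 5-year horizon.
settings:
  discount_rate: 0.035
  horizon_years: 5
  start_age: 70
  male_fraction: 0.46
  wtp_grid: {from: 0, to: 100000, by: 1000}
  population_size: 1415

life_table: bundled

strategies:
  MRGFUS:
    p_marked: 0.889
    p_mild: 0.100
    p_none: 0.011
    waning_annual: 0.092
    recurrence_annual: 0.01
    p_reop_given_recurrence: 0.05
    onset_delay_fraction: 0.0
    procedure_cost: 16500       # bundles all follow-up for years 1-5
    bundle_years: 5
    monitoring_annual: {"1": 0, "6": 169}
    medication_annual: 744
    u_bt: 0.69
    u_tr: 0.69
    u_mt_y1: 0.91
    u_mt_y2plus: 0.90
    u_mmt_y1: 0.80
    u_mmt_y2plus: 0.79
    ae_costs:
      infection: 657
      intracranial_haemorrhage: 20545
      lead_fracture_or_migration: 14777
      gait_disturbance: 0
      speech_problem: 42
  DBS:
    p_marked: 0.889
    p_mild: 0.100
    p_none: 0.011
    waning_annual: 0.077
    recurrence_annual: 0.039
    p_reop_given_recurrence: 0.05
    onset_delay_fraction: 0.25  # benefit from 3 months (device optimisation)
    procedure_cost: 47627       # bundles all follow-up for year 1
    bundle_years: 1
    monitoring_annual: {"1": 0, "2": 3172}
    medication_annual: 744
    u_bt: 0.69
    u_tr: 0.69
    u_mt_y1: 0.91
    u_mt_y2plus: 0.91
    u_mmt_y1: 0.80
    u_mmt_y2plus: 0.76
    ae_costs:
      infection: 657
      intracranial_haemorrhage: 20545
      lead_fracture_or_migration: 14777
      gait_disturbance: 0
      speech_problem: 42
  NONE:
    p_marked: 0.0
    p_mild: 0.0
    p_none: 1.0
    monitoring_annual: {"1": 169}
    medication_annual: 744
    u_bt: 0.69

psa:
  n_iterations: 1000
  sd_fraction: 0.2
  seed: 42

dsa:
  spread: 0.2
  filter: 0.05
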