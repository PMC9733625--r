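# Template for an alternative-inputs scenario (e.g. parameter values taken
# from a different clinical trial). Replace every FILL_ME before use; the
# schema is identical to base_case.yaml.
settings:
  discount_rate: 0.035
  horizon_years: 5
  start_age: 70
  male_fraction: 0.46

life_table: bundled

strategies:
  MRGFUS:
    p_marked: FILL_ME
    p_mild: FILL_ME
    p_none: FILL_ME
    waning_annual: FILL_ME
    recurrence_annual: FILL_ME
    p_reop_given_recurrence: 0.05
    onset_delay_fraction: 0.0
    procedure_cost: 16500
    bundle_years: 5
    monitoring_annual: {"1": 0, "6": 169}
    medication_annual: 744
    u_bt: FILL_ME
    u_mt_y1: FILL_ME
    u_mt_y2plus: FILL_ME
    u_mmt_y1: FILL_ME
    u_mmt_y2plus: FILL_ME
  DBS:
    p_marked: FILL_ME
    p_mild: FILL_ME
    p_none: FILL_ME
    waning_annual: FILL_ME
    recurrence_annual: FILL_ME
    p_reop_given_recurrence: 0.05
    onset_delay_fraction: 0.25
    procedure_cost: 47627
    bundle_years: 1
    monitoring_annual: {"1": 0, "2": 3172}
    medication_annual: 744
    u_bt: FILL_ME
    u_mt_y1: FILL_ME
    u_mt_y2plus: FILL_ME
    u_mmt_y1: FILL_ME
    u_mmt_y2plus: FILL_ME
  NONE:
    p_marked: 0.0
    p_mild: 0.0
    p_none: 1.0
    monitoring_annual: {"1": 169}
    medication_annual: 744
    u_bt: FILL_ME
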