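# Minimal two-arm RRMS scenario: untreated vs one 4-week 10 mg/kg NX210c cycle
name: two_arm_example
mode: full
n_patients: 25
horizon_years: 2
dt_days: 0.25
master_seed: 11
subclinical_threshold_frac: 0.05
arms:
  - name: untreated
    profile: rrms_default
  - name: nx210c_10
    profile: rrms_default
    nx: nx210c_10mgkg_cycle
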