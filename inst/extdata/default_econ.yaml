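# Default economic parameter set: SYNTHETIC plausible values for the
# Chinese mCRC setting. Not trial micro-costing data; replace with local
# inputs for any real decision analysis.
patient:
  height_cm: 165.0
  weight_kg: 65.0
  bsa_m2: 1.79
schedule:
  cycle_days: 21.0
  induction_cycles: 6.0
  bevacizumab_mg_per_kg: 7.5
  oxaliplatin_mg_per_m2: 130.0
  capecitabine_mg_per_m2: 1000.0
  capecitabine_doses_per_day: 2.0
  capecitabine_days: 14.0
drug_prices:
  bevacizumab: 1.1
  oxaliplatin: 0.6
  capecitabine: 0.0015
aci_price_per_cycle: 6819.45
utilities:
  u_pfs_aci: 0.8
  u_pfs_control: 0.78
  u_pd: 0.6
ae:
  name:
  - anemia
  - neutropenia
  - leukopenia
  - thrombocytopenia
  - diarrhea
  inc_aci:
  - 0.04
  - 0.07
  - 0.05
  - 0.05
  - 0.03
  inc_control:
  - 0.06
  - 0.09
  - 0.06
  - 0.06
  - 0.04
  cost:
  - 560.0
  - 640.0
  - 480.0
  - 910.0
  - 330.0
  disutility:
  - 0.07
  - 0.09
  - 0.07
  - 0.05
  - 0.1
  duration_days:
  - 14.0
  - 10.0
  - 10.0
  - 12.0
  - 6.0
subsequent_tx:
  prob_aci: 0.56
  prob_control: 0.647
  cost: 12000.0
bsc_cost_per_cycle: 380.0
followup_cost_per_cycle: 120.0
terminal_cost: 1800.0
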