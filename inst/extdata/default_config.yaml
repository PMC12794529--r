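# Default run configuration: adult 2 g reference versus pediatric
# 20/25/30/35 mg/kg bolus candidates, with a 1/5/10-min administration
# sweep at 25 mg/kg.  Units: mg, mL, min; concentrations mg/L.
model:
  cl_typ: 190
  v1_typ: 17300
  q_typ: 80.1
  v2_typ: 11400
  exp_cl_wt: 0.75
  exp_q_wt: 0.75
  exp_v1_wt: 1.0
  exp_v2_wt: 1.0
  exp_plt: 0.468
  exp_nirs: -0.29
  exp_il8: -0.0873
  ref_wt: 70
  ref_plt: 196
  ref_nirs: 88
  omega2_cl: 0.106
  omega2_v1: 0.0688
  omega2_q: 0.879
  omega2_v2: 0.0589
  sigma2_prop: 0.0238
population:
  n: 1000
  adult_covariates:
    weight: 80.1
    plt: 197
    nirs: 88
    il8: 20.3
  pediatric_ranges:
    age: [4.7, 15.4]
    weight: [17.7, 58.2]
    plt: [205, 433]
    nirs: [51, 80]
    il8: [6.6, 50.2]
regimens:
  adult_amount: 2000          # mg
  pediatric_doses_mg_kg: [20, 25, 30, 35]
  cap: 2000                   # mg/dose
  duration: 1                 # min
  sweep_dose_mg_kg: 25
  sweep_durations: [1, 5, 10] # min
grid:
  horizon: 480                # min
nca:
  threshold: 10               # mg/L
  t_ends:
    auc_0_4h: 240
    auc_0_8h: 480
error_mode: proportional
seed: 20260926
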