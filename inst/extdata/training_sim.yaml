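n_patients: 144
biomarker_marginals:
  tls_density:
  - 0.354166666666667
  - 0.4375
  - 0.208333333333333
  panck_foci:
  - 0.319444444444444
  - 0.402777777777778
  - 0.277777777777778
  ki67_pct:
  - 0.520833333333333
  - 0.361111111111111
  - 0.118055555555556
  n_driver_mutations:
  - 0.472222222222222
  - 0.388888888888889
  - 0.138888888888889
  pdl1_fold:
  - 0.409722222222222
  - 0.430555555555556
  - 0.159722222222222
  cd8_foxp3_ratio:
  - 0.375
  - 0.423611111111111
  - 0.201388888888889
  gzmb_density:
  - 0.347222222222222
  - 0.458333333333333
  - 0.194444444444444
clinical_marginals:
  age_group:
    <=55: 0.451388888888889
    '>55': 0.548611111111111
  sex:
    male: 0.694444444444444
    female: 0.305555555555556
  primary_site:
    oral_oropharynx: 0.673611111111111
    larynx_hypopharynx: 0.326388888888889
  cps:
    <1: 0.333333333333333
    '>=1': 0.666666666666667
  differentiation:
    well: 0.298611111111111
    moderate: 0.388888888888889
    poor: 0.3125
  stage:
    III: 0.618055555555556
    IV: 0.381944444444444
  radiologic_response:
    CR: 0.291666666666667
    PR: 0.569444444444444
    SD: 0.138888888888889
  pathologic_response:
    pCR: 0.319444444444444
    mPR_not_pCR: 0.402777777777778
    no_mPR: 0.277777777777778
  pni:
    'no': 0.930555555555556
    'yes': 0.069444444444444
  lvi:
    'no': 0.9375
    'yes': 0.0625
  ene:
    'no': 0.972222222222222
    'yes': 0.027777777777778
  margin_class:
    close: 0.0625
    clear: 0.9375
true_log_hr:
  lrc:
    differentiation:
      moderate: 0.444685821261446
      poor: 0.783901543828409
    pathologic_response:
      mPR_not_pCR: 0.371563556432483
      no_mPR: 0.72270598280149
    mrix_category:
      intermediate: 0.636576829071551
      high: 1.147402452837542
  dmfs:
    differentiation:
      moderate: 0.482426149244293
      poor: 0.693147180559945
    pathologic_response:
      mPR_not_pCR: 0.65232518603969
      no_mPR: 0.576613364303994
    mrix_category:
      intermediate: 0.779324876800998
      high: 1.264126727145683
baseline:
  family: exponential
  rate: ~
  shape: 1.0
  target_event_rate:
    lrc: 0.181
    dmfs: 0.215
censoring:
  admin_min: 24.0
  admin_max: 72.0
  random_rate: 0.0
band_intervals:
  tls_density:
  - - 3.0
    - 10.0
  - - 1.0
    - 3.0
  - - 0.0
    - 1.0
  panck_foci:
  - - 0.0
    - 0.0
  - - 0.0
    - 5.0
  - - 5.0
    - 15.0
  ki67_pct:
  - - 0.0
    - 5.0
  - - 5.0
    - 20.0
  - - 20.0
    - 60.0
  n_driver_mutations:
  - 0
  - 1
  - - 2
    - 3
    - 4
  pdl1_fold:
  - - 0.0
    - 1.0
  - - 1.0
    - 2.0
  - - 2.0
    - 8.0
  cd8_foxp3_ratio:
  - - 2.0
    - 6.0
  - - 1.0
    - 2.0
  - - 0.0
    - 1.0
  gzmb_density:
  - - 200.0
    - 500.0
  - - 50.0
    - 200.0
  - - 0.0
    - 50.0
references:
  differentiation: well
  pathologic_response: pCR
  mrix_category: low
  margin_class: clear
seed: 1
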