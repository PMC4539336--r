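id: dka_resp_alkalosis
title: DKA with concurrent respiratory alkalosis from urosepsis
difficulty: 4
narrative: >
  A 31-year-old with type 1 diabetes presents febrile and rigoring with flank
  pain. She is markedly tachypneic beyond what her acidosis predicts; the
  blood gas shows a mixed picture with a near-normal pH despite a wide anion
  gap.
precipitating_cause: infection
special_feature: respiratory_alkalosis
initial_state:
  glucose: 35
  potassium: 3.6
  sodium: 136
  chloride: 100
  bicarbonate: 12
  pco2: 18
  beta_hydroxybutyrate: 4.5
  creatinine: 95
  volume_deficit: 2500
  heart_rate: 105
  systolic_bp: 98
  diastolic_bp: 66
  respiratory_rate: 25.6
  temperature: 38.9
coefficients:
  resp_offset: -8
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_urinalysis:
    report: pyuria with nitrites and leukocyte esterase; 3+ ketones
  order_blood_culture:
    report: gram-negative bacilli in both sets at 18 h
  order_cbc:
    report: WBC 21.2 x10^9/L with left shift
  order_cxr:
    report: clear lung fields
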