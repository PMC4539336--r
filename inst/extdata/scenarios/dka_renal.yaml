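id: dka_renal
title: DKA with renal impairment and presenting hyperkalemia
difficulty: 4
narrative: >
  A 58-year-old with type 1 diabetes and diabetic nephropathy stopped insulin
  during a religious fast. Creatinine is three times baseline and the serum
  potassium is high on arrival - replacement must wait for the
  insulin-driven shift and urine output.
precipitating_cause: insulin_omission
special_feature: renal_impairment
initial_state:
  glucose: 38
  potassium: 5.8
  sodium: 133
  chloride: 97
  bicarbonate: 11
  pco2: 24
  beta_hydroxybutyrate: 5.0
  creatinine: 320
  volume_deficit: 2500
  heart_rate: 105
  systolic_bp: 98
  diastolic_bp: 66
  respiratory_rate: 26.4
  temperature: 37.0
coefficients:
  creat_fluid: -0.002
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_ecg:
    report: peaked T waves in the precordial leads
  order_cbc:
    report: normal white count; normocytic anaemia of chronic kidney disease
  order_urinalysis:
    report: 4+ glucose, 3+ ketones, 2+ protein
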