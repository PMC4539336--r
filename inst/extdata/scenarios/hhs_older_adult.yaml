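id: hhs_older_adult
title: Older adult in hyperosmolar hyperglycemic state
difficulty: 5
narrative: >
  An 81-year-old with type 2 diabetes is brought from a retirement residence
  confused and profoundly dehydrated after a week of a urinary infection.
  Glucose is extreme, ketones are minimal, and the effective osmolality is
  very high; fluid resuscitation, not insulin, is the first priority.
precipitating_cause: infection
special_feature: hyperosmolar_hyperglycemic_state
initial_state:
  glucose: 62
  potassium: 4.2
  sodium: 148
  chloride: 108
  bicarbonate: 20
  pco2: 38
  beta_hydroxybutyrate: 1.0
  creatinine: 180
  volume_deficit: 7000
  heart_rate: 129
  systolic_bp: 76
  diastolic_bp: 55
  respiratory_rate: 19.2
  temperature: 37.9
coefficients:
  glucose_drift: 1.5
  bhb_drift: 0.05
  hr_per_ml: 0.007
  sbp_per_ml: -0.006
  dbp_per_ml: -0.003
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_urinalysis:
    report: cloudy urine, nitrites and leukocyte esterase positive
  order_cbc:
    report: WBC 15.8 x10^9/L; haemoconcentration with haematocrit 0.52
  order_ecg:
    report: sinus tachycardia, low-voltage T waves
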