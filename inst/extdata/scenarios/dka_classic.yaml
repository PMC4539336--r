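id: dka_classic
title: Classic DKA precipitated by community-acquired pneumonia
difficulty: 3
narrative: >
  A 24-year-old with type 1 diabetes presents with two days of cough, fever,
  polyuria and vomiting. She is tachypneic with deep sighing respirations and
  her breath smells of acetone. Serum potassium is low-normal on arrival.
precipitating_cause: infection
initial_state:
  glucose: 40
  potassium: 3.2
  sodium: 134
  chloride: 98
  bicarbonate: 10
  pco2: 23
  beta_hydroxybutyrate: 5.5
  creatinine: 110
  volume_deficit: 3000
  heart_rate: 110
  systolic_bp: 94
  diastolic_bp: 64
  respiratory_rate: 27.2
  temperature: 38.5
coefficients: default
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_cxr:
    report: right lower lobe consolidation consistent with pneumonia
  order_cbc:
    report: WBC 18.5 x10^9/L with neutrophilia; haemoglobin and platelets normal
  order_blood_culture:
    report: preliminary growth of gram-positive cocci at 24 h
  order_urinalysis:
    report: 4+ glucose, 3+ ketones, no nitrites or leukocyte esterase
  order_ecg:
    report: sinus tachycardia; flattened T waves, no U waves
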