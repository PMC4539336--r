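id: dka_mild
title: Mild euglycemic DKA on an SGLT2 inhibitor
difficulty: 2
narrative: >
  A 47-year-old with type 2 diabetes on an SGLT2 inhibitor presents with
  malaise and vomiting after two days of fasting for a procedure. Glucose is
  only modestly elevated, which can hide a significant ketoacidosis unless
  ketones and the anion gap are checked.
precipitating_cause: medication
special_feature: euglycemic
initial_state:
  glucose: 13
  potassium: 3.8
  sodium: 138
  chloride: 102
  bicarbonate: 14
  pco2: 29
  beta_hydroxybutyrate: 4.0
  creatinine: 85
  volume_deficit: 1500
  heart_rate: 95
  systolic_bp: 106
  diastolic_bp: 70
  respiratory_rate: 24.0
  temperature: 37.2
coefficients: default
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_cbc:
    report: normal
  order_urinalysis:
    report: 3+ ketones, 4+ glucose despite modest hyperglycemia
  order_cxr:
    report: clear lung fields
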