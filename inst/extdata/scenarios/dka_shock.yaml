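id: dka_shock
title: Severe DKA with hypovolemic shock
difficulty: 5
narrative: >
  A 19-year-old with type 1 diabetes is found obtunded after three days of
  gastroenteritis and missed insulin. He is profoundly acidaemic and
  hypotensive with cold peripheries; rapid volume resuscitation must precede
  everything else.
precipitating_cause: infection
special_feature: hypovolemic_shock
initial_state:
  glucose: 45
  potassium: 3.4
  sodium: 132
  chloride: 96
  bicarbonate: 6
  pco2: 17
  beta_hydroxybutyrate: 7.0
  creatinine: 140
  volume_deficit: 6000
  heart_rate: 140
  systolic_bp: 70
  diastolic_bp: 52
  respiratory_rate: 30.4
  temperature: 38.8
coefficients: default
rubric: default
hint_rules: default
lab_latencies: default
static_results:
  order_cbc:
    report: WBC 24.0 x10^9/L, haemoconcentration
  order_blood_culture:
    report: no growth at 48 h
  order_cxr:
    report: clear lung fields, small cardiac silhouette
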