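Package: dkasim
Title: Diabetic Ketoacidosis Management Simulator and Scoring-System Validity Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, scriptable simulator of diabetic ketoacidosis (DKA)
    management for medical education. A discrete-time linear physiology engine
    responds to learner orders (insulin, fluids, potassium, investigations),
    six contrasting clinical scenarios drive case variety, and a rule-based
    feedback engine issues in-session hints and end-of-run summary reports.
    Sessions are scored on an 18-item, 7-domain rubric (total 18-54), and a
    psychometric pipeline provides the validity evidence used for
    standard-setting: outlier screening, Cronbach's alpha, Kaiser-Meyer-Olkin
    sampling adequacy, one-way ANOVA with Tukey HSD, correlations, and ROC
    analysis with Youden-index cut-point selection. Seeded generators produce
    scripted learner sessions at graded skill levels and participant cohorts
    with controllable group effects and covariate correlations, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
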