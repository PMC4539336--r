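# Fixtures built in code: drift-free coefficients for hand-checkable
# dynamics, a small deterministic test scenario, and random-order fuzzing.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_coeffs <- function(...) {
  dka_coefficients(glucose_drift = 0, potassium_drift = 0, sodium_drift = 0,
                   chloride_drift = 0, bicarb_drift = 0, bhb_drift = 0,
                   deficit_drift = 0, creat_deficit = 0, creat_fluid = 0,
                   resp_comp = 0, insulin_bicarb = 0, ...)
}

test_state <- function(potassium = 3.2, glucose = 40, ...) {
  patient_state(glucose = glucose, potassium = potassium, sodium = 134,
                chloride = 98, bicarbonate = 10, pco2 = 23,
                beta_hydroxybutyrate = 5.5, creatinine = 110,
                volume_deficit = 3000, heart_rate = 110, systolic_bp = 94,
                diastolic_bp = 64, respiratory_rate = 27.2,
                temperature = 38.5, ...)
}

test_scenario <- function(potassium = 3.2, coefficients = test_coeffs(),
                          precipitating_cause = "infection", ...) {
  scenario(id = "test_case", title = "deterministic test case",
           difficulty = 3, narrative = "synthetic fixture",
           precipitating_cause = precipitating_cause,
           initial_state = test_state(potassium = potassium),
           coefficients = coefficients, ...)
}

random_orders <- function() {
  active_orders(
    insulin_rate = stats::runif(1, 0, 0.3),
    fluid_type = sample(c("NS", "half-NS", "D5W", "none"), 1),
    fluid_rate = stats::runif(1, 0, 2000),
    kcl_rate = stats::runif(1, 0, 40),
    bicarbonate_given = stats::runif(1) < 0.2,
    antibiotics = stats::runif(1) < 0.2
  )
}

random_state <- function() {
  patient_state(glucose = stats::runif(1, 3, 80),
                potassium = stats::runif(1, 1.6, 8),
                sodium = stats::runif(1, 115, 170),
                chloride = stats::runif(1, 80, 130),
                bicarbonate = stats::runif(1, 2, 40),
                pco2 = stats::runif(1, 12, 90),
                beta_hydroxybutyrate = stats::runif(1, 0, 20),
                creatinine = stats::runif(1, 40, 900),
                volume_deficit = stats::runif(1, 0, 9000),
                heart_rate = stats::runif(1, 40, 180),
                systolic_bp = stats::runif(1, 60, 200),
                diastolic_bp = stats::runif(1, 30, 120),
                respiratory_rate = stats::runif(1, 8, 50),
                temperature = stats::runif(1, 34, 41))
}

state_vec <- function(state) unlist(state[dkasim:::.state_channels])

expert_log <- function(scn, seed = 1) {
  generate_sessions(policy_profile("expert", action_prob = 1,
                                   error_prob = 0), scn, 1, seed = seed)[[1]]
}

idle_log <- function(scn, seed = 1) {
  generate_sessions(policy_profile("novice", action_prob = 0,
                                   error_prob = 0), scn, 1, seed = seed)[[1]]
}
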