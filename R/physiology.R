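# Discrete-time linear physiology engine. The patient state advances on a
# 1-minute internal tick; coarser advances iterate ticks so that an advance of
# 10 minutes is bit-for-bit identical to two advances of 5.

.state_channels <- c(
  "time_min", "glucose", "potassium", "sodium", "chloride", "bicarbonate",
  "pco2", "ph", "beta_hydroxybutyrate", "creatinine", "volume_deficit",
  "heart_rate", "systolic_bp", "diastolic_bp", "respiratory_rate",
  "temperature"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a patient state
#'
#' A snapshot of the simulated patient's labs, vitals and volume status at one
#' time point. pH is always derived from bicarbonate and pCO2 via
#' Henderson-Hasselbalch, and mental status is an ordinal function of pH and
#' effective osmolality, so every view of the patient is internally
#' consistent.
#'
#' @param glucose plasma glucose, mmol/L
#' @param potassium serum potassium, mmol/L
#' @param sodium serum sodium, mmol/L
#' @param chloride serum chloride, mmol/L
#' @param bicarbonate serum bicarbonate, mmol/L
#' @param pco2 arterial pCO2, mmHg
#' @param beta_hydroxybutyrate serum beta-hydroxybutyrate, mmol/L
#' @param creatinine serum creatinine, umol/L
#' @param volume_deficit estimated total body water deficit, mL
#' @param heart_rate beats/min
#' @param systolic_bp,diastolic_bp mmHg
#' @param respiratory_rate breaths/min
#' @param temperature degrees Celsius
#' @param time_min minutes since case start
#' @return an object of class `dka_patient_state`
#' @export
patient_state <- function(glucose, potassium, sodium, chloride, bicarbonate,
                          pco2, beta_hydroxybutyrate, creatinine,
                          volume_deficit, heart_rate, systolic_bp,
                          diastolic_bp, respiratory_rate, temperature,
                          time_min = 0) {
  vec <- c(
    time_min = time_min, glucose = glucose, potassium = potassium,
    sodium = sodium, chloride = chloride, bicarbonate = bicarbonate,
    pco2 = pco2, ph = NA_real_,
    beta_hydroxybutyrate = beta_hydroxybutyrate, creatinine = creatinine,
    volume_deficit = volume_deficit, heart_rate = heart_rate,
    systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
    respiratory_rate = respiratory_rate, temperature = temperature
  )
  vec[["ph"]] <- .henderson_hasselbalch(bicarbonate, pco2)
  .validate_state_vec(vec)
  .state_from_vec(vec)
}

.henderson_hasselbalch <- function(hco3, pco2) {
  if (any(hco3 <= 0) || any(pco2 <= 0)) {
    stop("unphysiological state: bicarbonate and pCO2 must be positive",
         call. = FALSE)
  }
  min(max(6.1 + log10(hco3 / (0.03 * pco2)), 6.5), 8.0)
}

.validate_state_vec <- function(vec) {
  conc <- vec[c("glucose", "potassium", "sodium", "chloride", "bicarbonate",
                "pco2", "beta_hydroxybutyrate", "creatinine")]
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (vec[["ph"]] < 6.5 || vec[["ph"]] > 8.0)
    stop("ph out of admissible range [6.5, 8.0]", call. = FALSE)
  if (vec[["heart_rate"]] < 20 || vec[["heart_rate"]] > 220)
    stop("heart_rate out of admissible range [20, 220]", call. = FALSE)
  if (vec[["systolic_bp"]] < 40 || vec[["systolic_bp"]] > 250)
    stop("systolic_bp out of admissible range [40, 250]", call. = FALSE)
  if (vec[["volume_deficit"]] < 0)
    stop("volume_deficit must be non-negative", call. = FALSE)
  invisible(vec)
}

.state_from_vec <- function(vec) {
  out <- as.list(vec[.state_channels])
  out$mental_status <- .mental_status(vec)
  class(out) <- "dka_patient_state"
  out
}

.state_to_vec <- function(state) {
  unlist(state[.state_channels])
}

.mental_status <- function(vec) {
  eff_osm <- 2 * vec[["sodium"]] + vec[["glucose"]]
  ph <- vec[["ph"]]
  if (ph < 7.0 || eff_osm >= 340) "obtunded"
  else if (ph < 7.15 || eff_osm >= 320) "drowsy"
  else "alert"
}

#' @export
print.dka_patient_state <- function(x, ...) {
  cat(sprintf("<patient state at t = %d min>\n", as.integer(x$time_min)))
  cat(sprintf("  glucose %.1f  K %.2f  Na %.0f  Cl %.0f  HCO3 %.1f mmol/L\n",
              x$glucose, x$potassium, x$sodium, x$chloride, x$bicarbonate))
  cat(sprintf("  pH %.2f  pCO2 %.0f mmHg  BHB %.1f mmol/L  Cr %.0f umol/L\n",
              x$ph, x$pco2, x$beta_hydroxybutyrate, x$creatinine))
  cat(sprintf("  deficit %.0f mL  HR %.0f  BP %.0f/%.0f  RR %.0f  T %.1f C  [%s]\n",
              x$volume_deficit, x$heart_rate, x$systolic_bp, x$diastolic_bp,
              x$respiratory_rate, x$temperature, x$mental_status))
  invisible(x)
}

#' Linear dynamics coefficients
#'
#' Per-channel untreated drift rates and treatment response slopes for the
#' linear state update, plus saturation floors/ceilings. All rate coefficients
#' are per hour; the engine divides by 60 at each 1-minute tick. Defaults
#' reproduce guideline-typical trajectories: glucose falls ~3 mmol/L/h on an
#' insulin infusion of 0.1 units/kg/h, potassium falls ~0.4 mmol/L/h under
#' insulin without replacement.
#'
#' @param glucose_drift untreated glucose rise, mmol/L/h
#' @param insulin_glucose glucose slope, mmol/L/h per unit/kg/h of insulin
#'   (must be negative)
#' @param d5w_glucose glucose slope, mmol/L/h per mL/h of dextrose-containing
#'   fluid
#' @param potassium_drift untreated potassium drift, mmol/L/h
#' @param insulin_potassium intracellular potassium shift while any insulin
#'   infusion runs, mmol/L/h (negative)
#' @param kcl_potassium potassium rise per mmol of KCl infused, mmol/L per
#'   mmol (must be positive)
#' @param sodium_drift,ns_sodium,chloride_drift,ns_chloride sodium/chloride
#'   drifts (mmol/L/h) and isotonic-saline correction slopes (mmol/L/h per
#'   mL/h; half-normal saline contributes half weight)
#' @param bicarb_drift untreated bicarbonate fall, mmol/L/h
#' @param insulin_bicarb bicarbonate recovery, mmol/L/h per unit/kg/h
#' @param bicarb_infusion bicarbonate rise while a bicarbonate infusion runs,
#'   mmol/L/h
#' @param bhb_drift,insulin_bhb ketone (beta-hydroxybutyrate) drift and
#'   insulin clearance slopes, mmol/L/h (per unit/kg/h for the latter)
#' @param creat_deficit creatinine rise per litre of volume deficit, umol/L/h
#'   per L
#' @param creat_fluid creatinine slope per mL/h of fluids, umol/L/h per mL/h
#' @param deficit_drift ongoing losses without fluids, mL/h
#' @param fluid_retention fraction of infused volume retained (fluid slope on
#'   the deficit is `-fluid_retention`, necessarily negative)
#' @param resp_comp fraction per hour by which pCO2 relaxes toward the
#'   expected respiratory compensation (Winter's formula)
#' @param resp_offset persistent offset, mmHg, from the Winter's target
#'   (negative for a concurrent primary respiratory alkalosis)
#' @param hr_baseline,hr_per_ml heart rate at zero deficit (bpm) and gain per
#'   mL of deficit (positive)
#' @param sbp_baseline,sbp_per_ml,dbp_baseline,dbp_per_ml blood-pressure
#'   baselines (mmHg) and per-mL gains (negative)
#' @param rr_baseline,rr_per_hco3 respiratory rate at normal bicarbonate and
#'   Kussmaul gain per mmol/L of bicarbonate below 24
#' @param abx_temp cooling rate, degrees C/h, while antibiotics run and the
#'   patient is febrile
#' @param floors,ceilings named numeric vectors of per-channel saturation
#'   bounds; entries override the defaults
#' @return object of class `dka_coefficients`
#' @export
dka_coefficients <- function(glucose_drift = 1.0, insulin_glucose = -30,
                             d5w_glucose = 0.01, potassium_drift = 0,
                             insulin_potassium = -0.4, kcl_potassium = 0.015,
                             sodium_drift = -0.2, ns_sodium = 0.0008,
                             chloride_drift = 0, ns_chloride = 0.0015,
                             bicarb_drift = -0.6, insulin_bicarb = 8,
                             bicarb_infusion = 2.0, bhb_drift = 0.25,
                             insulin_bhb = -8, creat_deficit = 1.0,
                             creat_fluid = -0.004, deficit_drift = 60,
                             fluid_retention = 0.75, resp_comp = 0.5,
                             resp_offset = 0,
                             hr_baseline = 80, hr_per_ml = 0.01,
                             sbp_baseline = 118, sbp_per_ml = -0.008,
                             dbp_baseline = 76, dbp_per_ml = -0.004,
                             rr_baseline = 16, rr_per_hco3 = 0.8,
                             abx_temp = -0.2,
                             floors = NULL, ceilings = NULL) {
  cf <- list(
    glucose_drift = glucose_drift, insulin_glucose = insulin_glucose,
    d5w_glucose = d5w_glucose, potassium_drift = potassium_drift,
    insulin_potassium = insulin_potassium, kcl_potassium = kcl_potassium,
    sodium_drift = sodium_drift, ns_sodium = ns_sodium,
    chloride_drift = chloride_drift, ns_chloride = ns_chloride,
    bicarb_drift = bicarb_drift, insulin_bicarb = insulin_bicarb,
    bicarb_infusion = bicarb_infusion, bhb_drift = bhb_drift,
    insulin_bhb = insulin_bhb, creat_deficit = creat_deficit,
    creat_fluid = creat_fluid, deficit_drift = deficit_drift,
    fluid_retention = fluid_retention, resp_comp = resp_comp,
    resp_offset = resp_offset,
    hr_baseline = hr_baseline, hr_per_ml = hr_per_ml,
    sbp_baseline = sbp_baseline, sbp_per_ml = sbp_per_ml,
    dbp_baseline = dbp_baseline, dbp_per_ml = dbp_per_ml,
    rr_baseline = rr_baseline, rr_per_hco3 = rr_per_hco3,
    abx_temp = abx_temp
  )
  if (insulin_glucose >= 0)
    stop("insulin slope on glucose must be negative", call. = FALSE)
  if (kcl_potassium <= 0)
    stop("KCl slope on potassium must be positive", call. = FALSE)
  if (fluid_retention <= 0)
    stop("fluid slope on volume deficit must be negative (retention > 0)",
         call. = FALSE)
  if (insulin_potassium > 0)
    stop("insulin slope on potassium must be non-positive", call. = FALSE)
  def_floors <- c(glucose = 2.0, potassium = 1.5, sodium = 110, chloride = 70,
                  bicarbonate = 1, pco2 = 10, beta_hydroxybutyrate = 0,
                  creatinine = 30, volume_deficit = 0, heart_rate = 20,
                  systolic_bp = 40, diastolic_bp = 20, respiratory_rate = 6,
                  temperature = 32)
  def_ceils <- c(glucose = 120, potassium = 9, sodium = 180, chloride = 140,
                 bicarbonate = 45, pco2 = 120, beta_hydroxybutyrate = 25,
                 creatinine = 1500, volume_deficit = 12000, heart_rate = 220,
                 systolic_bp = 250, diastolic_bp = 150, respiratory_rate = 60,
                 temperature = 42)
  if (!is.null(floors)) def_floors[names(floors)] <- floors
  if (!is.null(ceilings)) def_ceils[names(ceilings)] <- ceilings
  cf$floors <- def_floors
  cf$ceilings <- def_ceils
  class(cf) <- "dka_coefficients"
  cf
}

#' Active treatment orders
#'
#' The set of orders currently running against the patient: at most one fluid
#' at a time, an insulin infusion rate, a KCl infusion rate, and boolean
#' flags for a bicarbonate infusion and antibiotics.
#'
#' @param insulin_rate units/kg/h, >= 0
#' @param fluid_type one of "NS", "half-NS", "D5W", "none"
#' @param fluid_rate mL/h, >= 0 (ignored when `fluid_type` is "none")
#' @param kcl_rate mmol/h, >= 0
#' @param bicarbonate_given logical, bicarbonate infusion running
#' @param antibiotics logical, antibiotics running
#' @return object of class `dka_orders`
#' @export
active_orders <- function(insulin_rate = 0, fluid_type = "none",
                          fluid_rate = 0, kcl_rate = 0,
                          bicarbonate_given = FALSE, antibiotics = FALSE) {
  fluid_type <- as.character(fluid_type)
  if (!fluid_type %in% c("NS", "half-NS", "D5W", "none"))
    stop("unknown fluid type: ", fluid_type, call. = FALSE)
  if (insulin_rate < 0 || fluid_rate < 0 || kcl_rate < 0)
    stop("order rates must be non-negative", call. = FALSE)
  structure(list(insulin_rate = insulin_rate, fluid_type = fluid_type,
                 fluid_rate = if (fluid_type == "none") 0 else fluid_rate,
                 kcl_rate = kcl_rate,
                 bicarbonate_given = isTRUE(bicarbonate_given),
                 antibiotics = isTRUE(antibiotics)),
            class = "dka_orders")
}

# one 1-minute tick on the raw state vector; pure, no allocation beyond vec
.tick <- function(vec, orders, cf) {
  ins <- orders$insulin_rate
  fl <- if (orders$fluid_type == "none") 0 else orders$fluid_rate
  dex <- if (orders$fluid_type == "D5W") fl else 0
  nsw <- switch(orders$fluid_type, NS = fl, `half-NS` = 0.5 * fl, 0)

  deficit <- vec[["volume_deficit"]]
  d <- c(
    glucose = cf$glucose_drift + cf$insulin_glucose * ins +
      cf$d5w_glucose * dex,
    potassium = cf$potassium_drift + (ins > 0) * cf$insulin_potassium +
      cf$kcl_potassium * orders$kcl_rate,
    sodium = cf$sodium_drift + cf$ns_sodium * nsw,
    chloride = cf$chloride_drift + cf$ns_chloride * nsw,
    bicarbonate = cf$bicarb_drift + cf$insulin_bicarb * ins +
      cf$bicarb_infusion * orders$bicarbonate_given,
    beta_hydroxybutyrate = cf$bhb_drift + cf$insulin_bhb * ins,
    creatinine = cf$creat_deficit * deficit / 1000 + cf$creat_fluid * fl,
    volume_deficit = cf$deficit_drift - cf$fluid_retention * fl,
    temperature = if (orders$antibiotics && vec[["temperature"]] > 37.1)
      cf$abx_temp else 0
  )
  for (ch in names(d)) {
    vec[[ch]] <- min(max(vec[[ch]] + d[[ch]] / 60, cf$floors[[ch]]),
                     cf$ceilings[[ch]])
  }
  # respiratory compensation relaxes pCO2 toward the Winter's-formula target
  target <- 1.5 * vec[["bicarbonate"]] + 8 + cf$resp_offset
  vec[["pco2"]] <- min(max(
    vec[["pco2"]] + cf$resp_comp * (target - vec[["pco2"]]) / 60,
    cf$floors[["pco2"]]), cf$ceilings[["pco2"]])
  vec[["ph"]] <- .henderson_hasselbalch(vec[["bicarbonate"]], vec[["pco2"]])
  vec <- .apply_vitals(vec, cf)
  vec[["time_min"]] <- vec[["time_min"]] + 1
  vec
}

.apply_vitals <- function(vec, cf) {
  deficit <- vec[["volume_deficit"]]
  hco3_gap <- max(0, 24 - vec[["bicarbonate"]])
  clamp <- function(ch, x) min(max(x, cf$floors[[ch]]), cf$ceilings[[ch]])
  vec[["heart_rate"]] <- clamp("heart_rate",
                               cf$hr_baseline + cf$hr_per_ml * deficit)
  vec[["systolic_bp"]] <- clamp("systolic_bp",
                                cf$sbp_baseline + cf$sbp_per_ml * deficit)
  vec[["diastolic_bp"]] <- clamp("diastolic_bp",
                                 cf$dbp_baseline + cf$dbp_per_ml * deficit)
  vec[["respiratory_rate"]] <- clamp("respiratory_rate",
                                     cf$rr_baseline + cf$rr_per_hco3 * hco3_gap)
  vec
}

#' Advance the patient state
#'
#' Applies the linear state update over `dt` minutes of simulated time under
#' a fixed set of active orders. The update is computed on an internal
#' 1-minute tick, so `step_state(s, o, c, 10)` is exactly
#' `step_state(step_state(s, o, c, 5), o, c, 5)` — the result does not depend
#' on how an interval is partitioned.
#'
#' @param state a `dka_patient_state`
#' @param orders a `dka_orders`
#' @param coeffs a `dka_coefficients`
#' @param dt minutes to advance; a non-negative integer
#' @return the state at `state$time_min + dt`
#' @export
step_state <- function(state, orders, coeffs, dt) {
  stopifnot(inherits(state, "dka_patient_state"),
            inherits(orders, "dka_orders"),
            inherits(coeffs, "dka_coefficients"))
  if (length(dt) != 1 || is.na(dt) || dt < 0 || dt != round(dt))
    stop("dt must be a non-negative whole number of minutes", call. = FALSE)
  if (dt == 0) return(state)
  vec <- .state_to_vec(state)
  for (i in seq_len(dt)) vec <- .tick(vec, orders, coeffs)
  .state_from_vec(vec)
}

#' Standard derived laboratory quantities
#'
#' Anion gap, effective osmolality and pH from their standard clinical
#' formulas: `AG = Na - (Cl + HCO3)`, `Eosm = 2*Na + glucose`,
#' `pH = 6.1 + log10(HCO3 / (0.03 * pCO2))`.
#'
#' @param state a `dka_patient_state`
#' @return list with `anion_gap` (mmol/L), `effective_osmolality` (mmol/kg),
#'   `ph`
#' @export
derived_labs <- function(state) {
  if (state$bicarbonate <= 0 || state$pco2 <= 0)
    stop("unphysiological state: bicarbonate and pCO2 must be positive",
         call. = FALSE)
  list(
    anion_gap = state$sodium - (state$chloride + state$bicarbonate),
    effective_osmolality = 2 * state$sodium + state$glucose,
    ph = 6.1 + log10(state$bicarbonate / (0.03 * state$pco2))
  )
}

#' Vital signs derived from volume status and acid-base state
#'
#' Heart rate and blood pressures are affine in the volume deficit (HR rises,
#' BP falls as the deficit grows); respiratory rate is affine in the
#' bicarbonate deficit (Kussmaul breathing). Every view of the patient calls
#' this same function, so displayed vitals are consistent everywhere.
#'
#' @param state a `dka_patient_state`
#' @param coeffs a `dka_coefficients`
#' @return list with `heart_rate`, `systolic_bp`, `diastolic_bp`,
#'   `respiratory_rate`, `temperature`
#' @export
vital_signs <- function(state, coeffs) {
  if (state$volume_deficit < 0)
    stop("volume_deficit must be non-negative", call. = FALSE)
  vec <- .apply_vitals(.state_to_vec(state), coeffs)
  list(heart_rate = vec[["heart_rate"]],
       systolic_bp = vec[["systolic_bp"]],
       diastolic_bp = vec[["diastolic_bp"]],
       respiratory_rate = vec[["respiratory_rate"]],
       temperature = vec[["temperature"]])
}
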