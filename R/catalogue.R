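# Preset action catalogue: every orderable action, its category, and (for
# investigations) the default result latency in minutes.

.action_catalogue <- data.frame(
  kind = c(
    "take_history", "examine_patient", "assess_volume_status",
    "assess_mental_status",
    "order_abg", "order_chemistry", "order_glucose_poc", "order_ketones",
    "order_cbc", "order_blood_culture", "order_urinalysis", "order_cxr",
    "order_ecg",
    "start_insulin_infusion", "stop_insulin_infusion", "start_fluids",
    "stop_fluids", "start_kcl", "stop_kcl", "give_bicarbonate",
    "stop_bicarbonate", "give_antibiotics",
    "talk_to_nurse", "order_vitals"
  ),
  category = c(
    rep("clinical_assessment", 4),
    rep("investigation", 9),
    rep("management", 9),
    rep("nursing", 2)
  ),
  latency_min = c(
    rep(0, 4),
    10, 30, 5, 30, 45, 60, 45, 30, 15,
    rep(0, 9),
    0, 0
  ),
  stringsAsFactors = FALSE
)

#' The preset action catalogue
#'
#' Every action a learner can submit, grouped into the four preset categories
#' (clinical assessment, investigations, management, nursing), with default
#' result latencies for investigations.
#'
#' @return data.frame with columns `kind`, `category`, `latency_min`
#' @export
action_catalogue <- function() .action_catalogue

.catalogue_entry <- function(kind) {
  i <- match(kind, .action_catalogue$kind)
  if (is.na(i)) stop("unknown action kind: ", kind, call. = FALSE)
  .action_catalogue[i, ]
}

.investigation_kinds <- function() {
  .action_catalogue$kind[.action_catalogue$category == "investigation"]
}

# lab panels returned when an investigation result matures; kinds not listed
# here fall back to scenario-authored static findings
.result_panels <- list(
  order_abg = c("ph", "pco2", "bicarbonate"),
  order_chemistry = c("sodium", "potassium", "chloride", "bicarbonate",
                      "glucose", "creatinine"),
  order_glucose_poc = "glucose",
  order_ketones = "beta_hydroxybutyrate"
)

.snapshot_result <- function(kind, state, scenario) {
  panel <- .result_panels[[kind]]
  if (!is.null(panel)) {
    vals <- state[panel]
    if (kind == "order_chemistry") {
      dl <- derived_labs(state)
      vals$anion_gap <- dl$anion_gap
      vals$effective_osmolality <- dl$effective_osmolality
    }
    return(vals)
  }
  scenario$static_results[[kind]] %||% list(report = "no abnormality detected")
}
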