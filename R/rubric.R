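# The 18-item, 7-domain performance rubric. Item content follows the seven
# guideline management priorities (potassium, volume, acidosis, hyperglycemia,
# precipitating cause, organization of care, monitoring); each item lists
# declarative required-action specs and optional critical-error predicates,
# and maps percent-correct to a 3-point score.

.scoring_domains <- c("potassium_deficiency", "volume_fluid_replacement",
                      "acidosis", "hyperglycemia", "precipitating_cause",
                      "organization_of_care", "monitoring")

#' Scoring domains of the rubric
#' @return character vector of the seven management-priority domains
#' @export
scoring_domains <- function() .scoring_domains

# --- declarative requirement specs -----------------------------------------
# type "action_by":       kind performed at time <= by_min (NULL = any time)
# type "action_before":   kind performed, and before the first `before` action
#                         if that action ever occurs
# type "action_count":    >= n occurrences of kind (within by_min if given)
# type "action_any":      at least one of `kinds` performed
# type "param_window":    first occurrence of kind has payload[[field]] in
#                         [lo, hi]
# type "param_equals":    first occurrence of kind has payload[[field]] equal
#                         to `value`
# type "recheck":         >= 1 occurrence of kind within `window_min` minutes
#                         after the first `after` action (fails if `after`
#                         never happens)
# type "sustained":       `start` performed and no `stop` within the first
#                         `min_duration` minutes after it
# type "cond_action":     condition `channel op value` becomes true at some
#                         time t in the trace and kind is performed within
#                         [t, t + window_min]; not applicable (dropped from
#                         the denominator) if the condition never holds
req <- function(type, ...) c(list(type = type), list(...))

# critical-error predicate: an event of `kind` at a time where
# `channel op value` holds in the state trace, unless the named order
# (`unless`, e.g. "kcl") is already active at that time
crit <- function(kind, channel, op, value, unless = NULL, tag) {
  list(kind = kind, channel = channel, op = op, value = value,
       unless = unless, tag = tag)
}

#' Construct a rubric performance item
#'
#' @param id integer item id (1-18)
#' @param domain one of [scoring_domains()]
#' @param label short description of the scored behaviour
#' @param required list of declarative required-action specs
#' @param critical list of critical-error predicates (may be empty)
#' @param pct_full,pct_partial percent-correct thresholds for scores 3 and 2
#' @return object of class `dka_item`
#' @export
performance_item <- function(id, domain, label, required, critical = list(),
                             pct_full = 80, pct_partial = 50) {
  if (!domain %in% .scoring_domains)
    stop("unknown scoring domain: ", domain, call. = FALSE)
  if (!(pct_partial >= 0 && pct_partial < pct_full && pct_full <= 100))
    stop("need 0 <= pct_partial < pct_full <= 100", call. = FALSE)
  if (length(required) == 0)
    stop("an item needs at least one required action", call. = FALSE)
  structure(list(id = as.integer(id), domain = domain, label = label,
                 required = required, critical = critical,
                 pct_full = pct_full, pct_partial = pct_partial),
            class = "dka_item")
}

#' The default 18-item rubric
#'
#' Two to three items per domain, reconstructed from the seven guideline
#' management priorities. The precipitating-cause items adapt to the
#' scenario's cause (antibiotics are required only when the cause is an
#' infection).
#'
#' @param precipitating_cause the scenario's cause; one of "infection",
#'   "insulin_omission", "new_onset", "medication", "cardiovascular",
#'   "unknown"
#' @return list of 18 `dka_item` objects
#' @export
default_rubric <- function(precipitating_cause = "new_onset") {
  cause_treat <- if (identical(precipitating_cause, "infection")) {
    req("action_by", kind = "give_antibiotics", by_min = 120)
  } else {
    req("action_by", kind = "examine_patient", by_min = 45)
  }
  list(
    performance_item(1L, "potassium_deficiency",
      "Potassium checked before starting insulin",
      required = list(req("action_before", kind = "order_chemistry",
                          before = "start_insulin_infusion")),
      critical = list(crit("start_insulin_infusion", "potassium", "<", 3.3,
                           unless = "kcl", tag = "insulin_low_k"))),
    performance_item(2L, "potassium_deficiency",
      "Potassium replacement started promptly at an adequate rate",
      required = list(req("action_by", kind = "start_kcl", by_min = 90),
                      req("param_window", kind = "start_kcl", field = "rate",
                          lo = 10, hi = 40))),
    performance_item(3L, "potassium_deficiency",
      "Potassium rechecked within two hours of starting insulin",
      required = list(req("recheck", kind = "order_chemistry",
                          after = "start_insulin_infusion",
                          window_min = 120))),
    performance_item(4L, "volume_fluid_replacement",
      "Isotonic fluids started promptly",
      required = list(req("action_by", kind = "start_fluids", by_min = 15),
                      req("param_equals", kind = "start_fluids",
                          field = "fluid_type", value = "NS"))),
    performance_item(5L, "volume_fluid_replacement",
      "Adequate initial fluid rate",
      required = list(req("param_window", kind = "start_fluids",
                          field = "rate", lo = 500, hi = 2000))),
    performance_item(6L, "volume_fluid_replacement",
      "Volume status assessed clinically",
      required = list(req("action_by", kind = "assess_volume_status",
                          by_min = 60))),
    performance_item(7L, "acidosis",
      "Arterial blood gas obtained early",
      required = list(req("action_by", kind = "order_abg", by_min = 20))),
    performance_item(8L, "acidosis",
      "Acid-base status reassessed during treatment",
      required = list(req("action_count", kind = "order_abg", n = 2,
                          by_min = 240))),
    performance_item(9L, "acidosis",
      "Ketonaemia measured; bicarbonate reserved for severe acidaemia",
      required = list(req("action_by", kind = "order_ketones", by_min = 60)),
      critical = list(crit("give_bicarbonate", "ph", ">=", 7.0,
                           tag = "bicarb_mild_acidosis"))),
    performance_item(10L, "hyperglycemia",
      "Insulin infusion started within the first hour",
      required = list(req("action_by", kind = "start_insulin_infusion",
                          by_min = 60))),
    performance_item(11L, "hyperglycemia",
      "Insulin infusion dosed in the guideline window",
      required = list(req("param_window", kind = "start_insulin_infusion",
                          field = "rate", lo = 0.05, hi = 0.15))),
    performance_item(12L, "hyperglycemia",
      "Insulin infusion maintained until ketoacidosis clears",
      required = list(req("sustained", start = "start_insulin_infusion",
                          stop = "stop_insulin_infusion",
                          min_duration = 180))),
    performance_item(13L, "precipitating_cause",
      "History and septic screen for a precipitating cause",
      required = list(req("action_by", kind = "take_history", by_min = 30),
                      req("action_any",
                          kinds = c("order_blood_culture", "order_urinalysis",
                                    "order_cxr")))),
    performance_item(14L, "precipitating_cause",
      "Precipitating cause addressed",
      required = list(cause_treat)),
    performance_item(15L, "organization_of_care",
      "Nursing staff engaged early",
      required = list(req("action_by", kind = "talk_to_nurse", by_min = 30))),
    performance_item(16L, "organization_of_care",
      "Ongoing communication with the nurse",
      required = list(req("action_count", kind = "talk_to_nurse", n = 2))),
    performance_item(17L, "monitoring",
      "Vital signs monitored serially",
      required = list(req("action_count", kind = "order_vitals", n = 3))),
    performance_item(18L, "monitoring",
      "Glucose followed with serial point-of-care checks",
      required = list(req("action_count", kind = "order_glucose_poc",
                          n = 3)))
  )
}

.validate_rubric <- function(rubric) {
  if (length(rubric) != 18)
    stop("rubric must define exactly 18 performance items, got ",
         length(rubric), call. = FALSE)
  ids <- vapply(rubric, function(it) it$id, integer(1))
  if (!identical(sort(ids), 1:18))
    stop("rubric item ids must be exactly 1..18", call. = FALSE)
  domains <- vapply(rubric, function(it) it$domain, character(1))
  missing <- setdiff(.scoring_domains, domains)
  if (length(missing))
    stop("rubric leaves scoring domain(s) empty: ",
         paste(missing, collapse = ", "), call. = FALSE)
  kinds_used <- unlist(lapply(rubric, function(it) {
    c(unlist(lapply(it$required, function(r)
        c(r$kind, r$kinds, r$before, r$after, r$start, r$stop))),
      vapply(it$critical, function(cr) cr$kind, character(1)))
  }))
  unknown <- setdiff(kinds_used, .action_catalogue$kind)
  if (length(unknown))
    stop("rubric references unknown action(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(rubric)
}

# --- default in-session hint rules -----------------------------------------

#' Construct a hint rule
#'
#' Hint triggers are pure predicates over the session log and state trace.
#' Two trigger types exist: `missing_action_by` fires once simulated time
#' passes `by_min` without the named action (optionally only while a state
#' condition holds); `action_while_state` fires when the named action is
#' performed while the condition holds (a post-hoc warning).
#'
#' @param id unique rule id (character)
#' @param text hint text shown to the learner
#' @param rationale why the action matters
#' @param trigger list with `type` and its parameters
#' @param once logical; fire at most once per session
#' @param covers character vector of critical-error tags this hint addresses
#' @return object of class `dka_hint_rule`
#' @export
hint_rule <- function(id, text, rationale, trigger, once = TRUE,
                      covers = character()) {
  stopifnot(trigger$type %in% c("missing_action_by", "action_while_state"))
  structure(list(id = id, text = text, rationale = rationale,
                 trigger = trigger, once = isTRUE(once), covers = covers),
            class = "dka_hint_rule")
}

#' The default hint-rule set
#' @return list of `dka_hint_rule`
#' @export
default_hint_rules <- function() {
  list(
    hint_rule("hint_abg",
      "Consider ordering an arterial blood gas.",
      paste("The ABG quantifies the severity of the metabolic acidosis and",
            "guides therapy; it should be obtained early in suspected DKA."),
      trigger = list(type = "missing_action_by", kind = "order_abg",
                     by_min = 20)),
    hint_rule("hint_fluids",
      "The patient appears volume deplete; consider intravenous fluids.",
      "Aggressive isotonic fluid resuscitation is the first priority in DKA.",
      trigger = list(type = "missing_action_by", kind = "start_fluids",
                     by_min = 20)),
    hint_rule("hint_potassium",
      "Serum potassium is falling; consider aggressive potassium replacement.",
      paste("Insulin shifts potassium into cells; without replacement the",
            "serum potassium will fall and risks life-threatening",
            "hypokalaemia."),
      trigger = list(type = "missing_action_by", kind = "start_kcl",
                     by_min = 90, channel = "potassium", op = "<",
                     value = 3.5),
      covers = "insulin_low_k"),
    hint_rule("hint_insulin",
      "Consider an intravenous insulin infusion.",
      "Insulin suppresses ketogenesis and corrects the hyperglycemia.",
      trigger = list(type = "missing_action_by",
                     kind = "start_insulin_infusion", by_min = 60)),
    hint_rule("hint_bicarb",
      "Bicarbonate is rarely indicated unless acidaemia is severe (pH < 7.0).",
      paste("Bicarbonate in mild-to-moderate DKA can worsen hypokalaemia and",
            "intracellular acidosis; fluids and insulin correct the",
            "acidosis."),
      trigger = list(type = "action_while_state", kind = "give_bicarbonate",
                     channel = "ph", op = ">=", value = 7.0),
      covers = "bicarb_mild_acidosis"),
    hint_rule("hint_insulin_low_k",
      "Hold or cover insulin: serum potassium is below 3.3 mmol/L.",
      paste("Starting insulin with uncorrected severe hypokalaemia can",
            "precipitate arrhythmia; replace potassium first."),
      trigger = list(type = "action_while_state",
                     kind = "start_insulin_infusion", channel = "potassium",
                     op = "<", value = 3.3),
      covers = "insulin_low_k")
  )
}

.op_fun <- function(op) switch(op,
  "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`, "==" = `==`,
  stop("unknown comparison operator: ", op, call. = FALSE))

.validate_hint_rules <- function(rules, rubric) {
  ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate hint rule ids", call. = FALSE)
  for (r in rules) {
    if (!r$trigger$kind %in% .action_catalogue$kind)
      stop("hint rule ", r$id, " references unknown action ",
           r$trigger$kind, call. = FALSE)
  }
  # coverage: every rubric critical-error tag has at least one hint rule
  tags <- unlist(lapply(rubric, function(it)
    vapply(it$critical, function(cr) cr$tag, character(1))))
  covered <- unlist(lapply(rules, function(r) r$covers))
  missing <- setdiff(tags, covered)
  if (length(missing))
    stop("critical error(s) without an associated hint rule: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(rules)
}
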