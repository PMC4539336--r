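# Scenario definition, validation, YAML (de)serialization, and the six
# built-in contrasting cases.

.scenario_fields <- c("id", "title", "difficulty", "narrative",
                      "precipitating_cause", "special_feature",
                      "initial_state", "coefficients", "rubric",
                      "hint_rules", "lab_latencies", "static_results")

.causes <- c("infection", "insulin_omission", "new_onset", "medication",
             "cardiovascular", "unknown")

#' Construct a scenario
#'
#' One clinical case: initial patient state, dynamics coefficients, the
#' scoring rubric bound to it, hint rules, and per-investigation result
#' latencies.
#'
#' @param id short unique identifier
#' @param title human-readable case title
#' @param difficulty ordinal 1 (easiest) to 5
#' @param narrative presenting vignette text
#' @param precipitating_cause one of infection, insulin_omission, new_onset,
#'   medication, cardiovascular, unknown
#' @param initial_state a `dka_patient_state`
#' @param coefficients a `dka_coefficients`
#' @param special_feature optional tag (e.g.
#'   "hyperosmolar_hyperglycemic_state", "respiratory_alkalosis")
#' @param rubric list of 18 `dka_item`s; defaults to
#'   [default_rubric()] for the case's cause
#' @param hint_rules list of `dka_hint_rule`; defaults to
#'   [default_hint_rules()]
#' @param lab_latencies named list, investigation kind -> minutes; entries
#'   override the catalogue defaults
#' @param static_results named list, investigation kind -> result list, for
#'   investigations not derived from the numeric state (imaging, cultures)
#' @return object of class `dka_scenario`
#' @export
scenario <- function(id, title, difficulty, narrative, precipitating_cause,
                     initial_state, coefficients = dka_coefficients(),
                     special_feature = NULL, rubric = NULL,
                     hint_rules = NULL, lab_latencies = list(),
                     static_results = list()) {
  if (!precipitating_cause %in% .causes)
    stop("unknown precipitating_cause: ", precipitating_cause, call. = FALSE)
  if (!(length(difficulty) == 1 && difficulty %in% 1:5))
    stop("difficulty must be an ordinal in 1..5", call. = FALSE)
  stopifnot(inherits(initial_state, "dka_patient_state"),
            inherits(coefficients, "dka_coefficients"))
  if (is.null(rubric)) rubric <- default_rubric(precipitating_cause)
  if (is.null(hint_rules)) hint_rules <- default_hint_rules()
  .validate_rubric(rubric)
  .validate_hint_rules(hint_rules, rubric)
  lat <- as.list(lab_latencies)
  unknown <- setdiff(names(lat), .investigation_kinds())
  if (length(unknown))
    stop("lab_latencies for unknown investigation(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  inv <- .action_catalogue$category == "investigation"
  full_lat <- as.list(stats::setNames(.action_catalogue$latency_min[inv],
                                      .action_catalogue$kind[inv]))
  full_lat[names(lat)] <- lapply(lat, as.numeric)
  structure(list(id = id, title = title, difficulty = as.integer(difficulty),
                 narrative = narrative,
                 precipitating_cause = precipitating_cause,
                 special_feature = special_feature,
                 initial_state = initial_state, coefficients = coefficients,
                 rubric = rubric, hint_rules = hint_rules,
                 lab_latencies = full_lat,
                 static_results = as.list(static_results)),
            class = "dka_scenario")
}

#' @export
print.dka_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s: %s (difficulty %d/5, cause: %s%s)>\n", x$id,
              x$title, x$difficulty, x$precipitating_cause,
              if (is.null(x$special_feature)) ""
              else paste0(", ", x$special_feature)))
  invisible(x)
}

#' Load a scenario from a YAML file
#'
#' Validation is total: a malformed file yields a diagnostic naming the
#' offending field, never a partially constructed scenario. `rubric`,
#' `hint_rules`, `coefficients` and `lab_latencies` may each be the string
#' `"default"` in the file.
#'
#' @param path path to a scenario YAML file
#' @return a `dka_scenario`
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .scenario_fields)
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  needed <- c("id", "title", "difficulty", "narrative", "precipitating_cause",
              "initial_state")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("scenario file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  state <- tryCatch(do.call(patient_state, raw$initial_state),
                    error = function(e) stop("invalid initial_state: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  cf_spec <- raw$coefficients
  coeffs <- if (is.null(cf_spec) || identical(cf_spec, "default")) {
    dka_coefficients()
  } else {
    if (!is.null(cf_spec$floors)) cf_spec$floors <- unlist(cf_spec$floors)
    if (!is.null(cf_spec$ceilings))
      cf_spec$ceilings <- unlist(cf_spec$ceilings)
    tryCatch(do.call(dka_coefficients, cf_spec),
             error = function(e) stop("invalid coefficients: ",
                                      conditionMessage(e), call. = FALSE))
  }
  rubric <- raw$rubric
  if (is.null(rubric) || identical(rubric, "default")) {
    rubric <- NULL
  } else {
    rubric <- lapply(rubric, .item_from_list)
  }
  hints <- raw$hint_rules
  if (is.null(hints) || identical(hints, "default")) {
    hints <- NULL
  } else {
    hints <- lapply(hints, .hint_from_list)
  }
  scenario(id = raw$id, title = raw$title, difficulty = raw$difficulty,
           narrative = raw$narrative,
           precipitating_cause = raw$precipitating_cause,
           special_feature = raw$special_feature,
           initial_state = state, coefficients = coeffs,
           rubric = rubric, hint_rules = hints,
           lab_latencies = if (identical(raw$lab_latencies, "default"))
             list() else raw$lab_latencies %||% list(),
           static_results = raw$static_results %||% list())
}

.item_from_list <- function(x) {
  needed <- c("id", "domain", "label", "required")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("rubric item missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  crits <- lapply(x$critical %||% list(), function(cr)
    crit(cr$kind, cr$channel, cr$op, cr$value, unless = cr$unless,
         tag = cr$tag))
  performance_item(x$id, x$domain, x$label, required = x$required,
                   critical = crits, pct_full = x$pct_full %||% 80,
                   pct_partial = x$pct_partial %||% 50)
}

.hint_from_list <- function(x) {
  hint_rule(x$id, x$text, x$rationale, trigger = x$trigger,
            once = x$once %||% TRUE,
            covers = as.character(unlist(x$covers %||% character())))
}

#' Save a scenario to a YAML file
#'
#' Writes the fully expanded scenario (rubric, hints and coefficients
#' materialized) so that `load_scenario(save_scenario(s, f))` reproduces `s`.
#'
#' @param scn a `dka_scenario`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "dka_scenario"))
  st <- scn$initial_state
  st <- st[setdiff(.state_channels, "ph")]  # ph is always derived
  cf <- unclass(scn$coefficients)
  cf$floors <- as.list(cf$floors)
  cf$ceilings <- as.list(cf$ceilings)
  out <- list(
    id = scn$id, title = scn$title, difficulty = scn$difficulty,
    narrative = scn$narrative,
    precipitating_cause = scn$precipitating_cause,
    special_feature = scn$special_feature,
    initial_state = st,
    coefficients = cf,
    rubric = lapply(scn$rubric, unclass),
    hint_rules = lapply(scn$hint_rules, unclass),
    lab_latencies = scn$lab_latencies,
    static_results = scn$static_results
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

.builtin_dir <- function() {
  system.file("extdata", "scenarios", package = "dkasim")
}

#' List the built-in scenarios
#'
#' Six contrasting cases of varying difficulty, including an older adult in a
#' hyperosmolar hyperglycemic state and a case with concurrent respiratory
#' alkalosis.
#'
#' @return data.frame with one row per case: `id`, `title`, `difficulty`,
#'   `precipitating_cause`, `special_feature`
#' @export
list_builtin_scenarios <- function() {
  files <- sort(list.files(.builtin_dir(), pattern = "\\.yaml$",
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    s <- load_scenario(f)
    data.frame(id = s$id, title = s$title, difficulty = s$difficulty,
               precipitating_cause = s$precipitating_cause,
               special_feature = s$special_feature %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load a built-in scenario by id
#' @param id one of the ids from [list_builtin_scenarios()]
#' @return a `dka_scenario`
#' @export
builtin_scenario <- function(id) {
  f <- file.path(.builtin_dir(), paste0(id, ".yaml"))
  if (!file.exists(f))
    stop("no built-in scenario with id '", id, "'; see ",
         "list_builtin_scenarios()", call. = FALSE)
  load_scenario(f)
}
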