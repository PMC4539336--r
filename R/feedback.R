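# End-of-run summary report: one section per scoring domain with item
# outcomes, deficiency flags, critical errors and additional reading.
# In-session "Helpful Hints" live in session.R (evaluate_hints); both are
# formative and never alter the score.

.domain_reading <- list(
  potassium_deficiency = paste(
    "Review potassium handling in DKA: total-body depletion despite",
    "normal-range serum values, replacement thresholds, and why insulin",
    "must wait for a potassium above 3.3 mmol/L."),
  volume_fluid_replacement = paste(
    "Review fluid resuscitation in hyperglycemic emergencies: isotonic",
    "saline first, rate targets, and reassessment of volume status."),
  acidosis = paste(
    "Review the biochemistry of ketoacidosis: anion gap, Winter's formula",
    "for expected respiratory compensation, and the narrow indications for",
    "bicarbonate."),
  hyperglycemia = paste(
    "Review insulin infusion therapy: weight-based dosing, glucose",
    "targets, and adding dextrose rather than stopping insulin as glucose",
    "normalizes."),
  precipitating_cause = paste(
    "Review precipitating causes of DKA (infection, insulin omission, new",
    "diagnosis, medications) and the screening investigations for each."),
  organization_of_care = paste(
    "Review team communication in emergencies: closed-loop orders with",
    "nursing staff and clear escalation."),
  monitoring = paste(
    "Review monitoring schedules in DKA: hourly glucose, 2-4 hourly",
    "electrolytes, and continuous or frequent vital signs.")
)

#' Build the end-of-run summary report
#'
#' One section per scoring domain (seven in all), listing each item's
#' outcome, flagging deficiencies (items scoring below 3) and critical
#' errors, and pointing to additional reading for any deficient domain.
#' The report is a deterministic function of the score report, so
#' regenerating it from a replayed log is byte-identical.
#'
#' @param report a `dka_score_report`
#' @param log the scoreable `dka_session_log` the report came from
#' @return object of class `dka_summary_report`
#' @export
summary_report <- function(report, log) {
  stopifnot(inherits(report, "dka_score_report"))
  if (!isTRUE(log$scored))
    .dka_stop("the session was exited without providing the score; no report",
              "dka_unscoreable")
  sections <- lapply(.scoring_domains, function(d) {
    rows <- report$items[report$items$domain == d, , drop = FALSE]
    deficient <- rows$label[rows$score < 3]
    list(domain = d,
         subscore = unname(report$domain_subscores[[d]]),
         max_subscore = 3L * nrow(rows),
         items = lapply(seq_len(nrow(rows)), function(i) list(
           id = rows$id[i], label = rows$label[i],
           percent_correct = rows$percent_correct[i],
           critical_errors = rows$critical_errors[i],
           score = rows$score[i])),
         deficiencies = as.character(deficient),
         additional_reading = if (length(deficient))
           .domain_reading[[d]] else NULL)
  })
  structure(list(scenario_id = log$scenario_id, total = report$total,
                 percent_score = report$percent_score,
                 critical_error_roster = report$critical_error_roster,
                 sections = sections),
            class = "dka_summary_report")
}

#' @export
format.dka_summary_report <- function(x, ...) {
  out <- c(
    sprintf("Summary report - scenario %s", x$scenario_id),
    sprintf("Total score %d/54 (%.1f%%)", x$total, x$percent_score),
    if (length(x$critical_error_roster))
      sprintf("Critical errors: %s",
              paste(x$critical_error_roster, collapse = ", "))
    else "Critical errors: none",
    ""
  )
  for (s in x$sections) {
    out <- c(out, sprintf("[%s] %d/%d", s$domain, s$subscore,
                          s$max_subscore))
    for (it in s$items) {
      out <- c(out, sprintf("  item %2d (%s): %.0f%% correct, %d critical error(s), score %d",
                            it$id, it$label, it$percent_correct,
                            it$critical_errors, it$score))
    }
    if (length(s$deficiencies)) {
      out <- c(out, sprintf("  needs work: %s",
                            paste(s$deficiencies, collapse = "; ")),
               sprintf("  reading: %s", s$additional_reading))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

#' @export
print.dka_summary_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
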