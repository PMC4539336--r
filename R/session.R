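# Interactive session runtime: order entry in the preset categories, result
# latency, learner-driven time advancement, nurse-mediated vitals, hint
# evaluation, event logging and termination semantics. Time is advanced
# explicitly by the learner in 5/10/30/60-minute jumps; there is no wall
# clock, so sessions are fully replay-deterministic.

.advance_increments <- c(5, 10, 30, 60)

.dka_stop <- function(msg, class) {
  stop(structure(class = c(class, "dka_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Start an interactive session
#'
#' @param scn a `dka_scenario`
#' @return a mutable session object (class `dka_session`)
#' @export
start_session <- function(scn) {
  stopifnot(inherits(scn, "dka_scenario"))
  s <- new.env(parent = emptyenv())
  s$scenario <- scn
  s$time <- 0
  s$vec <- .state_to_vec(scn$initial_state)
  s$orders <- active_orders()
  s$pending <- list()
  s$results <- list()
  s$events <- list()
  s$hints_fired <- character()
  s$trace <- list(s$vec)
  s$ended <- FALSE
  s$scored <- NA
  class(s) <- "dka_session"
  s
}

#' @export
print.dka_session <- function(x, ...) {
  cat(sprintf("<session: %s at t = %d min, %d event(s)%s>\n", x$scenario$id,
              x$time, length(x$events),
              if (x$ended) ", ended" else ""))
  invisible(x)
}

#' Current patient state of a session
#' @param session a `dka_session`
#' @return a `dka_patient_state`
#' @export
session_state <- function(session) .state_from_vec(session$vec)

.check_active <- function(session) {
  if (session$ended)
    .dka_stop("the session has ended; no further orders are possible",
              "dka_session_ended")
}

.record <- function(session, ev) {
  session$events[[length(session$events) + 1L]] <- ev
  invisible(ev)
}

.has_action <- function(session, kind, by_min = NULL) {
  for (ev in session$events) {
    if (ev$type == "action" && ev$kind %in% kind &&
        (is.null(by_min) || ev$time <= by_min)) return(TRUE)
  }
  FALSE
}

#' Submit a learner order
#'
#' Investigations enqueue a pending result that becomes available after the
#' scenario's latency for that test ("x has been ordered and will be
#' available in t min"); re-submitting an identical in-flight investigation
#' is rejected. Management orders update the active treatment set from the
#' current time. Vital signs are obtained through the nurse: `order_vitals`
#' requires a prior `talk_to_nurse`.
#'
#' @param session a `dka_session`
#' @param kind action id from [action_catalogue()]
#' @param payload named list of parameters (`rate` for infusions,
#'   `fluid_type` + `rate` for fluids)
#' @param source "interactive" or "scripted"
#' @return acknowledgment list with a `message`, invisibly
#' @export
submit_order <- function(session, kind, payload = list(),
                         source = "interactive") {
  .check_active(session)
  entry <- .catalogue_entry(kind)
  msg <- kind

  if (kind == "order_vitals" && !.has_action(session, "talk_to_nurse"))
    .dka_stop("talk to nurse to order vital signs", "dka_nurse_required")

  if (entry$category == "management") {
    session$orders <- .apply_management(session$orders, kind, payload)
  }

  latency <- session$scenario$lab_latencies[[kind]] %||% entry$latency_min
  immediate <- NULL
  if (entry$category == "investigation" && latency > 0) {
    for (p in session$pending) {
      if (p$kind == kind)
        .dka_stop(paste0(kind, " has already been ordered and is pending; ",
                         "submit is unavailable until the result returns"),
                  "dka_duplicate_order")
    }
    session$pending[[length(session$pending) + 1L]] <-
      list(kind = kind, ordered_at = session$time,
           available_at = session$time + latency)
    msg <- sprintf("%s has been ordered and will be available in %d min",
                   kind, as.integer(latency))
  } else if (entry$category == "investigation" || kind == "order_vitals") {
    immediate <- .release_result(session, kind, session$time)
    msg <- sprintf("%s result available", kind)
  }

  .record(session, list(time = session$time, type = "action",
                        category = entry$category, kind = kind,
                        payload = payload, source = source))
  hints <- .eval_hint_rules(session, "action_while_state")
  invisible(list(message = msg, result = immediate, hints = hints))
}

.apply_management <- function(orders, kind, payload) {
  o <- unclass(orders)
  switch(kind,
    start_insulin_infusion = { o$insulin_rate <- payload$rate %||% 0.1 },
    stop_insulin_infusion = { o$insulin_rate <- 0 },
    start_fluids = {
      if (o$fluid_type != "none")
        .dka_stop("a fluid order is already active; stop it first",
                  "dka_fluid_conflict")
      o$fluid_type <- payload$fluid_type %||% "NS"
      o$fluid_rate <- payload$rate %||% 500
    },
    stop_fluids = { o$fluid_type <- "none"; o$fluid_rate <- 0 },
    start_kcl = { o$kcl_rate <- payload$rate %||% 20 },
    stop_kcl = { o$kcl_rate <- 0 },
    give_bicarbonate = { o$bicarbonate_given <- TRUE },
    stop_bicarbonate = { o$bicarbonate_given <- FALSE },
    give_antibiotics = { o$antibiotics <- TRUE },
    stop("unknown management action: ", kind, call. = FALSE)
  )
  do.call(active_orders, o)
}

.release_result <- function(session, kind, ordered_at) {
  value <- .snapshot_result(kind, .state_from_vec(session$vec),
                            session$scenario)
  if (kind == "order_vitals") {
    value <- vital_signs(.state_from_vec(session$vec),
                         session$scenario$coefficients)
  }
  res <- list(kind = kind, ordered_at = ordered_at,
              available_at = session$time, value = value)
  session$results[[length(session$results) + 1L]] <- res
  .record(session, list(time = session$time, type = "result_available",
                        kind = kind, ordered_at = ordered_at))
  res
}

#' Advance simulated time
#'
#' Steps the physiology one minute at a time for the requested increment,
#' releasing any pending results that mature (result values are snapshotted
#' at availability time, like a real lab draw) and firing any hint rules
#' whose predicates become true.
#'
#' @param session a `dka_session`
#' @param minutes one of 5, 10, 30, 60
#' @return list with the new `state`, the `new_results` released during the
#'   advance, and `hints` fired
#' @export
advance_time <- function(session, minutes) {
  .check_active(session)
  if (!(length(minutes) == 1 && minutes %in% .advance_increments))
    .dka_stop(paste0("time can only be advanced by ",
                     paste(.advance_increments, collapse = ", "),
                     " minutes"), "dka_bad_increment")
  .record(session, list(time = session$time, type = "time_advanced",
                        minutes = minutes))
  released <- list()
  fired <- list()
  cf <- session$scenario$coefficients
  for (i in seq_len(minutes)) {
    session$vec <- .tick(session$vec, session$orders, cf)
    session$time <- session$time + 1L
    session$trace[[length(session$trace) + 1L]] <- session$vec
    mature <- vapply(session$pending, function(p) p$available_at <= session$time,
                     logical(1))
    if (any(mature)) {
      for (p in session$pending[mature])
        released[[length(released) + 1L]] <-
          .release_result(session, p$kind, p$ordered_at)
      session$pending <- session$pending[!mature]
    }
    fired <- c(fired, .eval_hint_rules(session, "missing_action_by"))
  }
  list(state = .state_from_vec(session$vec), new_results = released,
       hints = fired)
}

#' Evaluate hint rules against the current session
#'
#' Fires every rule whose trigger predicate holds on the current log and
#' state and that has not exhausted its fire-once budget; returns the fired
#' hints ordered by rule id. Hints are formative only and never alter the
#' score.
#'
#' @param session a `dka_session`
#' @return list of fired hint rules (possibly empty)
#' @export
evaluate_hints <- function(session) {
  .check_active(session)
  .eval_hint_rules(session, c("missing_action_by", "action_while_state"))
}

.eval_hint_rules <- function(session, types) {
  fired <- list()
  rules <- session$scenario$hint_rules
  ids <- vapply(rules, function(r) r$id, character(1))
  for (r in rules[order(ids)]) {
    if (!r$trigger$type %in% types) next
    if (r$once && r$id %in% session$hints_fired) next
    if (.hint_holds(r$trigger, session)) {
      session$hints_fired <- c(session$hints_fired, r$id)
      .record(session, list(time = session$time, type = "hint_shown",
                            hint_id = r$id))
      fired[[length(fired) + 1L]] <- r
    }
  }
  fired
}

.hint_holds <- function(trig, session) {
  if (trig$type == "missing_action_by") {
    if (session$time < trig$by_min) return(FALSE)
    if (.has_action(session, trig$kind)) return(FALSE)
    if (!is.null(trig$channel)) {
      cur <- session$vec[[trig$channel]]
      if (!.op_fun(trig$op)(cur, trig$value)) return(FALSE)
    }
    return(TRUE)
  }
  # action_while_state: some past action of this kind at a time where the
  # state condition held
  opf <- .op_fun(trig$op)
  for (ev in session$events) {
    if (ev$type == "action" && ev$kind == trig$kind) {
      row <- session$trace[[ev$time + 1L]]
      if (opf(row[[trig$channel]], trig$value)) return(TRUE)
    }
  }
  FALSE
}

#' End a session
#'
#' `end_and_score` marks the resulting log scoreable; `exit_without_score`
#' ends the simulation immediately without providing the score, and the
#' scoring engine will refuse the log.
#'
#' @param session a `dka_session`
#' @param mode "end_and_score" or "exit_without_score"
#' @return a `dka_session_log`
#' @export
end_session <- function(session, mode = c("end_and_score",
                                          "exit_without_score")) {
  mode <- match.arg(mode)
  if (session$ended)
    .dka_stop("the session has already been terminated",
              "dka_double_termination")
  scored <- mode == "end_and_score"
  .record(session, list(time = session$time, type = "session_ended",
                        scored = scored))
  session$ended <- TRUE
  session$scored <- scored
  session_log(session)
}

#' Extract the event log of a session
#' @param session a `dka_session`
#' @return a `dka_session_log`
#' @export
session_log <- function(session) {
  structure(list(scenario_id = session$scenario$id, schema_version = 1L,
                 scored = isTRUE(session$scored),
                 events = session$events),
            class = "dka_session_log")
}

#' @export
print.dka_session_log <- function(x, ...) {
  cat(sprintf("<session log: %s, %d event(s), %s>\n", x$scenario_id,
              length(x$events),
              if (x$scored) "scoreable" else "not scoreable"))
  invisible(x)
}

.validate_log <- function(log, scn) {
  if (!inherits(log, "dka_session_log"))
    stop("not a session log", call. = FALSE)
  if (!identical(log$scenario_id, scn$id))
    stop("log was recorded against scenario '", log$scenario_id,
         "', not '", scn$id, "'", call. = FALSE)
  times <- vapply(log$events, function(e) as.numeric(e$time), numeric(1))
  if (is.unsorted(times))
    stop("event timestamps must be non-decreasing", call. = FALSE)
  terminal <- vapply(log$events, function(e) e$type == "session_ended",
                     logical(1))
  if (sum(terminal) != 1 || !terminal[length(terminal)])
    stop("log must contain exactly one terminal event, at the end",
         call. = FALSE)
  kinds <- unlist(lapply(log$events, function(e)
    if (e$type == "action") e$kind else NULL))
  unknown <- setdiff(kinds, .action_catalogue$kind)
  if (length(unknown))
    stop("log references unknown action(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(log)
}

# re-run a recorded log through the live engine; returns the finished session
.replay_full <- function(log, scn) {
  .validate_log(log, scn)
  s <- start_session(scn)
  for (ev in log$events) {
    switch(ev$type,
      action = {
        if (ev$time != s$time)
          stop("log inconsistent: action at t=", ev$time,
               " but replay clock is at t=", s$time, call. = FALSE)
        submit_order(s, ev$kind, ev$payload %||% list(),
                     source = ev$source %||% "scripted")
      },
      time_advanced = advance_time(s, ev$minutes),
      session_ended = end_session(s, if (isTRUE(ev$scored)) "end_and_score"
                                     else "exit_without_score"),
      # result/hint events are outputs; the replay regenerates them
      NULL
    )
  }
  if (!s$ended) stop("log has no terminal event", call. = FALSE)
  s
}

#' Replay a session log
#'
#' Re-executes a recorded log against its scenario and returns the final
#' patient state. Because the engine is deterministic, the replayed state
#' (and any downstream score report) is identical to the live session's.
#'
#' @param log a `dka_session_log`
#' @param scn the `dka_scenario` the log was recorded against
#' @return the final `dka_patient_state`
#' @export
replay <- function(log, scn) {
  s <- .replay_full(log, scn)
  .state_from_vec(s$vec)
}
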