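# Scoring engine: tabulate each of the 18 performance items from the event
# log and state trace (percent of required actions performed, critical
# errors committed), map each to the 3-point item score, and roll up to the
# 7 domain subscores and the 18-54 total.

# evaluation context built from a finished (replayed) session
.score_context <- function(session) {
  acts <- Filter(function(e) e$type == "action", session$events)
  events <- data.frame(
    time = vapply(acts, function(e) as.numeric(e$time), numeric(1)),
    kind = vapply(acts, function(e) e$kind, character(1)),
    stringsAsFactors = FALSE
  )
  payloads <- lapply(acts, function(e) e$payload %||% list())
  trace <- do.call(rbind, session$trace)
  list(events = events, payloads = payloads, trace = trace)
}

.first_idx <- function(ctx, kind) {
  i <- which(ctx$events$kind == kind)
  if (length(i)) i[1] else NA_integer_
}

.kind_times <- function(ctx, kind) ctx$events$time[ctx$events$kind %in% kind]

.first_payload <- function(ctx, kind, field) {
  i <- .first_idx(ctx, kind)
  if (is.na(i)) return(NULL)
  ctx$payloads[[i]][[field]]
}

# TRUE/FALSE, or NA when a conditional requirement never became applicable
.eval_requirement <- function(r, ctx) {
  switch(r$type,
    action_by = {
      t <- .kind_times(ctx, r$kind)
      length(t) > 0 && min(t) <= (r$by_min %||% Inf)
    },
    action_before = {
      a <- .first_idx(ctx, r$kind)
      b <- .first_idx(ctx, r$before)
      !is.na(a) && (is.na(b) || a < b)
    },
    action_count = {
      sum(.kind_times(ctx, r$kind) <= (r$by_min %||% Inf)) >= r$n
    },
    action_any = {
      length(.kind_times(ctx, unlist(r$kinds))) > 0
    },
    param_window = {
      v <- .first_payload(ctx, r$kind, r$field)
      !is.null(v) && is.numeric(v) && v >= r$lo && v <= r$hi
    },
    param_equals = {
      v <- .first_payload(ctx, r$kind, r$field)
      !is.null(v) && identical(as.character(v), as.character(r$value))
    },
    recheck = {
      b <- .kind_times(ctx, r$after)
      if (!length(b)) return(FALSE)
      any(.kind_times(ctx, r$kind) > b[1] &
            .kind_times(ctx, r$kind) <= b[1] + r$window_min)
    },
    sustained = {
      s <- .kind_times(ctx, r$start)
      if (!length(s)) return(FALSE)
      !any(.kind_times(ctx, r$stop) > s[1] &
             .kind_times(ctx, r$stop) < s[1] + r$min_duration)
    },
    cond_action = {
      hit <- which(.op_fun(r$op)(ctx$trace[, r$channel], r$value))
      if (!length(hit)) return(NA)
      t0 <- ctx$trace[hit[1], "time_min"]
      any(.kind_times(ctx, r$kind) >= t0 &
            .kind_times(ctx, r$kind) <= t0 + r$window_min)
    },
    stop("unknown requirement type: ", r$type, call. = FALSE)
  )
}

# was the named infusion active at time t, judging from the event stream?
.order_active_at <- function(ctx, t, which) {
  pair <- switch(which,
    kcl = c("start_kcl", "stop_kcl"),
    insulin = c("start_insulin_infusion", "stop_insulin_infusion"),
    fluids = c("start_fluids", "stop_fluids"),
    bicarbonate = c("give_bicarbonate", "stop_bicarbonate"),
    stop("unknown order channel: ", which, call. = FALSE))
  upto <- ctx$events[ctx$events$time <= t, , drop = FALSE]
  relevant <- upto$kind[upto$kind %in% pair]
  length(relevant) > 0 && relevant[length(relevant)] == pair[1]
}

.count_critical <- function(item, ctx) {
  n <- 0L
  tags <- character()
  for (cr in item$critical) {
    opf <- .op_fun(cr$op)
    idx <- which(ctx$events$kind == cr$kind)
    for (i in idx) {
      t <- ctx$events$time[i]
      val <- ctx$trace[t + 1, cr$channel]
      if (opf(val, cr$value) &&
          (is.null(cr$unless) || !.order_active_at(ctx, t, cr$unless))) {
        n <- n + 1L
        tags <- c(tags, cr$tag)
      }
    }
  }
  list(n = n, tags = tags)
}

#' Tabulate one performance item from a session log
#'
#' Computes the percentage of the item's required actions that were
#' performed within their timing/dose windows, and counts critical-error
#' predicate hits over the state trace. Conditional requirements whose
#' triggering condition never arose are dropped from the denominator.
#'
#' @param log a scoreable `dka_session_log`
#' @param scn the scenario the log was recorded against
#' @param item a `dka_item`
#' @return list of class `dka_item_tabulation`: `id`, `percent_correct`,
#'   `critical_errors`, `score`
#' @export
tabulate_item <- function(log, scn, item) {
  if (!isTRUE(log$scored))
    .dka_stop("the session was exited without providing the score; it cannot be scored",
              "dka_unscoreable")
  ctx <- .score_context(.replay_full(log, scn))
  .tabulate_item_ctx(ctx, item)
}

.tabulate_item_ctx <- function(ctx, item) {
  vals <- vapply(item$required, function(r) .eval_requirement(r, ctx),
                 logical(1))
  applicable <- !is.na(vals)
  pct <- if (!any(applicable)) 0 else
    100 * sum(vals[applicable]) / sum(applicable)
  cr <- .count_critical(item, ctx)
  tab <- list(id = item$id, domain = item$domain, label = item$label,
              percent_correct = pct, critical_errors = cr$n,
              critical_tags = cr$tags)
  tab$score <- item_score(tab, item)
  class(tab) <- "dka_item_tabulation"
  tab
}

#' Map an item tabulation to the 3-point item score
#'
#' Score 3 requires `percent_correct >= pct_full` with no critical errors;
#' score 2 requires `percent_correct >= pct_partial` with no critical
#' errors; anything else — including any critical error, regardless of
#' percent correct — scores 1.
#'
#' @param tab an item tabulation (needs `percent_correct` and
#'   `critical_errors`)
#' @param item the `dka_item` supplying the thresholds
#' @return integer score in 1, 2, 3
#' @export
item_score <- function(tab, item) {
  if (tab$critical_errors > 0) return(1L)
  if (tab$percent_correct >= item$pct_full) return(3L)
  if (tab$percent_correct >= item$pct_partial) return(2L)
  1L
}

#' Roll item tabulations up to the score report
#'
#' @param tabs list of 18 item tabulations, one per item id 1-18
#' @param percent_scale "raw" reports `100 * S / 54`; "rescaled" reports
#'   `100 * (S - 18) / 36`
#' @return object of class `dka_score_report`: per-item table, 7 domain
#'   subscores, total S in 18-54, percent score, critical-error roster
#' @export
total_score <- function(tabs, percent_scale = c("raw", "rescaled")) {
  percent_scale <- match.arg(percent_scale)
  ids <- vapply(tabs, function(t) t$id, integer(1))
  if (length(tabs) != 18 || !identical(sort(ids), 1:18))
    stop("need exactly 18 tabulations with item ids 1..18", call. = FALSE)
  tabs <- tabs[order(ids)]
  items <- data.frame(
    id = 1:18,
    domain = vapply(tabs, function(t) t$domain, character(1)),
    label = vapply(tabs, function(t) t$label, character(1)),
    percent_correct = vapply(tabs, function(t) t$percent_correct, numeric(1)),
    critical_errors = vapply(tabs, function(t) t$critical_errors, integer(1)),
    score = vapply(tabs, function(t) t$score, integer(1)),
    stringsAsFactors = FALSE
  )
  subscores <- vapply(.scoring_domains, function(d)
    sum(items$score[items$domain == d]), numeric(1))
  total <- sum(items$score)
  pct <- if (percent_scale == "raw") round(100 * total / 54, 1)
         else round(100 * (total - 18) / 36, 1)
  roster <- unlist(lapply(tabs, function(t) t$critical_tags))
  structure(list(items = items, domain_subscores = subscores,
                 total = total, percent_score = pct,
                 percent_scale = percent_scale,
                 critical_error_roster = as.character(roster %||% character())),
            class = "dka_score_report")
}

#' Score a completed session
#'
#' Replays the log against its scenario, tabulates the 18 rubric items and
#' rolls them up. Logs ended with `exit_without_score` are refused.
#'
#' @param log a `dka_session_log`
#' @param scn the `dka_scenario`
#' @param percent_scale see [total_score()]
#' @return a `dka_score_report`
#' @export
score_session <- function(log, scn, percent_scale = c("raw", "rescaled")) {
  if (!isTRUE(log$scored))
    .dka_stop("the session was exited without providing the score; it cannot be scored",
              "dka_unscoreable")
  ctx <- .score_context(.replay_full(log, scn))
  tabs <- lapply(scn$rubric, function(it) .tabulate_item_ctx(ctx, it))
  total_score(tabs, percent_scale = percent_scale)
}

#' @export
print.dka_score_report <- function(x, ...) {
  cat(sprintf("<score report: total %d/54 (%.1f%%, %s scale), %d critical error(s)>\n",
              x$total, x$percent_score, x$percent_scale,
              length(x$critical_error_roster)))
  sub <- x$domain_subscores
  for (d in names(sub)) cat(sprintf("  %-26s %d\n", d, sub[[d]]))
  invisible(x)
}
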