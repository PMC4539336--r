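# helper: score a log built from an explicit action plan
plan_log <- function(scn, plan, horizon = 240) {
  s <- start_session(scn)
  for (row in plan) {
    while (s$time < row$time) {
      left <- row$time - s$time
      advance_time(s, max(c(5, 10, 30, 60)[c(5, 10, 30, 60) <= left]))
    }
    submit_order(s, row$kind, row$payload %||% list(), source = "scripted")
  }
  while (s$time < horizon) advance_time(s, 60)
  end_session(s, "end_and_score")
}

test_that("percent correct is the fraction of required actions satisfied", {
  scn <- test_scenario()
  item4 <- performance_item(1L, "monitoring", "four checks",
    required = list(
      list(type = "action_by", kind = "order_abg", by_min = 30),
      list(type = "action_by", kind = "order_chemistry", by_min = 30),
      list(type = "action_by", kind = "order_ketones", by_min = 30),
      list(type = "action_by", kind = "order_glucose_poc", by_min = 30)))
  all4 <- plan_log(scn, lapply(c("order_abg", "order_chemistry",
                                 "order_ketones", "order_glucose_poc"),
                               function(k) list(time = 0, kind = k)),
                   horizon = 60)
  t4 <- tabulate_item(all4, scn, item4)
  expect_equal(t4$percent_correct, 100)
  expect_equal(t4$critical_errors, 0L)

  two <- plan_log(scn, list(list(time = 0, kind = "order_abg"),
                            list(time = 0, kind = "order_chemistry")),
                  horizon = 60)
  expect_equal(tabulate_item(two, scn, item4)$percent_correct, 50)
})

test_that("insulin started at low potassium without KCl is a critical error", {
  scn <- test_scenario(potassium = 3.0)
  bad <- plan_log(scn, list(
    list(time = 5, kind = "start_insulin_infusion",
         payload = list(rate = 0.1))), horizon = 60)
  tab <- tabulate_item(bad, scn, scn$rubric[[1]])
  expect_gte(tab$critical_errors, 1L)
  expect_equal(tab$score, 1L)

  # covering the potassium first exempts the predicate
  ok <- plan_log(scn, list(
    list(time = 0, kind = "start_kcl", payload = list(rate = 20)),
    list(time = 5, kind = "start_insulin_infusion",
         payload = list(rate = 0.1))), horizon = 60)
  expect_equal(tabulate_item(ok, scn, scn$rubric[[1]])$critical_errors, 0L)
})

test_that("the 3-point mapping follows the thresholds and error dominance", {
  item <- performance_item(1L, "monitoring", "x",
    required = list(list(type = "action_by", kind = "order_abg")),
    pct_full = 80, pct_partial = 50)
  mk <- function(pct, errs) list(percent_correct = pct,
                                 critical_errors = errs)
  expect_equal(item_score(mk(100, 0), item), 3L)
  expect_equal(item_score(mk(80, 0), item), 3L)
  expect_equal(item_score(mk(100, 1), item), 1L)  # critical error dominates
  expect_equal(item_score(mk(60, 0), item), 2L)
  expect_equal(item_score(mk(50, 0), item), 2L)
  expect_equal(item_score(mk(49, 0), item), 1L)
})

test_that("totals span 18 to 54 and sum the domain subscores", {
  scn <- test_scenario()
  full <- score_session(expert_log(scn), scn)
  expect_equal(full$total, 54)
  expect_equal(full$percent_score, 100)
  idle <- score_session(idle_log(scn), scn)
  expect_equal(idle$total, 18)
  expect_equal(idle$percent_score, 33.3)
  for (rep in list(full, idle))
    expect_equal(sum(rep$domain_subscores), rep$total)
})

test_that("a mixed score profile sums correctly", {
  scn <- test_scenario()
  ctx <- dkasim:::.score_context(dkasim:::.replay_full(expert_log(scn), scn))
  tabs <- lapply(scn$rubric, function(it)
    dkasim:::.tabulate_item_ctx(ctx, it))
  # force ten 3s, five 2s, three 1s
  sc <- c(rep(3L, 10), rep(2L, 5), rep(1L, 3))
  for (i in seq_along(tabs)) tabs[[i]]$score <- sc[i]
  expect_equal(total_score(tabs)$total, 43)
})

test_that("total_score rejects missing or duplicated item ids", {
  scn <- test_scenario()
  ctx <- dkasim:::.score_context(dkasim:::.replay_full(expert_log(scn), scn))
  tabs <- lapply(scn$rubric, function(it)
    dkasim:::.tabulate_item_ctx(ctx, it))
  expect_error(total_score(tabs[-1]), "exactly 18")
  dup <- tabs; dup[[1]] <- dup[[2]]
  expect_error(total_score(dup), "exactly 18")
})

test_that("rescaled percent maps 18 to 0 and 54 to 100", {
  scn <- test_scenario()
  expect_equal(score_session(idle_log(scn), scn, "rescaled")$percent_score,
               0)
  expect_equal(score_session(expert_log(scn), scn,
                             "rescaled")$percent_score, 100)
})

test_that("adding a satisfied required action never lowers the total", {
  scn <- test_scenario()
  base_plan <- list(
    list(time = 0, kind = "talk_to_nurse"),
    list(time = 0, kind = "order_chemistry"),
    list(time = 5, kind = "start_fluids",
         payload = list(fluid_type = "NS", rate = 1000)))
  base <- score_session(plan_log(scn, base_plan, horizon = 120), scn)$total
  additions <- list(
    list(time = 0, kind = "order_abg"),
    list(time = 0, kind = "order_ketones"),
    list(time = 0, kind = "take_history"),
    list(time = 30, kind = "start_kcl", payload = list(rate = 20)))
  for (add in additions) {
    plan <- c(base_plan, list(add))
    plan <- plan[order(vapply(plan, function(r) r$time, numeric(1)))]
    expect_gte(score_session(plan_log(scn, plan, horizon = 120), scn)$total,
               base)
  }
})

test_that("adding a critical error never raises the total", {
  scn <- test_scenario(potassium = 3.0)
  plan <- list(list(time = 0, kind = "order_chemistry"),
               list(time = 5, kind = "start_fluids",
                    payload = list(fluid_type = "NS", rate = 1000)))
  base <- score_session(plan_log(scn, plan, horizon = 120), scn)$total
  worse <- c(plan, list(list(time = 10, kind = "give_bicarbonate")))
  worse <- worse[order(vapply(worse, function(r) r$time, numeric(1)))]
  expect_lte(score_session(plan_log(scn, worse, horizon = 120), scn)$total,
             base)
})

test_that("conditional requirements drop out of the denominator when inapplicable", {
  scn <- test_scenario()
  item <- performance_item(1L, "hyperglycemia", "dextrose once glucose < 14",
    required = list(list(type = "cond_action", kind = "stop_fluids",
                         channel = "glucose", op = "<", value = 14,
                         window_min = 60),
                    list(type = "action_by", kind = "order_glucose_poc")))
  # glucose never drops below 14 in an idle run: only the second requirement
  # counts, and it was not performed either
  expect_equal(tabulate_item(idle_log(scn), scn, item)$percent_correct, 0)
  done <- plan_log(scn, list(list(time = 0, kind = "order_glucose_poc")),
                   horizon = 60)
  expect_equal(tabulate_item(done, scn, item)$percent_correct, 100)
})
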