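test_that("investigations mature after the scenario latency", {
  scn <- test_scenario()  # default latencies: ABG 10 min
  s <- start_session(scn)
  advance_time(s, 30)
  ack <- submit_order(s, "order_abg")
  expect_match(ack$message, "will be available in 10 min")
  out5 <- advance_time(s, 5)
  expect_length(out5$new_results, 0)      # t = 35 < 40
  out10 <- advance_time(s, 5)
  expect_length(out10$new_results, 1)     # matures exactly at 40
  expect_equal(out10$new_results[[1]]$available_at, 40)
  expect_equal(out10$new_results[[1]]$ordered_at, 30)
})

test_that("an identical in-flight investigation is rejected", {
  s <- start_session(test_scenario())
  submit_order(s, "order_abg")
  expect_error(submit_order(s, "order_abg"), class = "dka_duplicate_order")
  advance_time(s, 10)  # result back; re-ordering allowed again
  expect_no_error(submit_order(s, "order_abg"))
})

test_that("vital signs go through the nurse channel", {
  s <- start_session(test_scenario())
  expect_error(submit_order(s, "order_vitals"), class = "dka_nurse_required")
  submit_order(s, "talk_to_nurse")
  ack <- submit_order(s, "order_vitals")
  expect_equal(ack$result$value$heart_rate, 110)
})

test_that("an advance reports the count of newly available results", {
  s <- start_session(test_scenario())
  submit_order(s, "order_abg")         # matures at 10
  submit_order(s, "order_glucose_poc") # matures at 5
  out <- advance_time(s, 10)
  expect_length(out$new_results, 2)
  s2 <- start_session(test_scenario())
  out2 <- advance_time(s2, 10)
  expect_length(out2$new_results, 0)
})

test_that("advancing 5 then 5 is identical to advancing 10", {
  run <- function(steps) {
    s <- start_session(test_scenario(coefficients = dka_coefficients()))
    submit_order(s, "order_chemistry")
    submit_order(s, "start_fluids", list(fluid_type = "NS", rate = 1000))
    for (m in steps) advance_time(s, m)
    s
  }
  a <- run(c(5, 5, 10, 5, 5))
  b <- run(c(10, 10, 10))
  expect_identical(a$vec, b$vec)
  expect_equal(length(a$results), length(b$results))
  expect_equal(a$results[[1]]$value, b$results[[1]]$value)
})

test_that("only the catalogue increments advance time", {
  s <- start_session(test_scenario())
  expect_error(advance_time(s, 7), class = "dka_bad_increment")
  expect_error(advance_time(s, 0), class = "dka_bad_increment")
})

test_that("results snapshot the state at availability time, not order time", {
  scn <- test_scenario(coefficients = test_coeffs(insulin_glucose = -30,
                                                  insulin_potassium = 0,
                                                  insulin_bhb = 0))
  s <- start_session(scn)
  submit_order(s, "start_insulin_infusion", list(rate = 0.1))
  submit_order(s, "order_glucose_poc")  # latency 5; glucose falls meanwhile
  out <- advance_time(s, 5)
  expect_equal(out$new_results[[1]]$value$glucose, 40 - 3 * 5 / 60,
               tolerance = 1e-9)
})

test_that("termination semantics: score flag, refusal, double ending", {
  s <- start_session(test_scenario())
  log <- end_session(s, "end_and_score")
  expect_true(log$scored)
  expect_error(end_session(s, "end_and_score"),
               class = "dka_double_termination")
  expect_error(submit_order(s, "order_abg"), class = "dka_session_ended")

  s2 <- start_session(test_scenario())
  log2 <- end_session(s2, "exit_without_score")
  expect_false(log2$scored)
  expect_error(score_session(log2, test_scenario()),
               class = "dka_unscoreable")
})

test_that("every submitted order appears in the log exactly once", {
  set.seed(5)
  scn <- test_scenario()
  s <- start_session(scn)
  kinds <- c("talk_to_nurse", "order_abg", "take_history",
             "start_fluids", "order_chemistry")
  for (k in kinds) submit_order(s, k)
  advance_time(s, 60)
  log <- end_session(s, "end_and_score")
  acts <- Filter(function(e) e$type == "action", log$events)
  expect_equal(sort(vapply(acts, function(e) e$kind, character(1))),
               sort(kinds))
})

test_that("replaying a log reproduces the live session exactly", {
  scn <- builtin_scenario("dka_classic")
  set.seed(9)
  s <- start_session(scn)
  submit_order(s, "talk_to_nurse")
  submit_order(s, "order_chemistry")
  advance_time(s, 10)
  submit_order(s, "start_fluids", list(fluid_type = "NS", rate = 1000))
  advance_time(s, 30)
  submit_order(s, "start_kcl", list(rate = 20))
  advance_time(s, 60)
  log <- end_session(s, "end_and_score")

  final <- replay(log, scn)
  expect_identical(state_vec(final), state_vec(session_state(s)))
  expect_equal(score_session(log, scn), score_session(log, scn))
})

test_that("logs with shuffled timestamps or wrong scenario are rejected", {
  scn <- test_scenario()
  log <- expert_log(scn)
  bad <- log
  bad$events <- rev(bad$events)
  expect_error(replay(bad, scn), "non-decreasing")
  expect_error(replay(log, builtin_scenario("dka_classic")),
               "recorded against")
})

test_that("session logs survive a JSON-lines write/read round trip", {
  scn <- test_scenario()
  log <- expert_log(scn)
  f <- tempfile(fileext = ".jsonl")
  write_session_log(log, f)
  log2 <- read_session_log(f)
  expect_equal(log2, log)
  expect_identical(state_vec(replay(log2, scn)),
                   state_vec(replay(log, scn)))
  expect_equal(score_session(log2, scn), score_session(log, scn))
})
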