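test_that("degenerate policies hit the score bounds exactly", {
  scn <- builtin_scenario("dka_classic")
  perfect <- generate_sessions(policy_profile("expert", action_prob = 1,
                                              error_prob = 0),
                               scn, 3, seed = 2)
  expect_equal(score_sessions(perfect, scn), rep(54, 3))
  absent <- generate_sessions(policy_profile("novice", action_prob = 0,
                                             error_prob = 0),
                              scn, 3, seed = 2)
  expect_equal(score_sessions(absent, scn), rep(18, 3))
})

test_that("session generation is reproducible under a fixed seed", {
  scn <- builtin_scenario("dka_classic")
  a <- generate_sessions(policy_profile("competent"), scn, 3, seed = 7)
  b <- generate_sessions(policy_profile("competent"), scn, 3, seed = 7)
  expect_equal(a, b)
})

test_that("mean scores increase strictly with the skill level", {
  scn <- builtin_scenario("dka_classic")
  means <- vapply(c("novice", "intermediate", "competent", "expert"),
                  function(sk) {
                    logs <- generate_sessions(policy_profile(sk), scn, 25,
                                              seed = 17, horizon_min = 180)
                    mean(score_sessions(logs, scn))
                  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("expert propensities dominate novice propensities", {
  nov <- policy_profile("novice"); exp_ <- policy_profile("expert")
  expect_gt(exp_$action_prob, nov$action_prob)
  expect_lt(exp_$error_prob, nov$error_prob)
  expect_gt(exp_$hint_response, nov$hint_response)
  expect_error(policy_profile("expert", action_prob = 1.4), "0, 1")
})

test_that("cohort generation is seeded and satisfies the record invariants", {
  spec <- cohort_spec()
  a <- generate_cohort(spec, seed = 5)
  b <- generate_cohort(spec, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 75)
  expect_true(all(a$total_score >= 18 & a$total_score <= 54))
  expect_equal(as.vector(table(a$group)), c(18, 21, 17, 19))
  subs <- a[, paste0("sub_", scoring_domains())]
  expect_equal(unname(rowSums(subs)), as.numeric(a$total_score))
  expect_equal(a$percent_score, round(100 * a$total_score / 54, 1))
})

test_that("generated cohorts recover the programmed structure at large n", {
  spec <- cohort_spec(group_sizes = c(MS1 = 400, MS3 = 400, PGY2 = 400,
                                      Staff = 400),
                      means = cohort_spec()$means, sds = cohort_spec()$sds)
  co <- generate_cohort(spec, seed = 11)
  gm <- as.vector(tapply(co$total_score, co$group, mean))
  expect_equal(gm, unname(cohort_spec()$means), tolerance = 0.03)
  # the copula correlation target applies within group; discretization to
  # five bands attenuates it somewhat
  r_within <- cor(stats::ave(co$comfort, co$group, FUN = scale),
                  stats::ave(co$total_score, co$group, FUN = scale))
  expect_gt(r_within, 0.35)
  expect_lt(r_within, 0.65)
  # the overall correlation adds the between-group gradient on top
  expect_gt(cor(co$comfort, co$total_score), 0.5)
  r_dka <- cor(co$n_dka_treated_band, co$total_score, method = "spearman")
  expect_gt(r_dka, 0.3)
})

test_that("outlier injection produces exactly k records beyond 2 SD", {
  spec81 <- cohort_spec(group_sizes = c(MS1 = 20, MS3 = 22, PGY2 = 19,
                                        Staff = 20),
                        means = cohort_spec()$means,
                        sds = cohort_spec()$sds)
  for (seed in 1:5) {
    co <- inject_outliers(generate_cohort(spec81, seed = seed), 6)
    expect_equal(nrow(co), 81)
    ex <- exclude_outliers(co)
    expect_equal(nrow(ex$retained), 75)
    expect_equal(sum(ex$excluded$short_duration), 5)
  }
  co <- generate_cohort(cohort_spec(), seed = 1)
  expect_identical(inject_outliers(co, 0), co)
  expect_error(inject_outliers(co, nrow(co)), "cannot")
})

test_that("a programmed group deficit is detected with the designed power", {
  spec <- cohort_spec()  # MS1 programmed well below the other groups
  hits <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    co <- generate_cohort(spec, seed = 1000 + i)
    if (oneway_anova(co$total_score, co$group)$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.8)
})

test_that("cohort CSV round trip preserves the table", {
  co <- generate_cohort(cohort_spec(), seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back$total_score, co$total_score)
  expect_equal(back$percent_score, co$percent_score)
  expect_equal(as.character(back$group), as.character(co$group))
})
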