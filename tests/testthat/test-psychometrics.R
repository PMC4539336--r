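test_that("the 2-SD exclusion rule is one-shot and handles degenerate spreads", {
  co <- data.frame(participant_id = 1:10, total_score = rep(40, 10),
                   duration_s = 900)
  expect_equal(nrow(exclude_outliers(co)$excluded), 0)  # SD = 0

  sym <- data.frame(participant_id = 1:3, total_score = c(30, 40, 50),
                    duration_s = 900)
  expect_equal(nrow(exclude_outliers(sym)$excluded), 0)

  co2 <- data.frame(participant_id = 1:12,
                    total_score = c(rep(40, 10), 41, 18),
                    duration_s = c(rep(900, 11), 45))
  ex <- exclude_outliers(co2)
  expect_equal(ex$excluded$participant_id, 12)
  expect_true(ex$excluded$short_duration)
  # one-shot: the retained set is not re-screened even though its own
  # mean/SD would now flag different records
  expect_equal(nrow(ex$retained), 11)
  expect_error(exclude_outliers(co2[1:2, ]), "at least 3")
})

test_that("Cronbach's alpha matches the closed-form oracle", {
  # identical subscales: alpha exactly 1
  m <- matrix(rep(c(1, 5, 3, 4, 2), 7), ncol = 7)
  expect_equal(cronbach_alpha(m), 1.0)

  # 3x3 toy case evaluated by hand from the formula:
  # column variances 1, 1, 0; total variance var(4,6,8) = 4
  # alpha = 3/2 * (1 - 2/4) = 0.75
  toy <- matrix(c(1, 2, 3, 1, 2, 3, 2, 2, 2), nrow = 3)
  expect_equal(cronbach_alpha(toy), 0.75)

  # independent columns: alpha tends to 0
  set.seed(1)
  ind <- matrix(rnorm(5000 * 7), ncol = 7)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  expect_error(cronbach_alpha(matrix(1, 3, 3)), "zero variance")
})

test_that("alpha is shift-invariant and rewards a duplicated subscale", {
  set.seed(2)
  base <- matrix(rnorm(200 * 6), ncol = 6)
  common <- rnorm(200)
  m <- base + common  # shared factor
  expect_equal(cronbach_alpha(m), cronbach_alpha(sweep(m, 2, c(1:6))))
  with_noise <- cbind(m, rnorm(200))          # 7th subscale pure noise
  with_dup <- cbind(m, m[, 1])                # 7th duplicates subscale 1
  expect_gt(cronbach_alpha(with_dup), cronbach_alpha(with_noise))
})

test_that("KMO separates factor-driven from orthogonal data", {
  set.seed(3)
  ortho <- matrix(rnorm(60 * 7), ncol = 7)
  k1 <- kmo(ortho)
  expect_lt(k1$value, 0.5)
  expect_false(k1$adequate)

  f <- rnorm(500)
  loaded <- sapply(1:7, function(i) 0.85 * f + sqrt(1 - 0.85^2) * rnorm(500))
  k2 <- kmo(loaded)
  expect_gt(k2$value, 0.5)
  expect_true(k2$adequate)
  for (k in list(k1, k2)) expect_true(k$value >= 0 && k$value <= 1)
})

test_that("one-way ANOVA matches the textbook decomposition", {
  g <- factor(rep(c("a", "b", "c", "d"), each = 3))
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5, 4, 5, 6)
  # by hand: SSB = 15 (df 3), SSW = 8 (df 8), F = 5
  fit <- oneway_anova(x, g)
  expect_equal(fit$F, 5)
  expect_equal(fit$df, c(3, 8))
  expect_equal(fit$p, stats::pf(5, 3, 8, lower.tail = FALSE))

  same <- oneway_anova(rep(c(1, 2, 3), 4), factor(rep(1:4, each = 3)))
  expect_equal(same$F, 0)

  expect_error(oneway_anova(1:5, factor(c(1, 1, 1, 1, 2))), "at least 2")
})

test_that("the four-group design gives df = (3, 71)", {
  g <- factor(rep(c("MS1", "MS3", "PGY2", "Staff"), c(18, 21, 17, 19)))
  set.seed(4)
  x <- rnorm(length(g), mean = as.integer(g))
  expect_equal(oneway_anova(x, g)$df, c(3, 71))
})

test_that("Tukey HSD isolates which group differs", {
  set.seed(5)
  g <- factor(rep(c("MS1", "MS3", "PGY2", "Staff"), c(18, 21, 17, 19)))
  x <- rnorm(length(g), mean = ifelse(g == "MS1", 36, 42), sd = 3.5)
  tk <- tukey_hsd(x, g)
  ms1_rows <- grepl("MS1", tk$comparison)
  expect_true(all(tk$p_adj[ms1_rows] < 0.05))
  expect_true(all(tk$p_adj[!ms1_rows] > 0.05))
})

test_that("correlations hit the closed-form oracle and the exact limits", {
  x <- c(1, 2, 3, 4, 5)
  co <- data.frame(participant_id = 1:5,
                   group = c("MS1", "MS1", "MS3", "MS3", "MS3"),
                   comfort = x, weeks_on_gim = x, age_group = x,
                   n_dka_treated_band = 6 - x, total_score = 2 * x + 30,
                   percent_score = 50, duration_s = 900)
  rows <- cohort_correlations(co)
  expect_equal(rows$estimate[rows$variable == "comfort"], 1)
  expect_equal(rows$estimate[rows$variable == "n_dka_treated_band"], -1)

  # hand-computable pair set against the sum formula
  y <- c(2, 1, 4, 3, 6)
  r_oracle <- (sum(x * y) - 5 * mean(x) * mean(y)) /
    sqrt((sum(x^2) - 5 * mean(x)^2) * (sum(y^2) - 5 * mean(y)^2))
  expect_equal(unname(cor(x, y)), r_oracle)
  co$comfort <- y
  expect_equal(rows2 <- cohort_correlations(co)$estimate[1], r_oracle,
               ignore_attr = TRUE)

  co$comfort <- rep(3, 5)
  expect_error(cohort_correlations(co), "zero variance")
})

test_that("ROC handles perfect separation and uninformative scores", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1.0)
  expect_equal(r$J_max, 1.0)
  expect_equal(r$optimal_cutoff, 10)

  set.seed(6)
  big <- roc_analysis(rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(big$auc - 0.5), 0.03)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoid AUC equals the pairwise-concordance oracle", {
  concordance <- function(scores, lab) {
    e <- scores[lab]; t <- scores[!lab]
    pairs <- outer(e, t, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:200, 1)
    lab <- c(TRUE, FALSE, stats::runif(n - 2) < 0.3)
    scores <- round(stats::rnorm(n, mean = 40 + 5 * lab, sd = 6), 1)
    r <- roc_analysis(scores, lab)
    expect_equal(r$auc, concordance(scores, lab), tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  lab <- stats::runif(80) < 0.35
  scores <- round(stats::rnorm(80, 40 + 4 * lab, 5))
  r <- roc_analysis(scores, lab)
  ref <- pROC::roc(response = lab, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("the Youden optimum matches its confusion-matrix recomputation", {
  set.seed(9)
  lab <- stats::runif(75) < 0.25
  scores <- round(stats::rnorm(75, 70 + 8 * lab, 7), 1)
  r <- roc_analysis(scores, lab)
  cut <- r$optimal_cutoff
  tp <- sum(scores[lab] >= cut); fn <- sum(lab) - tp
  tn <- sum(scores[!lab] < cut); fp <- sum(!lab) - tn
  cr <- confusion_rates(tp, fn, tn, fp)
  expect_equal(r$J_max, cr$J, tolerance = 1e-12)
  expect_equal(r$sensitivity_at_optimum, cr$sensitivity)
  # ties in J resolve to the lowest cutoff
  tie <- roc_analysis(c(1, 2, 3, 4), c(F, F, T, T))
  expect_equal(tie$J_max, 1)
  expect_equal(tie$optimal_cutoff, 3)
})

test_that("the validity report completes, is deterministic, and marks failed stages", {
  co <- generate_cohort(cohort_spec(), seed = 10)
  vr <- validity_report(co)
  expect_s3_class(vr, "dka_validity_report")
  expect_equal(vr$n_analyzed, vr$n_recruited - vr$n_excluded)
  expect_false(dkasim:::.failed(vr$cronbach_alpha))
  expect_false(dkasim:::.failed(vr$roc))
  expect_equal(validity_report(co), vr)

  no_staff <- co[co$group != "Staff", ]
  vr2 <- validity_report(no_staff)
  expect_true(dkasim:::.failed(vr2$roc))
  expect_false(dkasim:::.failed(vr2$anova))
})
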