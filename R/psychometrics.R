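# Validity-evidence pipeline for the simulator scoring system: one-shot
# 2-SD outlier exclusion, internal consistency (Cronbach's alpha over the 7
# domain subscales), Kaiser-Meyer-Olkin sampling adequacy, one-way ANOVA
# with Tukey HSD across the four training-level groups, score-covariate
# correlations, and ROC/Youden standard-setting between experts (staff) and
# trainees.

#' One-shot 2-SD outlier exclusion
#'
#' Excludes records whose score lies more than two sample standard
#' deviations from the cohort mean. The rule is applied once to the full
#' cohort — it is not iterated on the retained set. Excluded records with a
#' session duration under 60 seconds are annotated as non-completers.
#'
#' @param cohort a cohort data.frame (needs `total_score`; `duration_s` used
#'   for the annotation when present)
#' @param score_col name of the score column
#' @return list with `retained`, `excluded` (with a `short_duration`
#'   annotation column), and the `bounds` used
#' @export
exclude_outliers <- function(cohort, score_col = "total_score") {
  x <- cohort[[score_col]]
  if (is.null(x)) stop("no column '", score_col, "' in cohort",
                       call. = FALSE)
  if (length(x) < 3) stop("need at least 3 records", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    out <- cohort[0, , drop = FALSE]
    out$short_duration <- logical(0)
    return(list(retained = cohort, excluded = out, bounds = c(m, m)))
  }
  bad <- abs(x - m) > 2 * s
  excluded <- cohort[bad, , drop = FALSE]
  excluded$short_duration <- if (!is.null(excluded$duration_s))
    excluded$duration_s < 60 else NA
  list(retained = cohort[!bad, , drop = FALSE], excluded = excluded,
       bounds = c(m - 2 * s, m + 2 * s))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability over a matrix of subscale scores:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with sample variances,
#' where `var_total` is the variance of the row sums.
#'
#' @param m numeric matrix or data.frame, participants x subscales
#' @return alpha (numeric scalar)
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 participants and 2 subscales", call. = FALSE)
  k <- ncol(m)
  vt <- stats::var(rowSums(m))
  if (vt == 0)
    stop("total score has zero variance; alpha is undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Computed from the correlation matrix R and the anti-image partial
#' correlations: with `A = solve(R)`, the partial correlation between
#' variables i and j is `-A_ij / sqrt(A_ii * A_jj)`, and
#' `KMO = sum(r^2) / (sum(r^2) + sum(p^2))` over the off-diagonal entries.
#' Values below 0.5 indicate the sample is inadequate for factor analysis.
#'
#' @param m numeric matrix or data.frame, participants x variables
#' @return list of class `dka_kmo` with `value` and `adequate`
#' @export
kmo <- function(m) {
  m <- as.matrix(m)
  R <- stats::cor(m)
  A <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; KMO undefined", call. = FALSE))
  d <- sqrt(diag(A))
  P <- -A / tcrossprod(d)
  off <- upper.tri(R)
  v <- sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
  structure(list(value = v, adequate = v >= 0.5), class = "dka_kmo")
}

#' @export
print.dka_kmo <- function(x, ...) {
  cat(sprintf("KMO = %.3f (%s for factor analysis)\n", x$value,
              if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' One-way ANOVA of scores across groups
#'
#' Standard between/within decomposition via [stats::aov()], with group
#' membership as the between-subjects variable; df = (g - 1, N - g).
#'
#' @param score numeric vector
#' @param group factor of group membership
#' @return list with `F`, `df` (between, within), `p`, and the `aov` fit
#' @export
oneway_anova <- function(score, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  fit <- stats::aov(score ~ group)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], df = c(tab[1, "Df"], tab[2, "Df"]),
       p = tab[1, "Pr(>F)"], fit = fit)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' @param score numeric vector
#' @param group factor of group membership
#' @return data.frame of pairwise differences with adjusted p-values (from
#'   the studentized-range distribution)
#' @export
tukey_hsd <- function(score, group) {
  fit <- oneway_anova(score, group)$fit
  tk <- stats::TukeyHSD(fit)$group
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlations of the simulator score with participant covariates
#'
#' Pearson correlations for the (quasi-)continuous covariates — self-rated
#' comfort and medical students' weeks on the general internal medicine
#' rotation — and Spearman rank correlations for the ordinal banded
#' covariates (age group, number of DKA patients treated). Two-sided
#' p-values, no multiplicity correction.
#'
#' @param cohort a cohort data.frame
#' @return data.frame with `variable`, `method`, `estimate`, `p`, `n`
#' @export
cohort_correlations <- function(cohort) {
  one <- function(variable, x, y, method) {
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3)
      stop("need at least 3 paired observations for ", variable,
           call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance makes the correlation with ", variable,
           " undefined", call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    data.frame(variable = variable, method = method,
               estimate = unname(ct$estimate), p = ct$p.value,
               n = length(x), stringsAsFactors = FALSE)
  }
  students <- cohort$group %in% c("MS1", "MS3")
  rows <- list(
    one("comfort", cohort$comfort, cohort$total_score, "pearson"),
    one("weeks_on_gim", cohort$weeks_on_gim[students],
        cohort$total_score[students], "pearson"),
    one("age_group", cohort$age_group, cohort$total_score, "spearman"),
    one("n_dka_treated_band", cohort$n_dka_treated_band,
        cohort$total_score, "spearman")
  )
  do.call(rbind, rows)
}

#' Youden index
#'
#' @param sensitivity,specificity proportions in 0..1
#' @return `sensitivity + specificity - 1`
#' @export
youden_index <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fn true positives and false negatives (experts above/below the
#'   cutoff)
#' @param tn,fp true negatives and false positives
#' @return list with `sensitivity`, `specificity` (proportions) and the
#'   Youden `J`
#' @export
confusion_rates <- function(tp, fn, tn, fp) {
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(sensitivity = se, specificity = sp, J = youden_index(se, sp))
}

#' ROC analysis and Youden-index cut-point selection
#'
#' At every observed cutoff, a score greater than or equal to the cutoff
#' predicts "expert" (ties count as predicted-expert). AUC is computed by
#' the trapezoid rule over the resulting curve — numerically identical to
#' the pairwise-concordance (Mann-Whitney) statistic — with the
#' Hanley-McNeil standard error and a normal-approximation 95% CI. The
#' optimal cutoff maximizes J = Se + Sp - 1; ties resolve to the lowest
#' cutoff.
#'
#' @param scores numeric scores (e.g., percent scores)
#' @param is_expert logical; TRUE for the expert (staff) class
#' @return list of class `dka_roc`: `curve` (cutoff, sensitivity,
#'   specificity, J), `auc`, `auc_se`, `auc_ci`, `auc_p`,
#'   `optimal_cutoff`, `J_max`, `n_expert`, `n_trainee`
#' @export
roc_analysis <- function(scores, is_expert) {
  is_expert <- as.logical(is_expert)
  stopifnot(length(scores) == length(is_expert))
  keep <- stats::complete.cases(scores, is_expert)
  scores <- scores[keep]; is_expert <- is_expert[keep]
  n1 <- sum(is_expert); n0 <- sum(!is_expert)
  if (n1 == 0 || n0 == 0)
    stop("both classes (expert and trainee) must be present", call. = FALSE)
  cutoffs <- sort(unique(scores))
  se <- vapply(cutoffs, function(cc) mean(scores[is_expert] >= cc),
               numeric(1))
  sp <- vapply(cutoffs, function(cc) mean(scores[!is_expert] < cc),
               numeric(1))
  curve <- data.frame(cutoff = cutoffs, sensitivity = se, specificity = sp,
                      J = se + sp - 1)
  # trapezoid over the full curve including the (0,0) and (1,1) anchors
  fpr <- c(1, 1 - sp, 0)
  tpr <- c(1, se, 0)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) +
                               utils::tail(tpr[o], -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * auc_se, 0), 1)
  p <- if (auc_se == 0) NA_real_ else
    2 * stats::pnorm(-abs(auc - 0.5) / auc_se)
  best <- which(curve$J == max(curve$J))[1]
  structure(list(curve = curve, auc = auc, auc_se = auc_se, auc_ci = ci,
                 auc_p = p, optimal_cutoff = curve$cutoff[best],
                 J_max = curve$J[best],
                 sensitivity_at_optimum = curve$sensitivity[best],
                 specificity_at_optimum = curve$specificity[best],
                 n_expert = n1, n_trainee = n0),
            class = "dka_roc")
}

#' @export
print.dka_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.2f +/- %.2f (95%% CI %.2f-%.2f, p = %.3g)\n",
              x$auc, x$auc_se, x$auc_ci[1], x$auc_ci[2], x$auc_p))
  cat(sprintf("optimal cutoff %.1f: Se %.1f%%, Sp %.1f%%, J = %.3f\n",
              x$optimal_cutoff, 100 * x$sensitivity_at_optimum,
              100 * x$specificity_at_optimum, x$J_max))
  invisible(x)
}

#' @export
plot.dka_roc <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

.subscale_cols <- function() paste0("sub_", .scoring_domains)

#' Run the full validity-evidence pipeline on a cohort
#'
#' In order: one-shot 2-SD outlier exclusion, Cronbach's alpha over the 7
#' domain subscales, KMO sampling adequacy, one-way ANOVA with Tukey HSD
#' across the four groups, score-covariate correlations, and ROC/Youden
#' standard-setting of staff (expert) versus trainees on the percent score.
#' A failing stage is recorded as failed without aborting the others.
#'
#' @param cohort a cohort data.frame (see [read_cohort_csv()] for the
#'   column dictionary; the subscale columns `sub_*` enable the alpha and
#'   KMO stages)
#' @param percent_scale which percent convention the ROC runs on; passed
#'   through to the report
#' @return object of class `dka_validity_report`
#' @export
validity_report <- function(cohort, percent_scale = c("raw", "rescaled")) {
  percent_scale <- match.arg(percent_scale)
  cohort <- .validate_cohort(as.data.frame(cohort))
  stage <- function(expr) tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "dka_stage_failure"))

  excl <- exclude_outliers(cohort)
  kept <- excl$retained
  subs <- .subscale_cols()
  have_subs <- all(subs %in% names(kept))
  alpha <- if (have_subs) stage(cronbach_alpha(kept[, subs])) else
    structure(list(error = "no subscale columns"), class = "dka_stage_failure")
  kmo_v <- if (have_subs) stage(kmo(kept[, subs])) else
    structure(list(error = "no subscale columns"), class = "dka_stage_failure")
  anova <- stage(oneway_anova(kept$total_score, kept$group))
  tukey <- stage(tukey_hsd(kept$total_score, kept$group))
  corrs <- stage(cohort_correlations(kept))
  roc <- stage(roc_analysis(kept$percent_score, kept$group == "Staff"))

  structure(list(
    n_recruited = nrow(cohort), n_excluded = nrow(excl$excluded),
    n_analyzed = nrow(kept),
    excluded_short_duration = sum(excl$excluded$short_duration %in% TRUE),
    cronbach_alpha = alpha, kmo = kmo_v, anova = anova, tukey = tukey,
    correlations = corrs, roc = roc, percent_scale = percent_scale,
    input_hash = .cohort_hash(cohort)
  ), class = "dka_validity_report")
}

.failed <- function(x) inherits(x, "dka_stage_failure")

#' @export
print.dka_validity_report <- function(x, ...) {
  cat(sprintf("<validity report: %d recruited, %d excluded (>2 SD), %d analyzed>\n",
              x$n_recruited, x$n_excluded, x$n_analyzed))
  if (!.failed(x$cronbach_alpha))
    cat(sprintf("  Cronbach's alpha (7 subscales): %.3f\n",
                x$cronbach_alpha))
  if (!.failed(x$kmo))
    cat(sprintf("  KMO: %.3f (%s)\n", x$kmo$value,
                if (x$kmo$adequate) "adequate" else
                  "inadequate for factor analysis"))
  if (!.failed(x$anova))
    cat(sprintf("  ANOVA: F(%d, %d) = %.2f, p = %.3g\n", x$anova$df[1],
                x$anova$df[2], x$anova$F, x$anova$p))
  if (!.failed(x$roc))
    cat(sprintf("  ROC: AUC %.2f +/- %.2f; optimal cutoff %.1f%% (J = %.2f)\n",
                x$roc$auc, x$roc$auc_se, x$roc$optimal_cutoff, x$roc$J_max))
  for (nm in c("cronbach_alpha", "kmo", "anova", "tukey", "correlations",
               "roc")) {
    if (.failed(x[[nm]]))
      cat(sprintf("  [stage %s failed: %s]\n", nm, x[[nm]]$error))
  }
  invisible(x)
}

#' @export
summary.dka_validity_report <- function(object, ...) {
  print(object)
  if (!.failed(object$correlations)) {
    cat("  correlations with score:\n")
    print(object$correlations, row.names = FALSE)
  }
  if (!.failed(object$tukey)) {
    cat("  Tukey HSD:\n")
    print(object$tukey, row.names = FALSE)
  }
  invisible(object)
}
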