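# Seeded generators: (a) scripted learner sessions at graded skill levels,
# run through the live session engine; (b) participant cohorts with the
# group structure and covariate correlations the validity analyses assume.

#' A graded skill policy for scripted sessions
#'
#' Each skill level carries a probability of performing each required
#' action of the canonical management script, a propensity to commit a
#' critical error (early insulin with uncorrected hypokalaemia,
#' bicarbonate for mild acidaemia), and a probability of acting on a hint.
#' Expert propensities dominate novice propensities item-wise.
#'
#' @param skill "novice", "intermediate", "competent" or "expert"
#' @param action_prob,error_prob,hint_response optional overrides in 0..1
#' @return object of class `dka_policy`
#' @export
policy_profile <- function(skill = c("novice", "intermediate", "competent",
                                     "expert"),
                           action_prob = NULL, error_prob = NULL,
                           hint_response = NULL) {
  skill <- match.arg(skill)
  defaults <- list(
    novice = c(0.25, 0.25, 0.20),
    intermediate = c(0.50, 0.12, 0.45),
    competent = c(0.75, 0.05, 0.70),
    expert = c(0.92, 0.01, 0.90)
  )[[skill]]
  p <- c(action_prob %||% defaults[1], error_prob %||% defaults[2],
         hint_response %||% defaults[3])
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]",
                               call. = FALSE)
  structure(list(skill = skill, action_prob = p[1], error_prob = p[2],
                 hint_response = p[3]), class = "dka_policy")
}

# the canonical well-managed script for a scenario: what a fully competent
# learner does, at 5-minute resolution
.canonical_script <- function(scn) {
  rows <- list(
    list(time = 0, kind = "talk_to_nurse"),
    list(time = 0, kind = "order_vitals"),
    list(time = 0, kind = "take_history"),
    list(time = 0, kind = "examine_patient"),
    list(time = 0, kind = "assess_volume_status"),
    list(time = 0, kind = "order_abg"),
    list(time = 0, kind = "order_chemistry"),
    list(time = 0, kind = "order_glucose_poc"),
    list(time = 0, kind = "order_ketones"),
    list(time = 0, kind = "order_cbc"),
    list(time = 0, kind = "order_blood_culture"),
    list(time = 0, kind = "order_urinalysis"),
    list(time = 0, kind = "order_cxr"),
    list(time = 5, kind = "start_fluids",
         payload = list(fluid_type = "NS", rate = 1000)),
    list(time = 30, kind = "start_kcl", payload = list(rate = 20)),
    list(time = 35, kind = "start_insulin_infusion",
         payload = list(rate = 0.1)),
    list(time = 60, kind = "talk_to_nurse"),
    list(time = 60, kind = "order_vitals"),
    list(time = 60, kind = "order_glucose_poc"),
    list(time = 90, kind = "order_abg"),
    list(time = 120, kind = "order_chemistry"),
    list(time = 120, kind = "order_vitals"),
    list(time = 120, kind = "order_glucose_poc")
  )
  if (identical(scn$precipitating_cause, "infection"))
    rows[[length(rows) + 1]] <- list(time = 50, kind = "give_antibiotics")
  rows[order(vapply(rows, function(r) r$time, numeric(1)))]
}

# advance a session from its current time to `target` using the catalogue
# increments, largest first
.advance_to <- function(session, target) {
  while (session$time < target) {
    left <- target - session$time
    inc <- max(.advance_increments[.advance_increments <= left])
    advance_time(session, inc)
  }
}

#' Run one scripted session under a policy
#'
#' @param profile a `dka_policy`
#' @param scn a `dka_scenario`
#' @param horizon_min session length in minutes (multiple of 5)
#' @return a scoreable `dka_session_log`
#' @export
run_policy_session <- function(profile, scn, horizon_min = 240) {
  script <- .canonical_script(scn)
  keep <- stats::runif(length(script)) < profile$action_prob
  plan <- script[keep]
  if (stats::runif(1) < profile$error_prob) {
    # classic dangerous moves: insulin before the potassium is known and
    # covered, and bicarbonate for non-severe acidaemia
    plan <- c(plan, list(
      list(time = 5, kind = "start_insulin_infusion",
           payload = list(rate = 0.1)),
      list(time = 10, kind = "give_bicarbonate")))
    plan <- plan[order(vapply(plan, function(r) r$time, numeric(1)))]
  }
  s <- start_session(scn)
  for (row in plan) {
    .advance_to(s, row$time)
    tryCatch(
      submit_order(s, row$kind, row$payload %||% list(),
                   source = "scripted"),
      dka_error = function(e) NULL  # blocked orders are simply skipped
    )
  }
  .advance_to(s, horizon_min)
  end_session(s, "end_and_score")
}

#' Generate scripted session logs at a skill level
#'
#' Reproducible given the seed; scoring the logs shows mean scores that
#' increase strictly with the skill level.
#'
#' @param profile a `dka_policy`
#' @param scn a `dka_scenario`
#' @param n number of sessions
#' @param seed integer seed
#' @param horizon_min session length in minutes
#' @return list of `n` session logs
#' @export
generate_sessions <- function(profile, scn, n, seed = 1,
                              horizon_min = 240) {
  stopifnot(inherits(profile, "dka_policy"), inherits(scn, "dka_scenario"))
  set.seed(seed)
  lapply(seq_len(n), function(i) run_policy_session(profile, scn,
                                                    horizon_min))
}

#' Specification of a synthetic participant cohort
#'
#' Defaults emulate a four-group validation study: first- and third-year
#' medical students, second-year internal-medicine residents, and staff
#' endocrinologists, with group sizes 18/21/17/19, a pronounced MS1
#' deficit, and positive correlations between score and self-rated comfort
#' (target 0.55), students' weeks on the medicine rotation (target 0.40),
#' prior DKA exposure, and age.
#'
#' @param group_sizes named integer vector (MS1, MS3, PGY2, Staff)
#' @param means,sds per-group mean and SD of the total score (18-54 scale,
#'   truncated-normal margins)
#' @param r_comfort,r_weeks,r_dka,r_age latent within-group (copula) correlation targets between
#'   score and each covariate, each in (-1, 1)
#' @return object of class `dka_cohort_spec`
#' @export
cohort_spec <- function(group_sizes = c(MS1 = 18, MS3 = 21, PGY2 = 17,
                                        Staff = 19),
                        means = c(MS1 = 36, MS3 = 41, PGY2 = 42,
                                  Staff = 45),
                        sds = c(MS1 = 4, MS3 = 3.5, PGY2 = 3.5, Staff = 3),
                        r_comfort = 0.55, r_weeks = 0.40, r_dka = 0.45,
                        r_age = 0.30) {
  groups <- c("MS1", "MS3", "PGY2", "Staff")
  stopifnot(identical(names(group_sizes), groups),
            identical(names(means), groups), identical(names(sds), groups))
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  r <- c(r_comfort, r_weeks, r_dka, r_age)
  if (any(abs(r) >= 1))
    stop("correlation targets must lie in (-1, 1)", call. = FALSE)
  structure(list(group_sizes = group_sizes, means = means, sds = sds,
                 r_comfort = r_comfort, r_weeks = r_weeks, r_dka = r_dka,
                 r_age = r_age), class = "dka_cohort_spec")
}

.rtrunc_norm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(plo + u * (phi - plo))
}

.ord_cut <- function(z, breaks) findInterval(z, breaks) + 1L

# split S - 18 extra points over the 18 items (each item holds 0..2) and sum
# items into the 7 domain subscales. Points go out nearly proportionally
# (largest-remainder, random tie order) and a few random single-point swaps
# add item-level noise; the swap count sets the subscales' unique variance
# and hence the cohort's internal consistency (defaults give alpha near 0.8,
# the favorable-internal-structure regime the validity design assumes).
.allocate_subscales <- function(S, n_swap = 1L) {
  item_domain <- vapply(default_rubric(), function(it) it$domain,
                        character(1))
  left <- S - 18L
  base <- rep(left %/% 18L, 18L)
  rem <- left %% 18L
  ord <- sample.int(18L)
  extras <- base + as.integer(seq_len(18L) %in% ord[seq_len(rem)])
  for (i in seq_len(n_swap)) {
    from <- which(extras > 0L); to <- which(extras < 2L)
    if (!length(from) || !length(to)) break
    f <- from[sample.int(length(from), 1L)]
    t <- to[sample.int(length(to), 1L)]
    extras[f] <- extras[f] - 1L
    extras[t] <- extras[t] + 1L
  }
  item_scores <- 1L + extras
  vapply(.scoring_domains, function(d)
    sum(item_scores[item_domain == d]), numeric(1))
}

#' Generate a synthetic participant cohort
#'
#' Scores are drawn from per-group truncated normals on [18, 54] (rounded
#' to integer totals); covariates are tied to the score through a one-factor
#' Gaussian copula (each covariate's latent is `r * z_score +
#' sqrt(1 - r^2) * noise`), then discretized to the ordinal bands of the
#' participant-characteristics table. Domain subscale columns (`sub_*`)
#' are produced by randomly allocating the score's excess over 18 across
#' the 18 items, so subscales sum to the total exactly.
#'
#' @param spec a `dka_cohort_spec`
#' @param seed integer seed
#' @return a `dka_cohort` data.frame
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "dka_cohort_spec"))
  set.seed(seed)
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  zs <- stats::rnorm(n)
  mix <- function(r) r * zs + sqrt(1 - r^2) * stats::rnorm(n)
  zc <- mix(spec$r_comfort); zw <- mix(spec$r_weeks)
  zd <- mix(spec$r_dka); za <- mix(spec$r_age)

  S <- integer(n)
  for (g in names(spec$group_sizes)) {
    i <- groups == g
    S[i] <- as.integer(round(.rtrunc_norm(stats::pnorm(zs[i]),
                                          spec$means[[g]], spec$sds[[g]],
                                          18, 54)))
  }
  S <- pmin(pmax(S, 18L), 54L)

  cshift <- c(MS1 = -1.2, MS3 = -0.4, PGY2 = 0.6, Staff = 1.8)[groups]
  comfort <- .ord_cut(zc + cshift, c(-1.5, -0.5, 0.5, 1.5))
  dshift <- c(MS1 = -2.0, MS3 = -1.2, PGY2 = 0.5, Staff = 2.2)[groups]
  dka_band <- .ord_cut(zd + dshift, c(-0.8, 0, 0.8, 1.4, 2.0))
  ashift <- c(MS1 = -1.5, MS3 = -1.3, PGY2 = -1.0, Staff = 1.2)[groups]
  age_group <- pmin(.ord_cut(za + ashift, c(-0.5, 0.7, 1.6, 2.4)), 5L)
  weeks <- ifelse(groups == "MS1", pmax(0, round(0.5 * (zw - 1))),
           ifelse(groups == "MS3", pmax(0, round(2 + 1.5 * zw)),
           ifelse(groups == "PGY2", pmax(0, round(3 + 1.2 * zw)),
                  NA_real_)))
  subs <- t(vapply(S, .allocate_subscales,
                   numeric(length(.scoring_domains))))
  colnames(subs) <- .subscale_cols()

  df <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = groups,
    age_group = age_group,
    gender = sample(c("female", "male"), n, replace = TRUE,
                    prob = c(0.53, 0.47)),
    english_first_language = stats::runif(n) < 0.8,
    weeks_on_gim = weeks,
    comfort = comfort,
    n_dka_treated_band = dka_band,
    total_score = S,
    percent_score = round(100 * S / 54, 1),
    duration_s = round(stats::rlnorm(n, log(900), 0.35)),
    stringsAsFactors = FALSE
  )
  cbind(.validate_cohort(df), as.data.frame(subs))
}

#' Inject score outliers into a cohort
#'
#' Turns `k` records into outliers lying more than 2 sample SDs below the
#' (new) cohort mean: mode "short_duration" additionally stamps a session
#' duration under 60 seconds (a non-completer), mode "low_score" keeps a
#' plausible duration. If, after injection, any untouched record also falls
#' beyond the 2-SD band, it is pulled minimally inside the band so that the
#' post-condition "exactly k records beyond 2 SD" holds; impossible
#' requests (k = n, or bounds that cannot be realized within 18-54) are
#' signalled.
#'
#' @param cohort a `dka_cohort`
#' @param k number of outliers
#' @param mode character vector recycled to length `k`
#' @return the modified cohort
#' @export
inject_outliers <- function(cohort, k,
                            mode = c(rep("short_duration", 5), "low_score")) {
  if (k == 0) return(cohort)
  n <- nrow(cohort)
  if (k >= n)
    stop("cannot make all ", n, " records outliers of their own cohort",
         call. = FALSE)
  mode <- rep_len(mode, k)
  if (!all(mode %in% c("short_duration", "low_score")))
    stop("mode must be 'short_duration' or 'low_score'", call. = FALSE)
  idx <- order(cohort$total_score)[seq_len(k)]
  cohort$total_score[idx] <- 18L
  cohort$percent_score[idx] <- round(100 * 18 / 54, 1)
  cohort$duration_s[idx] <- ifelse(mode == "short_duration",
                                   30 + seq_len(k), 1200)
  subs <- intersect(.subscale_cols(), names(cohort))
  if (length(subs) == length(.scoring_domains)) {
    floorv <- c(3, 3, 3, 3, 2, 2, 2)
    for (j in seq_along(subs)) cohort[[subs[j]]][idx] <- floorv[j]
  }
  for (pass in 1:10) {
    m <- mean(cohort$total_score); s <- stats::sd(cohort$total_score)
    out <- which(abs(cohort$total_score - m) > 2 * s)
    stray <- setdiff(out, idx)
    if (!length(stray) && all(idx %in% out)) return(cohort)
    if (!all(idx %in% out))
      stop("cannot place ", k, " records beyond 2 SD without violating ",
           "the 18-54 score bounds", call. = FALSE)
    lo <- ceiling(m - 2 * s); hi <- floor(m + 2 * s)
    cohort$total_score[stray] <- pmin(pmax(cohort$total_score[stray], lo),
                                      hi)
    cohort$percent_score[stray] <-
      round(100 * cohort$total_score[stray] / 54, 1)
  }
  stop("could not stabilize the requested outlier structure", call. = FALSE)
}

#' Score a list of session logs
#'
#' Convenience wrapper mapping [score_session()] over logs.
#'
#' @param logs list of `dka_session_log`
#' @param scn the `dka_scenario`
#' @param percent_scale see [total_score()]
#' @return integer vector of total scores
#' @export
score_sessions <- function(logs, scn, percent_scale = "raw") {
  vapply(logs, function(l) score_session(l, scn, percent_scale)$total,
         numeric(1))
}
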