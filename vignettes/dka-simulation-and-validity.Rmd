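---
title: "Simulating DKA management and validating its scoring system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DKA management and validating its scoring system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkasim)
```

`dkasim` is a headless, scriptable simulator of diabetic ketoacidosis
(DKA) management for medical education research. A simulated patient
responds dynamically to a learner's orders; the learner's actions are
logged, scored on an 18-item rubric organized into the seven guideline
management priorities, and the resulting scores can be fed through a
complete psychometric validity pipeline. This vignette explains the models
behind each layer, the conventions we adopted where a design decision was
genuinely open, and what the synthetic generators do and do not emulate.

## The physiology model

The patient is a vector of labs and vitals (glucose, potassium, sodium,
chloride, bicarbonate, pCO2, beta-hydroxybutyrate, creatinine, volume
deficit, vitals, mental status) advanced on a fixed one-minute tick by a
linear update:

    x(t + 1 min) = clamp(x(t) + (drift + sum_j slope_j * input_j) / 60,
                         floor, ceiling)

Inputs are the active orders: the insulin infusion rate (units/kg/h), one
fluid order (type and mL/h), a KCl rate (mmol/h), and boolean bicarbonate
and antibiotic orders. Three quantities are always derived rather than
integrated, so every view of the patient is internally consistent: pH from
Henderson-Hasselbalch (`6.1 + log10(HCO3 / (0.03 pCO2))`), vitals as
affine functions of the volume deficit (heart rate rises and blood
pressure falls as the deficit grows; respiratory rate follows the
bicarbonate deficit, i.e. Kussmaul breathing), and mental status as an
ordinal function of pH and effective osmolality. pCO2 relaxes toward the
Winter's-formula compensation target (`1.5 HCO3 + 8`, plus a per-scenario
offset that implements a concurrent primary respiratory disturbance).

Because a coarse advance always iterates the one-minute tick, the state
after `dt` minutes is bit-for-bit independent of how `dt` is partitioned
— `step_state(s, o, c, 10)` is exactly two successive 5-minute steps.
This composition property is what makes recorded sessions replayable and
is fuzz-tested over random order streams.

Default coefficients (all per hour) were chosen once to reproduce
guideline-typical trajectories: glucose falls about 3 mmol/L/h on an
insulin infusion of 0.1 units/kg/h (`insulin_glucose = -30` per
unit/kg/h); serum potassium falls 0.4 mmol/L/h while insulin runs without
replacement; 20 mmol/h of KCl raises potassium by about 0.3 mmol/L/h
(`kcl_potassium = 0.015` per mmol); three quarters of infused fluid is
retained against the deficit. One modelling convention worth stating: the
insulin-driven intracellular potassium shift is applied whenever an
insulin infusion is running, independent of its rate. Within the narrow
dosing window the rubric accepts (0.05-0.15 units/kg/h) the
rate-dependence of the shift is second order, and a threshold effect keeps
the potassium trajectory — the pedagogically central channel — easy to
reason about for scenario authors.

Out-of-range excursions clamp to per-channel floors and ceilings rather
than erroring: the simulator provides feedback, not terminal failure
states, so there is no death or arrest mechanic.

## Scenarios

Six contrasting cases ship with the package (`list_builtin_scenarios()`),
spanning difficulty 2-5: classic new-onset DKA precipitated by pneumonia,
DKA with concurrent respiratory alkalosis from urosepsis, an older adult
in hyperosmolar hyperglycemic state, DKA with hypovolemic shock, DKA with
renal impairment and presenting hyperkalemia, and mild euglycemic DKA on
an SGLT2 inhibitor. Each scenario file (YAML, schema-validated with
unknown keys rejected) carries the initial state, the dynamics
coefficients, per-investigation result latencies, the rubric binding and
the hint rules, so educators can author new cases in a text editor.
Validation is total: a malformed file produces a diagnostic naming the
field, never a partial object, and rubric/hint cross-references are
checked (18 items covering all 7 domains; every critical-error predicate
covered by at least one hint rule).

The shipped default rubric is tuned to the hypokalaemic presentations
(prompt potassium replacement is a required action). For the renal case,
where potassium starts high, a stricter educator would override item 2 in
the scenario file; we kept the shared default for comparability across
cases and note this as a limitation.

## Session semantics

Time is learner-driven: it advances only in 5, 10, 30 or 60-minute jumps.
Investigations mature after a scenario-defined latency (defaults: blood
gas 10 min, chemistry 30 min, point-of-care glucose 5 min, cultures
60 min), an identical in-flight investigation cannot be re-submitted, and
result values are snapshotted at *availability* time — like a real lab
draw, and a documented convention since either choice is defensible.
Vital signs are obtained through the nurse: `order_vitals` requires a
prior `talk_to_nurse`, which is also how communication-of-care behaviour
becomes visible to the scoring engine. Every submitted order, matured
result, fired hint, time advance and the single terminal event are
recorded in an append-only log (serialized as JSON Lines at full numeric
precision), and replaying a log through the live engine reproduces the
final state and score exactly. A session ended with `exit_without_score`
is marked unscoreable and the scoring engine refuses it.

## The scoring system

Eighteen performance items partition into seven domains: potassium
deficiency (3), volume depletion and fluid replacement (3), acidosis (3),
hyperglycemia (3), precipitating cause (2), organization of care (2), and
monitoring (2). For each item the engine tabulates the percentage of its
required actions performed within their timing/dose windows and counts
critical-error predicate hits over the state trace (for example, starting
insulin while the serum potassium is below 3.3 mmol/L with no KCl
running, or giving bicarbonate at pH at or above 7.0). The 3-point item
score is then

* 3 if percent correct >= 80 and no critical error,
* 2 if percent correct >= 50 and no critical error,
* 1 otherwise — a critical error forces a 1 regardless of percent.

The 80/50 thresholds are rubric data with these defaults; critical-error
dominance encodes "unacceptable performance". Item scores sum to the
total S in [18, 54], domain subscores sum to S exactly, and the percent
score is `100 S / 54` rounded to one decimal. Whether a percent score
should instead be rescaled to `100 (S - 18) / 36` is genuinely ambiguous;
both conventions are implemented (`percent_scale = "raw"` or
`"rescaled"`) with raw as the default.

Conditional requirements ("add dextrose once glucose falls below
14 mmol/L") are dropped from an item's denominator when their triggering
condition never arises; an item whose requirements are all inapplicable
scores as having no evidence of correct action. The shipped default
rubric deliberately uses only unconditional requirements, which gives the
scale its two exact anchors: a session performing every required action
scores exactly 54 and an idle session exactly 18.

Hints are formative only. A rule fires when its predicate over the log
and state holds (e.g. no blood gas ordered by 20 minutes; KCl still
absent at 90 minutes while potassium is below 3.5), at most once per
session, and acting on a hint still earns full item credit — feedback and
scoring are parallel outputs, and whether the original design penalized
post-hint actions is unknown, so we chose the non-punitive reading. The
end-of-run summary report contains one section per domain with item
outcomes, deficiency flags and additional reading, and regenerates
byte-identically from a replayed log.

## The validity pipeline

`validity_report()` runs, in order: a one-shot 2-SD outlier exclusion
(records whose total score lies more than two sample standard deviations
from the cohort mean are dropped; the rule is deliberately not iterated
on the retained set, and excluded records with session durations under
60 s are annotated as non-completers); Cronbach's alpha over the seven
domain subscales (`k/(k-1) (1 - sum var_i / var_total)`); the
Kaiser-Meyer-Olkin statistic from the correlation and anti-image partial
correlation matrices, flagged inadequate below 0.5; a one-way ANOVA with
group membership as the between-subjects factor (df = (g-1, N-g)) and
Tukey HSD post-hocs via the studentized range; Pearson correlations of
score with self-rated comfort and the students' weeks on rotation, and
Spearman rank correlations for the ordinal banded covariates (age group,
DKA patients treated) — "nonparametric" without a named statistic is
read as Spearman; and ROC standard-setting of staff versus trainees.

ROC conventions: a score greater than or equal to the cutoff predicts
expert (ties count as predicted-expert), sensitivity and specificity are
computed at every observed cutoff, AUC is the trapezoid over the full
curve (identical to the pairwise-concordance Mann-Whitney statistic,
which the tests verify on every cohort up to n = 200, alongside an
independent reference implementation), the AUC standard error is
Hanley-McNeil with a normal 95% CI, and the optimal cutoff maximizes the
Youden index J = Se + Sp - 1 with ties resolved to the lowest cutoff.
All p-values are two-sided and no multiplicity correction is applied
anywhere in the pipeline. A failed stage (e.g. ROC on a cohort with no
staff) is recorded as failed without aborting the report, and every
report stores a hash of its input table.

## What the synthetic generators emulate

`generate_sessions()` drives the live engine with a canonical
well-managed action script, performing each scripted action with the
policy's `action_prob` and injecting the two classic dangerous moves with
probability `error_prob`. The four default profiles (novice 0.25/0.25,
intermediate 0.50/0.12, competent 0.75/0.05, expert 0.92/0.01) produce
strictly increasing mean scores, and the degenerate profiles give the
exact 18 and 54 anchors.

`generate_cohort()` emulates a four-group validation study: group sizes
18/21/17/19 (MS1/MS3/PGY2/staff), per-group truncated-normal score
margins on [18, 54] with defaults 36/41/42/45 (SD 4/3.5/3.5/3) — a
pronounced first-year deficit with the other groups close together, the
regime the design's power calculation (0.80 at alpha 0.05, total n = 66)
anticipates. Covariates are tied to the score through a one-factor
Gaussian copula (`z_cov = r z_score + sqrt(1 - r^2) eps`) and then
discretized to the ordinal bands of the participant table, with
group-dependent shifts reproducing the observed gradients (staff report
high comfort and many DKA patients treated; first-years almost none).
The copula targets (comfort 0.55, weeks 0.40) are within-group
correlations; the observed whole-cohort correlation adds the
between-group gradient on top, as it does in real data. Domain subscales
are produced by distributing the score's excess over 18 across the 18
items nearly proportionally with a single random one-point swap; that
one-swap noise level puts the cohort's Cronbach's alpha in the
favorable-internal-consistency regime (around 0.75-0.8) rather than the
degenerate extremes. `inject_outliers()` turns k records into outliers
beyond the 2-SD band (five non-completers and one very poor performance
in the default mix), pulling any stray untouched record minimally inside
the band so the post-condition "exactly k beyond 2 SD" holds
deterministically.

What the generators do **not** emulate: learning across repeated
attempts, item-level difficulty structure beyond the shared ability
factor, measurement noise in the labs, or free-text behaviour. Passing
tests therefore demonstrate that the pipeline recovers programmed
structure from data satisfying its assumptions — not that real learners
behave like the policies.

## Numerical choices and problem sizes

The internal tick is one minute; all rate coefficients are per hour and
divided by 60 per tick, so partition-independence is exact in floating
point. Tie-breaks: the Youden optimum takes the lowest cutoff; hint rules
evaluate in rule-id order; the one-shot outlier rule uses the single-pass
sample SD. Degenerate inputs are signalled rather than guessed at: zero
total-score variance (alpha), a singular correlation matrix (KMO), a
single-class ROC, groups of size below two (ANOVA), zero-variance
correlates.

The test suite sizes its simulations to be decisive yet quick: 1000
random order streams for the composition invariant, 1000 log
perturbations for scoring monotonicity, cohorts up to n = 200 for the
AUC-concordance identity, n = 5000 for the alpha limits, 500 replicate
cohorts for the ANOVA power check (observed power comfortably above
0.8), and 25 sessions per skill level for the skill-ordering property.
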