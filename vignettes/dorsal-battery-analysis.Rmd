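---
title: "Scoring and base-rate analysis of dorsal-stream test batteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and base-rate analysis of dorsal-stream test batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsalstream)
```

## The problem

Children with early brain damage are at risk for dysfunctions of the dorsal
visual stream — the occipito-parietal pathway supporting motion perception,
visuospatial attention and visuomotor control. Object recognition in
*suboptimal* representations (noise-occluded, overlapping, unconventionally
viewed drawings) also loads on parietal structures, so an object-recognition
battery can act as a screen for dorsal-stream involvement. The analytic
question this package operationalises is: given a battery of correlated
tasks scored against age-referenced norms, how many children would be
flagged by chance alone (the *base rate*), does an observed patient cohort
exceed that, and do children flagged on object recognition also show
weaknesses in the other dorsal functions?

The package provides the full chain as tested, reusable functions: item- and
trial-level scoring, developmental-age norm entry, percentile
classification, roll-up to function-level weakness, Monte Carlo base rates,
and the inferential layer (exact binomial tests, Clopper–Pearson intervals,
Fisher's exact test, Mann–Whitney U).

## Scoring models

### Object recognition (L94)

Five subtasks: visual matching (VISM), noise-occluded drawings (NOISE, 7
levels), overlapping drawings (OVERL, 4 levels), unconventional views (VIEW,
3 or 4 conditions per item) and De Vos drawings (DEVOS). Graded items score

$$s = \frac{k - j}{k - 1},$$

with $k$ the number of conditions and $j$ the 1-based index of the condition
at which the object was recognized; binary items score 1/0. An item whose
*control* condition (the easiest presentation) was failed is *inconclusive*
and excluded — failure there may reflect naming or language rather than
perception. The subtask score is the mean of conclusive item scores; a
patient enters the analysis with at least three evaluable subtasks.

**Index convention.** Read literally as "the number of conditions presented
*before* recognition", $j = 0$ at the first condition would push scores
above 1. We adopt the 1-based reading ($j$ = index of the recognition
condition), the only reading that keeps scores in $[0, 1]$ with 0 at the
control condition and that reproduces the 1 / 0.5 / 0 anchors of the
motion-defined-form task ($j = 1, 2, 3$ with $k = 3$). VIEW's three
conventionally-excluded items are an overridable default exclusion list;
exclusion is harmless because inconclusive items never change a score
(a tested invariant). Whether timed-out matching items score 0 or are
skipped is unstated in the source procedures; we score 0.

### Motion tasks

Global motion (coherence) and motion speed (speed difference, deg/s) use an
adaptive 2-up-1-down staircase: one step harder after two consecutive
correct responses, one step easier after each error. This transformed
up-down rule converges where $P(\text{correct})^2 = 0.5$, i.e. at the
70.7%-correct point of the psychometric function, and the threshold is the
mean level of the last 4 of 8 reversals. Motion-defined form is
condition-graded (1 / 0.5 / 0, inconclusive excluded) like the L94.

Choices the task descriptions leave open, and what we did:

* **"2 up-1 down" reading.** We use 2-consecutive-correct ⇒ harder /
  1-incorrect ⇒ easier (the convention converging at 70.7%); `n_up` is
  configurable if the opposite reading is wanted.
* **Step geometry.** Only a "scaling factor" $s$ is stated. We use
  multiplicative steps (×$(1-s)$ harder, ÷$(1-s)$ easier): coherence is
  bounded in $(0, 1]$ and speed differences span a large dynamic range, so
  proportional steps are the natural geometry; `step_type = "additive"` is
  available.
* **Counter reset.** The consecutive-correct counter resets after every
  step; whether it should instead persist across steps is unstated.
* **Late scaling.** The speed task shrinks $s$ from 0.33 to 0.25 "from the
  fifth reversal"; we apply the new factor to the step taken on the
  reversal trial itself, so the first *level* after the fifth reversal
  already uses it. The global-motion task has no late factor.
* **Level range.** The speed staircase's range is open above: its published
  10th-percentile cutoffs (20.0–23.8 deg/s) exceed the 17.0 deg/s starting
  difference, so worse-than-start thresholds must be representable.

The estimator's behaviour is checked by simulation: 500 staircases driven
by a cumulative-Gaussian observer (in log stimulus level) centre within a
few percent of the observer's analytic 70.7% point, and every recorded
response sequence replays bit-exactly through `staircase_replay()`.

### Visual search

A pop-out reaction-time task (motor baseline), three serial-search tasks
with 4/9/19 distracters, and a closing reaction-time task. Under serial
search, reaction time = motor time + search time, so the outcome per load is

$$\text{search time} = \mathrm{med}(\text{search RTs}) - \mathrm{med}(\text{pooled RT-task RTs}).$$

False-alarm trials are excluded from all medians and counted as errors.
The two reaction-time administrations are *pooled* into one median (more
robust than averaging two 5-trial medians; configurable). Negative search
times are retained — clamping would bias group medians. Ties at a cutoff
are never flagged ("below the percentile" is strict), including the error
count: with a cutoff of 1 error, one error is not weak. That reading of the
error norm is our choice, not asserted as the norm authors' intent.

## Developmental age and norm entry

To control for cognitive impairment, scores are referenced at developmental
age: $DA_{IQ}$ = median non-verbal subtest age-equivalent (even counts: mean
of the central pair), projected to the assessment date by
$DA = (DA_{IQ}/CA_{IQ}) \cdot CA$, assuming a locally constant developmental
rate. Entry is capped at chronological age when PIQ ≥ 100 *or* the projected
DA exceeds CA — the source rule conjoins the triggers ambiguously; we apply
the cap if either holds, so the entry age never exceeds CA. Ages are carried
in months and only formatted to year-month notation at report time. Entry
ages outside the norm bands use the nearest band (ties to the younger band).

## Base rates by Monte Carlo

With $m$ tests each flagged below its 5th percentile, the expected fraction
of *healthy* children with ≥ 1 flag is $1 - 0.95^m = 22.6\%$ under
independence and 5% under perfect correlation; real batteries sit in
between. We model standardized scores as multivariate normal with a
supplied correlation matrix and estimate

$$P\!\left(\#\{i : Z_i < z\} \ge k\right)$$

by simulation (`base_rate_counts()`), and the analogous weak-function count
(`base_rate_functions()`: a function is weak iff ≥ 1 of its tasks is below
$z$). All criteria are evaluated on one shared simulant matrix, making
monotonicity in $k$ exact per seed; the default $10^6$ draws put the Monte
Carlo SE at ≤ 0.0005 near $p = 0.2$. Under identity correlation the engine
must agree with the exact Poisson-binomial tail
(`base_rate_independent()`), a tested invariant. No analytic orthant
integration is attempted — Monte Carlo plus the independence oracle covers
the precision this design needs.

The reference correlations of the normative samples behind published base
rates are not public. The packaged default is therefore an explicitly
synthetic exchangeable matrix — 0.3 within a function, 0.1 between
functions — chosen once because it places the ≥ 1-of-5 base rate between
the independence and comonotone limits, the regime published rates near 20%
imply. It is an input, not an estimate: substitute empirical correlations
via `reference_model()` or a YAML config whenever they are available.
Published function-level base rates can only be bracketed, not reproduced,
without those correlations; `base_rate_rho_sweep()` computes the attainable
range over an exchangeable correlation $\rho \in [0, 1]$ at fixed
function-level marginals. Of note, the attainable range for ≥ 2 weak
functions at marginals 27.9/21.1/16.8% is increasing in $\rho$ from its
independence value 12.14%, so published values slightly below that (e.g.
11.8%) can arise only from simulation noise or negative inter-function
correlation.

## Inference

* **One-sample binomial** against a base rate treated as a fixed number:
  the primary p-value is the exact tail $P(X \ge x)$; a score-test $z$ is
  reported descriptively (continuity correction optional — published $z$
  values for such designs do not pin the formula down, so $z$ is secondary).
* **Clopper–Pearson** 95% intervals (`exact_binomial_ci()`): the method
  reproduces published intervals for these designs to one decimal.
* **Fisher's exact test**: one-sided hypergeometric tail in the direction
  of the observed association; the two-sided p sums all fixed-margin tables
  no more probable than the observed one (the probability-mass convention).
  Verified in the suite against a complete enumeration oracle for all
  tables up to $N = 40$.
* **Mann–Whitney U** with midranks: U is the smaller group statistic, $z$
  uses the tie-corrected variance without continuity correction, and
  p-values are exact (null U distribution, or complete enumeration for tied
  pooled samples up to `choose(n, n1)` = 20000) falling back to the normal
  approximation. No multiple-testing correction is applied anywhere, by
  design fidelity to the analysis this mirrors.

## The synthetic cohort generator

`generate_reference_scores()` draws correlated standard-normal score
vectors; `generate_patient_cohort()` plants a mean decrement (z-units) on
the tasks of affected functions, so the flag probability on an affected
task at cutoff $z$ is exactly $\Phi(z + \text{shift})$ — the closed form
that parameter-recovery tests check against. `observer_model()` simulates a
staircase participant (cumulative Gaussian on log level by default —
standard for coherence/speed thresholds; guess and lapse rates explicit).
`generate_search_rts()` draws lognormal reaction times whose median equals
motor + scan-per-item × (distracters + 1)/2; medians are the pipeline's
statistic, so the family only needs correct medians — the right-skew is
realism, not load-bearing. All generators take one explicit seed; planted
effect sizes are illustrative (no published effect sizes exist for the
clinical population), not calibrated.

What the generator does *not* emulate: administration effects (fatigue,
encouragement, administrator latency beyond its inclusion in the motor
baseline), item-level difficulty heterogeneity within a subtask,
inconclusive-item processes correlated with ability, visual-field defects,
or missingness mechanisms. Passing recovery tests therefore demonstrate
correctness of the scoring/classification chain under the stated model, not
clinical validity on real data.

## The engineered fixture cohort

`make_fixture_cohort()` inverts the pipeline: given a count specification
(cohort size; patients with ≥ 1, 2, 3 abnormal scores; per-subtask
administered/abnormal counts; weak-function patterns of the
function-complete subgroup) it constructs item- and trial-level tables that
reproduce those counts exactly — L94 item responses on the intended side of
the cutoffs, deterministic staircase response sequences, search-trial RT
sets with exact medians, and visuomotor standard scores. Infeasible
specifications (e.g. ≥ 2 count exceeding the ≥ 1 count) are rejected. The
L94 norm cutoffs used by the fixture are synthetic (flat 0.60 at the 5th
percentile) because the real instrument's norms are proprietary; the
motion and search norm tables are the published preliminary cutoffs.
`paper_fixture_spec()` encodes the marginal counts of the published cohort
analysis; the narrative co-occurrence details that are not marginal counts
(e.g. which matching-task abnormals also failed which other subtask) are
not constrained.

## Numerical choices and problem sizes

Degenerate inputs: empty item lists and all-inconclusive subtasks are "not
evaluable", never zero; a search condition with all trials excluded is
missing; degenerate Fisher margins give p = 1 with a warning; fully tied
Mann–Whitney samples give z = 0, p = 1. Correlation matrices must be
symmetric (1e-12), unit-diagonal, and PSD to −1e-10 (Cholesky with an
eigendecomposition fallback that clips eigenvalues in [−1e-10, 0]).

The test suite sizes its simulations to what each check needs: $10^6$ draws
where a spec-level Monte Carlo error of ~0.001 matters (marginal normality,
correlation recovery, oracle agreement), $10^5$ for bracket sweeps, 500
replicate staircases, and 2000-patient cohorts for recovery within 3
binomial SEs. These are the package's own choices of statistical
resolution.

## Limitations

* The default correlation matrix and the L94/visuomotor norm cutoffs are
  synthetic stand-ins; conclusions about real children require the real
  norms and, for base rates, empirical reference correlations.
* The staircase threshold is the raw reversal mean, faithful to the
  procedure it mirrors; no psychometric-function fit (and hence no slope
  estimate or threshold SE) is produced.
* Base rates assume a latent multivariate normal; heavy-tailed or skewed
  score distributions would change tail co-occurrence rates.
* The developmental-age projection assumes a constant developmental rate
  between IQ and battery assessment.
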