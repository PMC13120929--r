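---
title: "Mining disease trajectories from longitudinal clinical cohorts"
author: "ptra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease trajectories from longitudinal clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptra)
```

## The problem

Chronic diseases with heterogeneous progression — multiple sclerosis is the
motivating case — leave behind longitudinal records: visits with disability
scores (EDSS and its functional-system components), relapse onsets, MRI
lesion findings, and treatment switches. `ptra` mines such records for
*directed trajectories*: ordered pairs of clinical events `A -> B` where `B`
is disproportionately likely to follow `A` within a lag window, chained into
a directed graph, clustered, and summarized demographically. The output is a
hypothesis-generation device, not a causal claim: event order in a registry
reflects recording practice as much as biology.

## The statistic

For an ordered pair `A -> B` and a half-open lag window `[lo, hi)` days:

* Every patient with at least one `A` is *exposed*, anchored at their first
  `A`. The exposed outcome rate is `p_AB / (p_AB + p_AnotB)`, where `p_AB`
  counts exposed patients with at least one `B` whose lag from the anchor
  falls in the window.
* An equal number of *never-exposed* patients is drawn, matched to the cases
  on sex and on age at the anchor. Each control is assigned a pseudo-anchor:
  the calendar date at which the control reaches the case's anchor age,
  clamped into the control's follow-up. The unexposed rate is
  `p_notA_B / (p_notA_B + p_notA_notB)` over the matched sample.
* The relative risk is the ratio of the two rates. `RR = 2` means `B` is
  twice as likely within the window after `A` as without `A`.

Control sets are redrawn `n_resamples` times (10,000 by default) and the
empirical p-value is the add-one fraction of resamples with `RR <= 1`.
Pairs with `rr_mean > 1` and `p < 0.01` survive; when both directions of a
pair survive, an exact two-sided binomial test on the per-patient temporal
order (ties dropped) keeps the dominant direction at the 0.05 level, falling
back to the larger RR (flagged unresolved) when indecisive.

### What the empirical p-value does and does not account for

The resampling randomizes *only the control selection*: the exposed rate and
the candidate pool are held fixed. Two consequences matter in practice and
are easy to miss:

1. The p-value ignores the sampling variance of the exposed rate itself and
   of the pool mean. Relative to the resampling variance these omitted terms
   scale like `n_exposed / n_pool`, so the test is close to nominal only
   when the never-exposed pool is large relative to the exposed set —
   i.e. for exposure prevalences well below one half. For prevalent
   exposures the reported p-values are optimistic, a property of the method
   itself rather than of this implementation.
2. Sampling controls *without* replacement from a pool not much larger than
   the exposed set shrinks the across-resample variance by a finite-
   population factor and makes the problem worse. With
   `matching_policy(with_replacement = TRUE)` each resample draws controls
   independently per case, which restores the correctly sized resampling
   variance; the calibration results below use it. The default policy keeps
   without-replacement draws, which preserve the classical matched-sample
   reading of a single control set.

A second design point discovered during calibration: never-exposed patients
systematically have shorter follow-up than exposed ones (observing an `A`
requires observation time), so an age-aligned pseudo-anchor alone leaves
controls with less post-anchor observation time — up to a third of controls
end up clamped to their last visit with a zero-length window, deflating the
control rate and inflating RR under the null. Control eligibility therefore
additionally requires each control to remain under observation after its
pseudo-anchor for the case's own post-anchor span, truncated at the window
end. The requirement can only make the control's observed window at least as
long as the case's, which is conservative.

Under a null simulator (independent event streams, 200 patients, 15 event
types at 0.02 events/patient-year, 500 resamples) the pipeline's rejection
count over 210 ordered pairs at `p < 0.01` stays within the 99% binomial
band of the nominal 1% — the test suite and the acceptance script recompute
this from scratch.

### Matching and relaxation

Default matching requires the same sex and an age at anchor within 5 years
(the tolerance is a package default; tighten or relax as the cohort allows).
When a case's pool at the nominal tolerance is exhausted, eligibility falls
back tier-wise to 2x and 4x the tolerance and finally drops the age
constraint; sex is never relaxed. A pool that is exhausted even then — which
is guaranteed to happen without replacement whenever exposure prevalence
exceeds 50% — raises a matching error; the batch driver records such pairs
as `matched = FALSE` instead of failing the table.

## Event extraction

Analysis-grade events form a two-tier hierarchy (main category /
subcategory); each subcategory belongs to exactly one main category, and a
category without distinct subcategories serves as both.

* **MS course change**: `to CIS` only at the first recorded course, then a
  dated event at each recorded change to RRMS or SPMS.
* **Relapse**: onset dates, no subcategories.
* **MRI activity**: recorded lesion increases, by region (`MRI BR` /
  `MRI SC`).
* **EDSS / FSS changes**: a score change at a visit becomes a `+`/`-` event
  (dated at the first changed visit) only when the next visit with a
  non-missing score differs from the *pre-change* value in the same
  direction. The reference then moves to the changed value, so a settled
  reversal later emits a new opposite-signed event. When two or more
  functional systems change in the same direction between the same visit
  pair, they merge into a single `+FSS`/`-FSS` event.
* **DMT change**: each treatment start, labeled by mode-of-action group
  (interferons/glatiramer, anti-CD20, classical immunosuppressants, and the
  single-drug groups; cladribine is carried separately as the index
  treatment of the small-cohort analysis).

For the treatment-effectiveness analysis the taxonomy switches to evidence
of disease activity after the index treatment start: relapses (optionally
guarded to be >= 30 days from any recorded infection), confirmed disability
worsening (an EDSS increase over the peri-initiation baseline sustained for
at least 183 days; when no visit falls inside the sustain window the first
visit after it decides, and an increase with no subsequent visit at all is
not confirmed), and MRI activity; a patient with no such event receives a
single `NEDA-3` event dated at the anchor plus the study horizon, which by
construction is mutually exclusive with disease-activity events. Prior-DMT
and prior-DMT-count events (fewer than two vs at least two distinct groups)
are dated at the index start. The NEDA anchor defaults to the treatment
start, since all observation horizons are measured from initiation; it can
be switched to the first visit.

Missing scores are simply unusable for anchoring or confirming a change —
no imputation. Ages follow the exact day-count / 365.25 convention, which
reproduces one-decimal year reporting.

## Trajectory graph, clustering, demographics

Significant, direction-resolved pairs carried by at least `min_patients`
patients (10 by default, about 1% of a ~1000-patient cohort) become edges
annotated with patient count, percentage of cohort, and RR. The graph is
clustered with the Markov Clustering algorithm on the symmetrized weighted
adjacency: column-normalize, then alternate expansion (matrix square) and
inflation (entrywise power 2.0, then renormalize) to a fixed point; clusters
are the connected components of the limit matrix's nonzero structure.
Numerical choices: patient counts as edge weights (shared flow scales with
how common a transition is), symmetrization by the maximum of the two
directions, self-loops at the maximum incident weight (unit loops next to
heavy edges let the diagonal dominate expansion and shatter small connected
groups), entries below 1e-10 pruned, convergence at a max-change below 1e-8,
error after 100 iterations.

Per cluster, membership is the set of patients contributing to the
exposed-with-outcome count of at least one intra-cluster edge; age is taken
at each member's first event among the cluster's labels. Gender proportions
are compared to the cohort with a Z-test treating the cohort as a finite
population: the reference variance is shrunk by `(N - n)/(N - 1)`, with a
two-sided normal tail. Applied to the published cluster compositions
(148 female of 231, and 131 of 163, reference 69.75% female, N = 985) this
reproduces the published p-values 0.031 and 0.0012.

For display, clusters with at least three events are drawn as DOT subgraphs
(edge label `n (pct%) \n RR`), optionally hiding edges below a display RR
cutoff (1.05 and 1.25 are the customary cutoffs at the coarser windows);
two-event clusters are returned as a side table and singletons are skipped.

## The synthetic cohort generator

Real registry cohorts of this kind are not public, so the generator is a
first-class module: every stage of the pipeline is exercised against cohorts
whose ground truth is known.

* **Demographics and observation**: 985 patients by default, 69.75% female;
  age at first visit lognormal around a 43.1-year median (sdlog 0.32 chosen
  to match a 34-53 interquartile range); follow-up lognormal around an
  80.8-month median (sdlog 0.893 from a 40-135 month IQR), clamped to
  3-300 months; visit intervals lognormal around 165 days, floored at two
  weeks, which yields a median of about 15 visits. Courses start as
  administratively recorded CIS for 85% of patients (converting to RRMS
  with a ~14-month median, then to SPMS at 0.035/year), 9% PPMS, the rest
  unrecorded.
* **Event streams** are thinned Poisson processes with per-label hazards
  (events per patient-year); the defaults put a default-size cohort within a
  factor of two of the ~11,000-event volume of a real tertiary-center
  cohort. A `planted_effect(trigger, outcome, hazard_ratio, lag)` multiplies
  the outcome hazard inside the lag window after every trigger occurrence,
  and `expected_rr()` returns the closed-form RR implied by the piecewise-
  constant hazard — the ground truth for recovery tests.
* **Score series are synthesized backwards** from the intended confirmed
  change events: a step at the event visit, held thereafter, with events
  spaced at least two visits apart, so the extractor's confirmation rule is
  exercised rather than bypassed. Steps that would leave the score range are
  dropped together with their event. A small EDSS missingness rate (2%)
  spares event and confirmation visits.

What the simulator does *not* model: treatment effects on subsequent event
rates (unless planted), correlation between EDSS and FSS series, informative
visit timing, measurement error in scores, or cohort-entry selection.
Passing tests therefore demonstrate statistical correctness of the pipeline
machinery, not realism of MS natural history — a planted hazard ratio is
recovered, a null is calibrated, and the printed-count statistics are
reproduced, but real-data idiosyncrasies (recording lags, missingness
patterns) are out of scope.

## Problem sizes used by the test suite

The suite and the acceptance script run at sizes chosen to exercise every
code path at desk scale: micro-cohorts of 8-20 patients for brute-force
oracle equivalence (50 cohorts, all ordered pairs, all three windows); a
200-patient null cohort with 210 ordered pairs and 500 resamples for
calibration; a 500-patient cohort for planted-effect recovery; and a
300-patient cohort with 100 resamples for the structural six-experiment run
(three windows x two category levels). The method's reference settings —
10,000 resamples, minimum 10 patients per trajectory — remain the function
defaults.

## Known limitations

* The empirical p-value is optimistic for prevalent exposures (see above);
  interpret high-prevalence pairs with care, or use larger cohorts where the
  pool dwarfs the exposed set.
* No multiple-testing correction across pairs, mirroring the method's
  per-pair filter; the pair count is available for post-hoc correction.
* Matching without replacement is infeasible above 50% exposure prevalence;
  such pairs are reported unmatched rather than silently switched to
  replacement.
* Direction selection uses first occurrences only; recurrent interleaved
  events contribute a single ordering vote per patient.
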