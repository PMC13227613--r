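---
title: "Consensus activity labels from a thigh-worn sensor and verbal self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus activity labels from a thigh-worn sensor and verbal self-reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Activity trackers for older adults must be validated against ground
truth collected in daily life, but in-the-wild studies cannot film their
participants. Two label sources remain practical: a thigh-worn posture
sensor that exports per-minute activity-second compositions, and the
participants' own verbal activity reports recorded on a smartwatch.
Both err in characteristic ways — the sensor misreads atypical postures
(stool-sitting read as standing, reclined sitting reported as lying by
the wearer), and verbal reports have fuzzy time cues and systematically
under-report brief, low-intensity activity. `actconsensus` treats the
*agreement* of the two sources as the ground-truth proxy: a minute earns
a consensus label only when the smartwatch was worn, the thigh sensor
produced a valid label, and that label belongs to the verbally reported
label set for the minute. The package quantifies what that costs (data
shrinkage) and what it buys (cleaner benchmarking of a third-party
recognizer).

All analysis is on a shared hierarchical scheme of 8 leaf activities —
Lying, Sitting not in transport, Sitting in transport, Standing, Low /
Moderate / Vigorous Stepping, Cycling — under three postural branches
(Sedentary, Upright, Cycling). The two source mappings (thigh export
classes and recognizer classes) ship as an auditable JSON resource
(`inst/extdata/activity_scheme.json`) and can be overridden.

## Epoch labeling

The thigh sensor's 1-minute epochs may contain several activities, each
with a duration in seconds. A minute is labeled with the unique activity
whose duration **strictly exceeds 30 s**; because two durations cannot
both exceed half of a 60 s minute, the winner is unique by construction,
and minutes without a winner (alternating activities) are excluded via a
distinguished sentinel that no statistic ever counts. "Exceeding 30
seconds" is read strictly — an exact 30/30 split is excluded — because
that is the only reading under which uniqueness is provable.

Three labels are derived before the rule is applied: lying = primary +
secondary lying channels; sitting not in transport = sedentary − seated
transport; standing = upright − stepping − cycling. Sensor exports carry
rounding noise, so subtraction results in `(-1, 0)` s are clamped to
zero (and counted); anything below −1 s flags the record invalid rather
than silently fixing it. Timestamps are floored to a half-open
wall-clock minute grid `[t, t + 60 s)`.

## Personalized stepping intensity

Step counts map to metabolic intensity only roughly; the conventional
MET bands (light ≤ 2.99, moderate 3.00–5.99, vigorous 6.00–8.99, with
MET = 6 as the vigorous comparison line) hide large between-person
differences in cadence, especially among older adults. The package
therefore builds a per-participant cadence distribution over stepping
epochs — 2 steps/min bins, Gaussian KDE overlay, epochs under 50
steps/min dropped (they are dominated by partial stepping minutes; a
config flag restricts the filter to plotting only) — and places
thresholds at density valleys between prominent peaks.

Numerical choices, all config-exposed because the original procedure was
manual-visual and specifies none of them:

- kernel bandwidth: Silverman's rule on the filtered cadences;
- peak acceptance: topographic prominence at least 5 % of the maximum
  density; more than three accepted peaks keep the three tallest;
- valley placement: the density minimum between adjacent accepted peaks,
  leftmost grid point on ties (determinism);
- boundary convention: thresholds are inclusive on the higher-intensity
  side (`steps >= theta` promotes), also config-exposed.

Two peaks yield only `theta_LM`; one peak flags the profile
*indeterminate*, which is a hard error downstream unless manual
thresholds are supplied — a manual threshold file is always
authoritative when present. An audit utility cross-checks thresholds
against exertion language ("moderate pace", "ran") using a fixed,
deliberately small keyword lexicon; free-text keyword inference is known
to be unreliable in this population, which is why the lexicon is not a
learning component.

## Verbal time-cue reconstruction

Structured annotations of the voice entries arrive as activity events: a
label set (singleton / composite / undefined) plus one of ten time-cue
styles. The seven complete styles are reconstructed literally (durations
in minutes): C1 `[report − duration, report)`; C2
`[previous report, report)`; C3 `[report, report + window)` with a
1-minute default window — the style says nothing about the full
interval, so the package refuses to extrapolate; C4 and C5
`[stated start, stated end)` (C5's fields must be resolved by the
annotator across reports; the module validates, never guesses); C6
`[stated start, report)`; C7 `[report, report + duration)`. I1–I3 and
any reconstruction with `end <= start` (or a C2 without a preceding
report) fall to the sentinel.

Exclusions are tallied with mutually exclusive reasons — no usable time,
no label (undefined), both, or not worn — and the identity
`events_total = retained + sum(reasons)` holds exactly on every run.
Events straddling worn/unworn boundaries are truncated to worn minutes
rather than dropped (counted as truncations); the projection onto the
minute grid credits a minute when the event overlaps it by at least
30 s, mirroring the epoch rule, and overlapping events union their label
sets (composite semantics).

## Triangulation, shrinkage, benchmarking

Consensus is set membership: `consensus = thigh_label` iff worn, thigh
valid, and `thigh_label` in the verbal set; composites therefore
contribute whenever they contain the sensor's label, and undefined
events never do. The shrinkage report counts minutes at each stage
(thigh-labeled, worn, thigh-labeled-on-worn, verbally-labeled-on-worn,
consensus) per participant and per activity; both candidate denominators
(worn minutes and thigh-labeled worn minutes) are reported, neither
silently preferred. Percentages render half-up to integers; full
precision is retained internally. The confusion matrix counts *minutes*
(not events), defaults to singleton verbal reports only, and normalizes
by thigh (row) totals.

The recognizer benchmark is per-class one-vs-rest on raw 0–100
confidences: threshold-sweep ROC with grouped ties, Youden's J
maximization with ties broken toward the higher threshold (the more
conservative detector), and Mann–Whitney AUC with midrank tie
correction (equal to the trapezoidal area under the grouped curve; AUC
on raw confidences rather than thresholded labels is the standard choice
and is noted as an assumption). Minutes a source did not label are
dropped for that source only — the three sources deliberately evaluate
on different minute sets, which is exactly the label-source effect the
tool exposes — and `n_pos`/`n_neg` are always reported. `TILTING` and
`UNKNOWN` carry no posture semantics, map to the empty set, and are
excluded from evaluation (the original analysis never evaluates them);
this exclusion is flagged rather than configurable.

## The synthetic cohort: what it emulates, and what it does not

The study's raw data are not public, so the package ships a generator
whose defaults state the simulated world once: 13 participants × 7
days; overnight lying blocks with a daytime semi-Markov chain
(gamma-distributed dwell in whole minutes; episodes are minute-aligned);
a smartwatch worn ~10.3 h/day versus a near-24/7 thigh sensor with rare
removal episodes; vigorous stepping restricted to two participants, as
observed. One master seed feeds per-participant substreams through a
splittable counter, so adding participants never perturbs existing ones
and identical `(config, seed)` regenerate bit-identical files.

Observation channels, each with its own rate:

- **Fragmentation.** Minutes of the three fragmentable classes (sitting
  not in transport, standing, low stepping) split their 60 s with a
  companion class — two-way at a uniform integer cut (exclusion only at
  the exact 30/30 cut, probability 1/59), three-way over uniform integer
  compositions (no 30 s majority in 493 of 1711 compositions). The
  default rates (0.30 two-way, 0.075 three-way) were calibrated once,
  analytically, so that the cohort-level epoch-exclusion rate sits near
  the observed ~1.3 % given the chain's fragmentable-minute share; the
  test suite compares the measured rate to the generator's analytic
  probability, not to the historical figure.
- **Posture confusion.** Stool-sitting read as standing, lying read as
  sitting (and a small reverse rate), and the sensor-placement channel
  for cycling: a fraction of true cycling minutes read as standing or
  moderate stepping, and a small reverse stepping-to-cycling rate.
  These channels exist so that thigh-source label noise is *material*
  for the high-intensity recognizer classes — that is what makes the
  qualitative guarantee "consensus AUC is never below a single source"
  hold by construction on every seed rather than on average.
- **Under-reporting.** Per-class verbal coverage rises with intensity
  (0.25 for lying up to 0.95 for vigorous stepping), which by
  construction reproduces the observed ordering: high-intensity
  activities retain more consensus data than low-intensity ones.
- **Time-cue styles and defects.** Styles draw from the empirical mix
  (C1 32.4 % … I3 1.0 %); undefined-label defects are injected
  conditionally on the style group so the no-time / no-label / both
  exclusion shares land near the observed 6 % / 5 % / 1 %. Recall noise
  (sd 5 min) perturbs stated times and durations; composite merging
  (probability 0.3) unions an episode with its successor, restricted to
  low-intensity classes, as observed of real composites.
- **Recognizer error modes.** True-positive and background confidences
  are beta draws; overlays inject motorized-tool minutes (standing with
  vehicle-like confidence), idling-vehicle misses, and wrist-still
  cycling minutes at configured rates, which the error cross-tab
  recovers.

The generator does **not** emulate raw accelerometry (the smartwatch IMU
is reduced to a wear mask), physiological covariates, weekly routine
structure, or free-text semantics (`raw_text` carries short fixed
phrases only so the exertion audit has keywords to find). A green test
on this world therefore establishes that the *pipeline* is correct and
that its qualitative conclusions follow from the stated error structure
— not that the error structure is a validated model of older adults'
behavior.

A `noise = "none"` preset (full coverage, all-C4 styles, no channels,
near-deterministic recognizer) defines the identity world in which the
pipeline must return the truth exactly: consensus equals truth on every
worn minute and all shrinkage ratios equal 1. This is the end-to-end
correctness anchor.

## Known discrepancies and limitations

- The original tables' exclusion percentages (6.3 + 5.2 + 1.3 = 12.8 %)
  do not reconcile with their printed counts (82 + 62 + 17 of 1357 =
  11.9 %); the denominator is ambiguous. The package reports both
  count- and percentage-based tallies and its acceptance report carries
  the count-based value.
- Singleton/composite/undefined shares were reported as 59/32/6 %,
  which sum to 97 %; the residual is unexplained upstream and the
  package derives `event_class` from the label set instead of trusting
  such shares.
- Threshold estimation needs all stepping modes present; participants
  without a full range yield indeterminate profiles by design and
  require manual thresholds.
- Real per-participant style preferences (some participants almost never
  used incomplete cues) are not modeled; the style mix is cohort-level.
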