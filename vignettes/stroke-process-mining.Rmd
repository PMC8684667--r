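---
title: "Mining acute stroke pathways with a time perspective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining acute stroke pathways with a time perspective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflow)
```

`careflow` turns hospital event logs into timeline-enhanced process models
and automated performance indicators for time-critical care, using acute
ischemic stroke (AIS) and intravenous thrombolysis as its concrete setting.
This vignette explains the models and procedures the package implements,
the parameters that matter, the design decisions that were genuinely open,
and what the synthetic simulator does and does not establish about real
hospital data.

## The activity ontology

Clinical information systems record the same act under many names and at
very fine granularity. `careflow` standardizes activities in a hierarchical
classification tree. Codes are dot-separated paths: the first segment is
always `C` (clinical activity), the second names one of five categories —
Evaluation (`E`), Observation (`O`), Drug (`D`), Operation (`P`), and a
reserved Artificial (`A`) branch for milestone events — and deeper segments
are successive subclasses, so Benzylpenicillin sits at `C.D.1.1.1.1` under
Drug → Antimicrobial → Antibacterial → Penicillins. Leaves are the most
specific activities; the closer to the root, the more abstract.

Two representational choices deserve a note. Only the Drug letter is fixed
by convention in the stroke-coding literature we follow; the letters for
the other categories are a package choice and are held in a configurable
table (`default_category_letters()`) so an alternative letter set can be
dropped in. Second, composite examinations such as "Head CT" (an
examination type applied to a body site) are modelled as ordinary leaves:
the composition lives in the ontology file, not in the code syntax, because
no published syntax exists for such combinations. Numeric segments compare
as text throughout — codes are identifiers, not ordinals.

`aggregate_log()` abstracts a log to any depth by replacing each activity
with its ancestor, shrinking the set of event types and taming the
"spaghetti" that defeats models mined from raw leaves. Artificial
milestones pass through unchanged (abstracting "onset" and "arrival" into
one node would destroy the timeline). The operation never touches
timestamps or event counts, is idempotent at a fixed depth, and composes by
prefix: aggregating to depth 4 and then 2 equals aggregating to 2 directly.
These three laws are enforced by property tests.

## Event logs, lifecycles and milestones

An event log holds one trace per patient, each event carrying an activity
code, a display name, a `start`/`complete` lifecycle and a timestamp at
minute or finer precision. Activities for which only one instant was
recorded (nursing, physical examination) are represented as a start and a
complete event at the same timestamp — the convention that such activities
start when they finish. Events sort ascending in time; because
minute-precision data makes ties common, the order is made deterministic by
breaking ties with lifecycle (`start` first), then activity code, then
input order.

Three artificial milestones — symptom onset, hospital arrival, neurology-
department arrival — are not orders in any information system; they are
inserted from patient attributes by `add_artificial_events()`, which is
idempotent. Logs read and write as XES (IEEE 1849) with the case id in the
trace's `concept:name`, the activity code in a custom `activity:code`
string attribute, and patient attributes as trace-level attributes; a flat
CSV dialect with a patient sidecar file serves the same role for tabular
exports. The XES attribute layout is a package choice (the standard does
not prescribe one); readers tolerate foreign logs lacking `activity:code`
by matching display names against the ontology.

## The preprocessing rules

Nine rules clean a log before mining. Seven validate: onset and arrival
present (1); onset strictly before arrival (2); every order strictly after
arrival (3); arrival strictly before neurology arrival (4, only meaningful
for "cooperative" hospitals that transfer stroke patients to a neurology
ward, hence gated by a config flag); rt-PA doses within 20–300 mg (7);
door-to-needle within (0, 360] minutes (8); onset-to-needle within (0, 360]
minutes (9). Two derive: the needle time as the start of the *earliest*
thrombolytic order — rt-PA or urokinase — when several exist (5), and the
neurology arrival as the first order issued after admission (6), used as a
fallback when no explicit arrival attribute was recorded (an explicit
attribute wins; that precedence is a package decision).

Numerical choices worth stating plainly: all "earlier"/"later" comparisons
are strict, so equal timestamps violate — with minute-precision data this
is a real possibility, and it is deliberate (an order time-stamped at the
arrival minute cannot be shown to follow it). Dose limits apply per order,
not per patient total. A rule-3 violation rejects the whole patient by
default, consistent with removing unreasonable *patient* data; a
`strict_order_times = FALSE` switch drops only the offending events
instead. Rules 7–9 apply only to patients with a needle time; violations
are verdicts in a report, never errors.

One logical consequence is worth knowing when planting test violations:
since onset precedes arrival on any otherwise-valid trace, onset-to-needle
always exceeds door-to-needle, so a trace violating rule 8 necessarily
violates rule 9 as well. The simulator's ground truth records the implied
pair.

## Cohorts and the observation window

Patients split into a thrombolysis and a non-thrombolysis cohort by the
presence of a thrombolytic-drug order. The thrombolysis process has a
natural last event — the thrombolytic drug itself — and is not truncated.
The non-thrombolysis process has none, so it is bounded to the activities
within a window after arrival, 180 minutes by default: the thrombolysis
cohort's ~2-hour median door-to-needle time plus the 1-hour thrombolytic
infusion. "Within" is inclusive — an event at exactly arrival + window is
kept — and the window is measured against each event's recorded timestamp
(the data do not distinguish whether a bound should apply to starts or
completions). Pre-arrival events and artificial milestones always survive
truncation.

## Dependency graphs and the time perspective

Discovery counts the directly-follows relation over *complete*-lifecycle
events only; counting starts as well would double-count every activity
whose start equals its completion. On those counts the package uses the
classic heuristics-miner dependency measure — `(|a>b| − |b>a|) / (|a>b| +
|b>a| + 1)` for distinct activities, `|a>a| / (|a>a| + 1)` for self-loops.
This is the package's single largest inference: the interactive mining
tools this workflow descends from integrate several algorithms and do not
commit to a printed formula, so the measure is isolated behind one function
(`dependency_measure()`) where an alternative can be substituted. Nodes are
kept when their patient-frequency ratio (share of traces containing the
activity) reaches a threshold, edges when their dependency does; both
default to the values used for the packaged scenario (0.9 and 0.05) and
both are antitone — raising a threshold never adds anything. Long-distance
dependencies, AND/XOR splits and two-step loops are out of scope: the
target model is a plain annotated dependency graph, which practitioners in
this setting found more interpretable than Petri nets.

The time perspective then replaces layout-by-topology with
layout-by-clock. Hospital arrival is the anchor at minute 0; every
activity's offsets are signed minutes from it (onset is negative), kept at
0.1-minute resolution. Per activity the package reports the minimum, median
and maximum offset and the frequency ratio, and each node is displayed at
its **median** offset with the label `Name(ratio, median)` — ratio to two
decimals, minutes to one, as in `ECG(0.40,8.5)`. Two ambiguities were
settled as follows: the frequency ratio's numerator is the *patient* count
(the 0.40 reads "40% of patients performed this activity"), with an
event-count variant behind a switch; and offset statistics use each
patient's *first* occurrence of an activity by default, since repeated
laboratory tests would otherwise drag medians rightward — an
all-occurrences mode exists for studying exactly those repeats. Where a
display-time convention could read "average", the median is used
throughout: it is the definition the method states, and it is robust to the
long service-time tails. All statistics are invariant under global time
translation, which the tests verify by shifting whole cohorts by a year.

DOT rendering follows the established color scheme — Observation green,
Drug red, Artificial black, Evaluation orange, Operation blue — and groups
nodes into 5-minute bins (configurable) that share a rank with an invisible
chain of tick nodes forming the left-hand time axis. DOT text is the
contract; SVG is produced only if a Graphviz binary happens to be present.

## Performance indicators

Door-to-needle (DNT) is needle minus arrival; imaging-to-needle (INT) is
needle minus the completion of the last qualifying brain-imaging event at
or before the needle (head CT and MRI by default; a first-imaging mode is
provided since the qualifying convention is not standardized).
Onset-to-needle, the percentage of thrombolysed patients with DNT ≤ 60 min,
and the percentage of patients arriving within 2 h of onset who were
treated within 3 h complete the report; "within X minutes" is inclusive
everywhere, consistent with guideline phrasing. Medians over even counts
average the middle pair. The identity DNT = INT + (imaging completion −
arrival) holds exactly per patient and is asserted in the tests. Reports
attach configurable published reference values (SITS-MOST 68-min DNT, RCSN
31-min INT, the 75% within-60-min target, GWTG 71.6%) but deliberately
perform no between-cohort statistical testing — the report juxtaposes,
the analyst judges.

## The synthetic simulator

`simulate_stroke_log()` generates the packaged scenario: 125 thrombolysed
and 295 conventionally treated patients — the two-cohort scale this kind of
single-hospital stroke study operates at — with known ground truth per
patient. Service delays are log-normal (non-negative, right-skewed, the
standard choice for service times). The defining parameters:

* **DNT** ~ LogNormal with median 117 min and `sdlog = log(60/117) /
  qnorm(0.064)` ≈ 0.439, fixing 6.4% of the mass within the 60-min
  guideline. Median and within-60 mass are the two headline values such a
  delayed-thrombolysis hospital reports, so the distribution is pinned to
  both.
* **INT** ~ LogNormal, median 33 min; the CT completion is placed at
  needle − INT, so DNT = INT + door-to-imaging holds exactly by
  construction.
* **Neurology arrival** sits a few minutes (log-normal, median 3) before
  the needle — ward physicians issue their orders in batch on arrival — so
  the CT-to-neurology transit emerges near 30 min.
* **Onset-to-arrival**: log-normal medians of 80 min (thrombolysis) and
  120 min (conventional). These are not published values; they are
  clinically plausible choices fixed once for the simulator.
* Occurrence probabilities and delays of the work-up activities (ECG at
  probability 0.40 with median completion ~10 min, laboratory panels,
  nursing, evaluations, neuroprotective drugs; EEG/TCCD/MRI only in the
  conventional cohort) are likewise fixed, plausible values. Laboratory
  tests repeat across the emergency/hospitalization boundary, emulating
  the re-ordering that incompatible lab systems force.

Timestamps are emitted at whole minutes, deliberately producing ties that
exercise the tie-breaking rules. Draws are truncated so that clean patients
satisfy all nine rules (door-to-needle capped at 320 min, onset-to-needle
at 350 min — the simulated population, like a study population, has already
passed its inclusion criteria); the truncation trims about 1% of the mass
and shifts the large-sample DNT median by roughly −2 min, which the
acceptance tolerances comfortably absorb. A violation plan
(`list("2" = 5)`) corrupts exactly the requested number of traces per rule,
records the planted — and logically implied — rule ids in the ground truth,
and never overlaps two plants on one trace. The same seed yields a
byte-identical log.

`simulate_pathway_log()` is the controlled counterpart: a stage-based
template with fixed or log-normal offsets from arrival, used for the
experiments where the truth must be exact — a deterministic linear pathway
(onset → arrival → CT → neurology → rt-PA) that discovery must recover
without extras, and fixed-offset cohorts whose display times must equal the
generating offsets.

What passing these tests shows — and does not. The simulator validates the
machinery: counting, filtering, statistics, rendering, and parameter
recovery at realistic scale. It does not reproduce real clinical
correlation structure (severity-dependent pathways, weekend effects,
documentation gaps beyond the modelled single-instant activities), so
results on synthetic data say nothing about any particular hospital's
bottlenecks; they say the instrument measures correctly.

## Problem sizes and budgets

The test suite runs the brute-force dependency oracle on 200 random logs
(≤ 8 activities, ≤ 30 traces), XES round-trips on 100 logs, parameter
recovery on a 1000-patient cohort, and the full pipeline on the packaged
420-patient scenario; these sizes make every statistical tolerance
comfortable while keeping the whole suite around a minute on one core.
`scripts/acceptance.R` re-runs the 420-patient scenario end to end.

## Known limitations

* No database or free-text extraction: files (XES/CSV) are the boundary.
* The dependency measure is an inference, not a reproduction of a specific
  interactive tool's internals; alternative measures plug in at one
  function.
* No Petri-net semantics, conformance checking, per-edge waiting-time
  distributions, or between-cohort significance testing.
* Whether minimum/maximum offsets should be outlier-trimmed for display is
  left to the analyst; the package reports them raw.
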