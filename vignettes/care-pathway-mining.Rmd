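---
title: "Care-pathway process mining with careflowr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Care-pathway process mining with careflowr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflowr)
```

## The problem

Oncology care generates long longitudinal event histories — diagnoses,
surgeries, drug episodes, lab measurements, death records — that sit in
EHR tables as flat rows. Clinicians reviewing a cohort need the *process*
behind those rows: which care steps follow which, how long patients stay
in each, how subgroups differ, and which individual patients follow which
pathway. careflowr implements that analysis chain for clinical event logs,
exercised end to end on synthetic prostate-cancer care logs, since real
hospital extractions of this kind cannot be redistributed.

## The model: a timed directly-follows workflow

An **event log** is a set of traces, one per patient, each a
chronologically ordered sequence of dated care episodes.
`discover_workflow()` converts a log into a **timed directly-follows
graph**:

* one node per distinct activity label, plus an artificial `@Start` and
  `@End` that every trace enters and leaves, so node and arc execution
  counts are conserved (`sum of arcs leaving @Start = number of traces`);
* one directed arc per observed consecutive activity pair;
* every node/arc execution keeps its patient, start date and **sojourn**
  — the days until the trace's next event starts.

Two modelling choices matter and are deliberate:

* **Repeated activities accumulate on one node per label.** The rendered
  process views have one node per episode type; no label splitting is
  attempted.
* **A trace's final event gets sojourn 0** (unless it carries an explicit
  end date), so duration summaries are totals over all executions rather
  than dropping the final visit. For day-dated point events an arc's
  duration (time in its source node) numerically equals its full duration
  (start-of-source to start-of-target); logs with end dates populate the
  two criteria differently, which is why both exist.

Richer workflow formalisms with explicit parallel branches exist for this
kind of data; a directly-follows graph reproduces every view this engine
renders (models, heat layers, difference maps, per-cluster models) while
staying exactly recomputable from bigram counts, which is what the test
suite checks it against.

## Reading real-style data

`read_log()` ingests comma-delimited text with columns
`Patient ID, Date, Episode, Type, Value` plus diagnosis-level cohort
columns (`Age`, `PSA Range`, `Grade`, `Tr1`, `TR1 detail`) whose
first-seen value per patient becomes trace metadata. Dates parse
tolerantly (ISO, `18 May 2021`, `18/05/2021`) and are held at day
resolution; all durations are measured in days.

Day resolution creates a recording artifact: diagnosis and first
treatment are routinely stored with the same date, so the treatment can
appear "before" the diagnosis depending on row order. Within one day,
events are therefore ordered by a configurable activity priority —
Diagnosis first, Exitus last, everything else in file order — and
`quality_report()` reports same-date diagnosis+treatment as an
informational note rather than an error. Its error rules are the ones
that matter for curation: events after Exitus, treatments strictly before
diagnosis, traces without a diagnosis, and PSA episodes without a valid
value.

## Enhancement layers

`build_enhancement()` colours a model by a per-element criterion
(execution count, trace count, duration summation / average / median,
duration by trace, the node-only fraction-of-trace-time, and the
arc-only full-duration statistics). Normalization is anchored at the
**maximum** criterion value per element kind and clamped: with the
default `low_pct = 20` and `high_pct = 80`, elements at or below 20% of
the maximum take the first palette colour and elements at or above 80%
take the last, with linear interpolation between. The anchor is the
maximum rather than the sum because the clamp sliders bound a min–max
range; sum-anchoring is a configuration away for users who prefer
"percent of total". `@Start`/`@End` are coloured but excluded from the
normalization extremes by default, so two structural nodes that every
trace traverses do not compress the clinical colour scale.

Two duration-by-trace readings circulate for these views: time in the
element divided by the number of traversing traces, and time in a node
divided by the total trace time. The first is implemented as
`duration_by_trace` (it is the one consistent across nodes and arcs);
the second is exposed separately as `duration_fraction_of_trace` so
neither meaning is silently lost.

The palette registry is frozen: nine palettes, of which five are designed
for colour-blind users. Heat palettes carry three gradient stops,
difference palettes four (three gradient stops plus a dedicated colour
for elements absent from one model). Since no concrete RGB values are
canonical for such views, the shipped values are arbitrary but stable,
and the colour-blind sets are chosen for monotone luminance with at least
40/255 separation between adjacent stops — a property the test suite
asserts numerically rather than takes on trust.

## Comparing cohorts

`difference_map()` compares two models element-wise: absolute criterion
deltas, normalized by the maximum delta of that element kind, coloured
across the difference palette's gradient (near-zero → first stop);
elements present in only one model are flagged and given the absent
colour. Deltas are symmetric under argument exchange up to swapping the
absence flags.

Per-node significance uses a two-sided **Mann–Whitney U** test on the two
sojourn-duration samples. The literature behind such dashboards states a
0.05 threshold but not a test; rank-sum is the defensible default for
skewed, day-valued sojourn times, and the choice is pluggable (a
two-proportion z-test on traversal fractions is available as the
`frequency` test). Implementation details that the contract fixes:

* both samples of size ≤ 8: the exact null distribution of U is built by
  full enumeration of group assignments, which handles ties without
  approximation; two fully tied samples give p = 1;
* larger samples: tie-corrected normal approximation without continuity
  correction (cross-checked in the tests against the standard rank-sum
  reference on tie-free data);
* no multiple-testing correction by default, matching the plain per-node
  0.05 convention; Benjamini–Hochberg is a flag.

Calibration is verified by simulation: two cohorts drawn from the same
generator, per-node verdicts pooled over ≥ 2000 comparisons, rejection
rate required to sit in 0.05 ± 0.02. Pooled verdicts are restricted to
nodes with at least 10 sojourns in both cohorts and non-degenerate pooled
durations: an exact rank test on 3-vs-3 samples cannot reject at 0.05 at
all, and all-tied samples (e.g. a node always followed the same day)
return p = 1 by construction, so including them would measure
attainability rather than calibration.

## Trace clustering

Three normalized trace distances are provided: `levenshtein` (unit-cost
edit distance over activity sequences divided by the longer length),
`topological` (1 − Jaccard similarity of the directly-follows arc sets of
the two single-trace models, artificial arcs included) and `heuristic`
(mean of activity-multiset Jaccard distance and normalized Levenshtein —
content plus order). The topological and heuristic definitions follow
cited distance families whose originals are not restated in the
literature this package draws on; the surrogates here are frozen,
documented, and pluggable via `get_distance()` so a faithful
reimplementation can be swapped in.

`qt_cluster()` implements classic quality-threshold clustering with
complete-linkage (diameter) quality: every remaining trace seeds a
candidate grown greedily by the trace minimizing the resulting diameter,
candidates stop at the threshold `q`, the largest candidate commits, and
ties always break toward the smallest trace index so runs are
reproducible without randomness. Traces left below `min_size` (default 2)
are reported unassigned rather than forced into clusters. The diameter
guarantee (`max pairwise distance ≤ q` in every committed cluster) is
asserted post hoc in the tests on every run. Note one subtlety: the
committed-cluster count is only monotone in `q` when singletons count as
clusters (`min_size = 1`); with a larger `min_size`, raising `q` can
promote former leftovers into countable clusters.

For PSA-evolution clustering, `derive_state_traces()` first re-expresses
each trace as the sequence of PSA states `<10`, `10-20`, `>20` (ng/ml).
Binning is boundary-inclusive in the middle bin — `[10, 20]` — matching
the printed "10–20" range style, with the strict left-closed convention
available by flag. Consecutive repeats of the same state are collapsed
(configurable), because repeated stable measurements would otherwise
dominate the edit distances.

## The synthetic cohort generator

`default_prostate_scenario()` fixes the study conditions the tests run
under; `generate_log()` draws from them through a single seeded stream,
so a seed determines the CSV byte-for-byte. The generator emulates:

* **three pathway circuits** — radical prostatectomy followed by further
  treatment (weight 0.3), prostatectomy only (0.3), non-surgical
  treatment only (0.4) — over the six clinical activities plus PSA
  measurement episodes;
* **inter-event gaps** log-normal with median 60 days (`sdlog` 0.6),
  a realistic scale for oncology follow-up intervals;
* **PSA trajectories** per circuit: a uniform start range, linear drift
  per 30 days, a multiplicative drop at each treatment, and additive
  measurement noise; the diagnosis-day PSA determines the recorded
  `PSA Range` metadata;
* **metadata**: age normal(70, 8) truncated to [45, 95]; ISUP grade
  drawn *conditionally on the circuit* (prostatectomy circuits skew
  toward grade groups 1–2, the non-surgical circuit toward 3–5), which
  reproduces the clinically expected grade/surgery association while
  keeping circuit marginals exactly at the configured weights;
* **the same-date recording artifact** (diagnosis and first treatment
  share a date, probability 1 by default) and a terminal Exitus with
  probability 0.15;
* **error-injection switches** (treatment after exitus, pre-diagnosis
  treatment, missing PSA value), off by default, whose injected counts
  the quality report must recover exactly.

What the generator does **not** emulate: clinically validated PSA
kinetics or survival models, co-morbidities, treatment lines conditioned
on response, or non-EHR data streams. Passing tests therefore demonstrate
that the engine's mechanics (discovery, statistics, comparison,
clustering, reporting) are correct under controlled conditions — not that
any clinical conclusion transfers to real cohorts.

## Numerical choices and degenerate inputs

* Variance in statistics blocks is the population variance (the block
  describes the observed executions); sample variance is a flag.
* Medians of even-sized samples are the mean of the central pair;
  percentage tables round half-up to one decimal, the printed style of
  cohort tables.
* Duration histograms span `[min, max]` with equal-width bins; the
  Gaussian overlay is fitted by sample mean/sd and scaled by
  `n × bin width`; all-equal durations give one occupied bin and the
  overlay is suppressed.
* Zero-range enhancement criteria (maximum 0) normalize to 0; a shared
  positive value normalizes everything to 1 (every element is at the
  maximum).
* Empty logs refuse discovery; traces without PSA events are dropped
  from state-trace derivation with a warning; a node absent from one
  model is a difference-map fact, not a significance test.

## Problem sizes used by the checks

The bundled verification runs at deliberately modest sizes: 100 random
logs of up to 50 traces for the discovery oracle, 1000 random trace pairs
for the distance properties, ≥ 2000 pooled node verdicts (25 patients
per cohort per comparison) for significance calibration, and 500-patient
logs for cohort-level summaries. These sizes give stable Monte-Carlo
estimates while keeping a full run in the low minutes on one core.

## Known limitations

* No parallel-branch or hidden-state semantics: concurrent care episodes
  appear as interleavings.
* No conformance checking, alignments, or model-level fitness metrics.
* The topological and heuristic distances are surrogate definitions (see
  above), not reimplementations of their original references.
* Significance compares one criterion at a time; duration and frequency
  tests are not combined.
* The CLI's histogram export requires a cairo-capable R build for SVG.
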