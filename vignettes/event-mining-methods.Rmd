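---
title: "Event mining in biomedical time series: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event mining in biomedical time series: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsevents)
```

`tsevents` implements an event-centric pipeline for fixed-rate biomedical
signals: declare what an event is, detect and characterise events, compare
subjects by event similarity, build per-class reference models by clustering
events (after outlier screening), and classify new subjects by maximum
model similarity. This vignette is the package's account of the science:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
where the design was genuinely open.

## Signals, indices and units

A series is a vector of samples at a fixed sampling period (default 10 ms,
i.e. 100 Hz). Sample indices are **0-based** and intervals **half-open**
`[start, end)`, so `duration_ms = (end - start) * sampling_period_ms` holds
exactly and the sample at index `i` lives at time `i * sampling_period_ms`.
All times are milliseconds; conversion between samples and time happens
only through the sampling period. Subjects are fixed three-level trees
(register → measurement → condition → leaves), serialised to a single
canonical XML dialect; any other dialect must be converted upstream.

## Cleaning

Two mechanisms mirror how such recordings are screened in practice:

* `trim_edges()` removes start/end fragments (electrode settling, stepping
  onto the force plate). Which fragments to cut is a judgement call, so the
  package takes explicit indices rather than guessing.
* `clean_series()` drops samples equal to a missing-value sentinel (a
  pressure sensor reads exactly 0 when unloaded) or outside a plausible
  range, and declares the series valid only if at least 70% of samples
  survive. The comparison is **inclusive** (retaining exactly 70% is
  valid). Dropped interior samples are removed, not interpolated — the
  cleaned series is shorter and all downstream indices live on the cleaned
  index space. Interpolation would invent signal precisely where the sensor
  failed, which is the wrong default for event magnitudes.

What counts as "inconsistent" is domain knowledge; `valid_range` is
deliberately a free parameter with no default.

## Event definitions and detection

Two trigger families cover the two study domains.

**Relative-amplitude events (EEG waves).** The signal is mean-centred and
cut at zero crossings; each maximal same-sign run is a wave carrying its
extremum and period. A wave is an event when

* its peak deviation exceeds `k` times the baseline scale — the MAD of the
  mean-centred signal by default (`baseline_stat = "std"` switches to the
  standard deviation), and
* its period lies within `[min_period_ms, max_period_ms]` — 20–70 ms for
  spikes, 70–200 ms for sharp waves, and
* (spicules) an immediately adjacent wave has opposite sign — automatic for
  zero-crossing waves — **and** is itself prominent, with peak deviation
  above `polarity_factor` (default `k/2`) times the baseline scale. That is
  the operational reading of an "abrupt change of polarity": the wave does
  not decay back through baseline but swings hard the other way.

The MAD is preferred because the events themselves inflate a standard
deviation: a robust scale estimates the *background*, which is what
"relatively higher than the other waves" should mean. The whole series is
the reference for that baseline; a window-local baseline is left as an
extension.

Numerical choices: samples within `1e-9 * max|centred signal|` of zero are
boundary points and attach to the *following* wave (trailing ones to the
preceding wave). This makes an exactly sampled sine cycle segment into two
waves of equal period instead of leaking one boundary sample into the wrong
wave. A constant series has no waves. Period bounds are inclusive.

**Absolute-threshold events (falls).** Each maximal run of samples strictly
above ∂ is an event; its magnitude is the mean of the suprathreshold
samples and its anchor the maximum. Two guards deal with sensor chatter:
sub-threshold gaps up to `merge_gap_ms` are bridged, and events shorter
than `min_duration_ms` are discarded. Both default to 0 — the definition
alone decides — but the shipped stabilometric rule file sets both to
100 ms: when the pressure hovers near ∂, sensor noise otherwise shatters
one fall into a burst of fragments. 100 ms is well below any plausible
fall (the cohort averages are 346 and 754 ms) and well above the 10 ms
sampling grid.

The prominence factor defaults to `k = 3`. The broad-band `paroxysm`
rule — a single relative-amplitude definition with a 20–400 ms window, used
when an analysis keys on event features rather than spike/sharp sub-type
labels — sets `k = 3.5`: its window admits waves as short as two samples,
and for Gaussian background at 100 Hz a 10-second series is expected to
contain about 2.7 chance exceedances of 3 robust sd but only ~0.5 of 3.5,
while a deflection five noise-sd tall is still missed in under 5% of
cases. Rule files are YAML, one block per event type; `parse_definitions()`
validates every block and names the offending one on error.

Detection is deterministic, and `check_events()` re-verifies every detected
event against its definition without reusing detector state.

## Agreement and matching

`match_event_sets()` matches a detected set against a reference annotation:
a pair is admissible when types agree and the intervals overlap at least
`min_overlap` (default 0.5) of the **shorter** event; the matching is the
maximum-cardinality bipartite matching over admissible pairs. When an
expert event and a detected event count as "the same" is not something a
formula can decide; half the shorter event is a common, symmetric choice.
Agreement is then

$$\mathrm{SIM} = \frac{2\,\#\mathrm{matched}}{\#\mathrm{expert} + \#\mathrm{detected}},$$

which is 1 exactly when both sets coincide in count and pairing, 0 when
nothing matches. Two empty sets score 1 (the formula is 0/0 there; finding
nothing where there is nothing is perfect agreement). Published agreement
tables *truncate* to three decimals — 2·1412/2942 = 0.9599 is printed
0.959 — so `sim_display()` truncates by default and can round instead.

## Similarity

Event similarity is a weighted mean over duration, magnitude and anchor
time of `max(0, 1 - |f_a - f_b| / range_f)`, and 0 across different event
types. The form was chosen for interpretability — each feature contributes
a unit-interval score, the ranges make units irrelevant — and because with
degenerate weights it collapses exactly onto the agreement statistic above,
which the tests exploit as a cross-check. Ranges default to the observed
feature spread of the pooled cohort events (`scaling_from_events()`),
floored at a small positive value; weights default to equal thirds for EEG
and to zero anchor weight for stabilometry, where *when* a fall happened
says little about the athlete. Each weighting is configurable.

Series-level similarity is the maximum-weight one-to-one assignment between
the two event sets (igraph's push–relabel weighted bipartite matching;
events are pre-sorted by position and type so that equal-weight ties
resolve deterministically), normalised Dice-style by `2Σw/(n_a + n_b)` so
unmatched events on either side cost symmetrically. Both sets empty gives
1; one empty gives 0. Subject-level similarity walks the shared tree:
series leaves score as above, quantitative leaves score
`max(0, 1 - |a-b|/range)` (range configurable per variable, defaulting to
`max(|a|, |b|, 1)` so self-comparison is always 1), qualitative leaves
score by equality, and each internal node averages its children with equal
weights — nothing in the domain model privileges one measurement over
another a priori. All similarities are symmetric, bounded in [0, 1] and
reflexive; a structural mismatch reports the first divergent tree path.

## Reference models

All events of the retained training subjects are pooled and clustered per
event type with average-linkage agglomerative clustering on
`1 - event_similarity`, cut at `tau_m = 0.3` (normalised feature units).
Agglomerative clustering was preferred to k-means because the number of
event populations is exactly what we do not know. A cluster enters the
model only if its *support* — the fraction of training series contributing
at least one event to it — reaches `min_support = 0.5`: "events often
found" read as "in at least half the series". Each retained cluster is
represented by its **medoid**, so model events are real observed events
with honest feature combinations, not centroids that may average a long
weak wave with a short strong one into something never seen. Medoid ties
break towards the smallest total distance, then the earliest anchor. The
model records support and cluster size per event and is sorted by anchor
timestamp; if no cluster reaches support the model is *degenerate* and the
build fails loudly rather than returning an empty archetype.

## Outlier screening

Screening works on the pairwise subject-similarity matrix and emulates how
a person reading a cluster picture calls strays. Four criteria vote, and
`vote_threshold = 2` of them flag an outlier:

* **C1, low average affinity**: the subject's mean similarity to the rest
  falls more than `z = 2` robust sd below the cohort's central row mean.
  This criterion uses median and MAD rather than mean and sd: with mean/sd
  a single gross outlier (say, a subject with no detectable events at all)
  inflates the spread and masks a second, milder outlier — we observed
  exactly this masking on synthetic cohorts with two planted outliers.
* **C2, isolation**: the subject's best similarity to anyone is below 0.5 —
  it has no near neighbour.
* **C3, tiny cluster**: average-linkage clustering of `1 - S` cut at
  `tau_c = 0.3` leaves the subject in a cluster smaller than
  `min_cluster_size = 2`. `tau_c` matches `tau_m` deliberately: both cuts
  live on the same normalised-dissimilarity scale, and 0.3 makes a subject
  whose events sit several feature-sd from the cohort a singleton.
* **C4, cohesion damage**: removing the subject raises its cluster's mean
  within-pair similarity by more than `delta = 0.05`; for clusters too
  small for that comparison the whole cohort plays the role of the cluster.

Screening runs inside each training split only — never on held-out
subjects — so cross-validation estimates are not contaminated by decisions
that peeked at the test fold.

## Classification and validation

One reference model per class; a new subject goes to the class of the most
similar model, with exact ties broken towards the lexicographically first
label and flagged in the result. `cross_validate()` stratifies folds by
class (proportions hold within one subject per fold), with an explicit,
logged seed. Accuracy is reported pooled over folds, overall and per class;
per-fold assignments stay available in the result object.

## The synthetic generator

`generate_series()` plants events in Gaussian baseline noise at
non-overlapping uniform-random positions (bounded retries; generation
fails loudly if the series cannot hold the requested events). EEG-like
events are single half-sine deflections with random polarity (an
opposite-polarity flank of 80% amplitude when a spicule is requested);
falls are suprathreshold plateaus. Event counts are Poisson, durations
lognormal (positivity), magnitudes normal. The built-in class
specifications carry the published per-class statistics — epileptic EEG
9.47 events/series, 195 ms, amplitude 78; healthy 5.49/56/54; basketball
3.37 falls/series, 754 ms, intensity 107; skating 1.45/346/83. Only the
means are published, so standard deviations default to 20% of the mean.
The remaining free choices, fixed once: baseline noise sd 10 for EEG and 5
for stabilometry (event magnitudes then sit roughly 5–20 noise-sd above
background, a regime where detection should work and occasionally
doesn't — which is what makes the loop-closure tests informative); series
lengths of 10 s (EEG) and 30 s (unilateral stance); 10 ms sampling
everywhere. Cohort-level outlier injection shifts a planted outlier's
duration and magnitude means by `outlier_shift_sd` (default 5) generator-sd
units with an **independent random sign per feature**, so anomalies point
either way and two outliers rarely resemble each other.

What the generator does *not* emulate: real EEG background spectra (the
noise is white), multichannel montages, sway dynamics between falls,
artefacts (eye movements, muscle noise — the study data were pre-screened),
or expert disagreement. Passing tests on these cohorts therefore shows the
pipeline's machinery is correct under the stated statistical structure, not
that it would match clinical performance figures; the published
cohort-scale accuracies depend on recordings the package does not ship.

## Problem sizes in the test suite

The suite validates the cohort-scale claims at sizes a laptop handles
comfortably: the classification stand-in uses 20 subjects per class with
10-fold cross-validation over 5 seeds; loop-closure agreement pools 100 EEG
and 60 stabilometric series; outlier recovery pools ten 20-subject cohorts
with 10% injected outliers; the assignment solver is checked against an
exhaustive oracle on 200 instances with at most six events per side. All
stochastic tests fix their seeds and assert frozen outcomes.

## Known limitations

* The comparison and model-generation algorithms are reconstructions
  faithful to the published contracts (feature-characterised events,
  cluster-medoid models, four-criteria outlier voting, maximum-similarity
  classification); the cited original formulations are not public, so exact
  functional forms here are the package's own documented choices.
* Wave segmentation by zero crossings assumes a roughly stationary mean; a
  strong drift would need detrending upstream.
* The ≥ 70% retention rule validates a series globally; it does not detect
  locally corrupted stretches that happen to keep the global count high.
* Subject trees must share structure exactly; there is no partial matching
  of records with missing branches.
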