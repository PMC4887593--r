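# tsevents

Event-centric analysis of biomedical time series: detect domain-defined
events, compare subjects by the similarity of their events, distil a cohort
into a class *reference model*, and classify new subjects against those
models.

Many clinical signals carry their diagnostic content in short, sparse
episodes rather than in the waveform as a whole: paroxysmal abnormalities in
an EEG (spike waves, sharp waves, spicules), or *falls* in a posturographic
unilateral-stance test, where the raised foot touches the platform and the
sensor pressure exceeds a threshold ∂. Whole-series distances (Euclidean,
DTW, spectral) average those episodes away. `tsevents` is for researchers
who want the opposite: everything keys on the events.

## The method

1. **Event definition and detection.** Events are declared, not hard-coded.
   A *relative-amplitude* rule turns a wave — a run of the mean-centred
   signal between zero crossings — into an event when its peak deviation
   exceeds `k` robust standard deviations (MAD) of the signal and its period
   lies in a window (spikes 20–70 ms, sharp waves 70–200 ms; a spicule is a
   sharp wave flanked by a prominent opposite-polarity wave). An
   *absolute-threshold* rule turns each maximal run of samples above ∂ into
   an event (falls). Every event is characterised by its duration, its
   magnitude (peak amplitude or mean suprathreshold intensity) and its
   anchor (the extremum's timestamp).

2. **Agreement with experts.** A detected event set is scored against a
   reference annotation with the Dice-style statistic

   SIM = 2·#matched / (#expert + #detected) ∈ [0, 1],

   where events match when types agree and intervals overlap at least half
   of the shorter event (maximum-cardinality bipartite matching).

3. **Similarity.** Two event sets are compared by a maximum-weight one-to-one
   assignment under a per-event similarity (weighted, range-normalised L1
   over duration, magnitude and anchor time, gated on event type), with the
   same Dice normalisation `2·Σw/(n_a + n_b)`. Subjects — modelled as a
   register → measurement → condition → leaf tree — are compared bottom-up,
   series leaves by event similarity, value leaves directly, each node
   averaging its children.

4. **Reference models and outliers.** For each class, all training events
   are pooled and clustered (average linkage on 1 − similarity, cut at
   τ_m); clusters supported by at least half of the training series
   contribute their medoid event to the class model — an archetypal
   pseudo-subject. Before modelling, subjects are screened on the pairwise
   similarity matrix by four voting criteria (low average affinity,
   isolation, tiny-cluster membership, cohesion damage); two votes flag an
   outlier.

5. **Classification.** A new subject is assigned to the class
   C_j = argmax_i similarity(P_new, M_i). A stratified k-fold
   cross-validation harness reports pooled and per-class accuracy.

A seed-deterministic generator produces synthetic cohorts with planted,
exactly-known events matching published per-class statistics (epileptic EEG:
9.47 events/series, 195 ms, amplitude 78; healthy: 5.49, 56 ms, 54;
basketball stabilometry: 3.37 falls, 754 ms, intensity 107; skating: 1.45,
346 ms, 83), so the whole pipeline is testable without any clinical data.

## Worked example

```r
library(tsevents)

coh      <- generate_cohort(eeg_class_specs(), n_per_class = 20, seed = 7)
subjects <- annotate_cohort(coh, paroxysm_definition())
clf      <- train_classifier(subjects, domain = "eeg")
tidy(clf)
#> # A tibble: 2 x 9
#>   class_label event event_type duration_ms magnitude anchor anchor_ms support
#>   <chr>       <int> <chr>            <dbl>     <dbl>  <int>     <dbl>   <dbl>
#> 1 epileptic       1 paroxysm           210      86.7    533      5330       1
#> 2 healthy         1 paroxysm            80      61.5    517      5170       1

cross_validate(subjects, k = 10, seed = 7, domain = "eeg")
#> <cv_result> 10-fold CV, 40 subjects, overall accuracy 95.00%
#>   class_label     n correct accuracy
#> 1 epileptic      20      19       95
#> 2 healthy        20      19       95
```

Each class model is a table of representative events — here one archetypal
paroxysm per class, long and tall for the epileptic cohort (210 ms,
amplitude 87), short and weak for the healthy one (80 ms, 62) — and the
classifier separates the two synthetic cohorts at 95% accuracy under
10-fold cross-validation.

Detection closes the loop on planted ground truth:

```r
ann <- generate_series(stabilometry_class_specs()$basketball, seed = 3)
det <- detect_events(ann$series,
                     fall_definition(50, min_duration_ms = 100, merge_gap_ms = 100))
match_event_sets(ann$events, det$events, min_overlap = 0.5)
#> <evaluation_counts> expert 6 | detected 6 | matched 6 | SIM 1.0000
```

`autoplot()` methods draw annotated series and cross-validation summaries;
`plot_similarity_matrix()` draws cohort similarity heatmaps. A thin command
line (`inst/cli/tsevents`) exposes `simulate`, `detect`, `evaluate`,
`compare`, `model`, `classify` and `cv` subcommands over YAML configs.

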