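---
title: "Quantifying paroxysmal sympathetic hyperactivity from vital-sign trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paroxysmal sympathetic hyperactivity from vital-sign trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshkit)
```

## The problem

Paroxysmal sympathetic hyperactivity (PSH) is a syndrome of recurrent,
abrupt-onset sympathetic surges — simultaneous elevations of heart rate (HR),
respiratory rate (RR), systolic blood pressure (SBP), and other features —
seen in a substantial fraction of critically ill patients after acquired
brain injury. Bedside monitors in the ICU stream vital-sign *trend* data
(nominally 0.5 Hz, one sample every 2 s), but routine PSH assessment relies
on hourly chart values and subjective recall, which miss short episodes
entirely. `pshkit` implements three automated quantification methods that
use only the objective trend data:

1. an hourly **high-resolution Clinical Feature Scale (hrCFS)**, a 0–9
   severity score built from the HR/RR/SBP threshold bands of the standard
   clinical feature scale;
2. a rule-based **expert-system (ES) episode detector** over sliding
   HR windows;
3. a **support-vector-machine (SVM) episode detector** over rolling-window
   HR summary features,

together with the **episode burden score** (temporal density of episodes),
12-hour burden trends, cohort summaries with Cohen's d effect sizes, and
**range-based precision/recall** for scoring detected against annotated
episode intervals. A synthetic vital-sign simulator with ground-truth
episodes makes the whole pipeline testable end to end without any patient
data.

## Conventions shared by every module

* **Time** is measured in seconds from *time zero*, the first recorded
  sample of the patient's monitoring record. Hours, analysis windows, and
  trend windows are all anchored there, not to the wall clock.
* **Every interval is half-open**, `[start, end)`. This makes windows that
  tile a record partition it exactly — no sample is counted twice at a
  boundary — and makes abutting episodes overlap by zero.
* **Window statistics** use the *population* variance (divide by `n`). The
  ES variance rule was calibrated on ~300-sample windows, where the
  population/sample distinction is far below the rule's resolution, and the
  population form is defined (zero) for a single sample. The median of an
  even-sized window is the midpoint average.
* **Artifact filtering** keeps samples inside a closed plausibility
  interval; a value equal to a bound is physiology, not artifact, so bounds
  are inclusive. HR uses the adult normal reference range 30–250 bpm. No
  equivalent published bounds exist for the other two trends, so RR
  [4, 80] breaths/min and SBP [40, 300] mmHg are package defaults chosen on
  the same plausibility principle; both are arguments, not constants.

## The hourly hrCFS

Each signal hour `[3600h, 3600(h+1))` is scanned by 5-minute rolling windows
with 50% overlap: start offsets 0, 150, …, 3450 s — 24 windows per hour. The
24th window would overrun the hour, so it is truncated to its final 2.5
minutes; that keeps exactly 24 values per hour without letting one hour's
score see the next hour's data. The hourly summary value is the maximum of
the per-window maxima (for a fully covered hour this equals the plain hourly
maximum; the windowed construction is retained because it is the defined
procedure and exposes per-window values for inspection), and is then scored
0–3 per signal:

| Score | HR (bpm) | RR (breaths/min) | SBP (mmHg) |
|------:|---------:|-----------------:|-----------:|
| 0 | <100 | <18 | <140 |
| 1 | 100–119 | 18–23 | 140–159 |
| 2 | 120–139 | 24–29 | 160–179 |
| 3 | ≥140 | ≥30 | ≥180 |

The composite hrCFS is the sum of the three subscores, range 0–9. Sweating,
posturing, and temperature — the remaining features of the full clinical
scale — cannot be derived from these trends and are out of scope.

**Missingness.** The defined procedure assumes dense data; real records have
gaps. A signal-hour whose coverage (observed / expected samples at 0.5 Hz)
falls below `min_coverage` yields a missing subscore, and the composite is
missing unless all three subscores exist. The default `min_coverage = 0.5`
asks an hourly *maximum* to have seen at least half the hour; it is exposed
as an argument because no principled universal value exists.

```{r}
ts <- seq(0, 3598, by = 2)
rec <- compute_hrcfs(vital_series("p1", "HR", ts, rep(150, 1800)),
                     vital_series("p1", "RR", ts, rep(25, 1800)),
                     vital_series("p1", "SBP", ts, rep(165, 1800)))
rec
```

## The expert-system detector

Clinician-annotated PSH episodes show a sudden HR rise to a stably elevated,
high-variance plateau. The ES detector encodes this as three parameterized
rules on each 10-minute window, stepped densely (2 s) through the record:

* HR minimum > *a* (default 95 bpm),
* HR median > *b* (default 104 bpm),
* HR variance > *c* (default 37 bpm²),

all strict inequalities. A window votes positive when at least 2 of the 3
rules hold; a sample's final label is the **maximum vote over every window
covering it**, so one positive window marks its whole span. Empty windows
(data gaps) vote negative rather than abstaining, so a monitoring dropout
cannot create positives. The window grid is anchored at time zero.

The defaults (95, 104, 37) are the rule set derived from single-patient
annotated training data; `grid_search_rules()` re-derives such a triple on
any annotated record by exhaustive search, scoring each candidate by
range-based F1 = 2PR/(P+R). The scalarization is this package's choice — the
derivation procedure is described only as jointly optimizing precision and
recall — and ties prefer the more conservative (larger) thresholds.

Dense stepping over multi-week records needs exact sliding statistics:
`pshkit` maintains a Fenwick tree over rank-compressed values (order
statistics in `O(log n)` per window, each sample entering and leaving the
active set once), with sums kept in extended precision on mean-centered
values. Approximate medians are not acceptable here because the median rule
is a strict threshold. A relative dead-band (1e-9) clamps the variance of
constant windows to exactly zero, where floating-point cancellation would
otherwise leave residues of order 1e-15.

## The SVM detector

The machine-learning detector summarizes each 10-minute window by five
features — mean, standard deviation, minimum, maximum, median — on a
2.5-minute step (75% overlap; the coarser step limits redundancy between
neighbouring training windows). Training labels come from annotated
episodes: a window fully inside an episode is positive, a window disjoint
from every episode is negative, and a window straddling an episode boundary
is **excluded** — its mixed statistics belong to neither class. Features are
standardized to the training set and fed to an RBF-kernel SVM
(regularization cost 1; kernel width `1/(n_features × mean feature
variance)` of the standardized features; no class rebalancing — all exposed
as arguments since no reference values exist for them). Prediction reuses
the training geometry (150-s step) so that prediction-time feature
distributions match training, then applies the same per-sample max-fusion as
the ES detector.

**Known limitation — boundary-window overhang.** At detection time the model
must also classify the straddling windows it never trained on. A window
mixing ~25% episode with ~75% baseline has a bimodal value distribution: its
standard deviation and maximum exceed even the positive class's range, so
any RBF boundary fit to the two pure classes classifies it positive, and
max-fusion then marks its full 10-minute span. Detected episodes therefore
systematically overhang the true episode by several minutes on each side.
Recall is unaffected (episodes are fully covered), but range precision is
bounded by roughly `d/(d + 2·overhang)` for a true episode of duration `d` —
the bundled acceptance tests quantify this on simulated patients, where the
ES detector (whose minimum rule suppresses mixed windows below ~50% overlap)
reaches the 0.8 precision mark and the SVM detector falls short of it. This
is a structural property of window-level classification with max-fusion, not
of any particular hyperparameter setting; the tests demonstrating it probe
cost, kernel width, and class weights.

## Episodes, burden, and trends

Point labels become episodes by run-length assembly: each maximal run of
consecutive positive samples becomes `[t_first, t_last + 2 s)` — the episode
extends one sampling period past its last positive sample, keeping intervals
half-open on the sampling grid. A sampling gap longer than
`max_sample_gap_s` (default 60 s, deliberately aligned with the merge
threshold) splits a run, so dropouts do not silently bridge episodes.
Episodes separated by a break *strictly* shorter than 1 minute are then
merged, transitively; a break of exactly 60 s survives.

The **burden score** over a frame `[t0, t1)` of length `T` is

$$B = \frac{1}{T}\sum_n |\varepsilon_n \cap [t_0, t_1)|,$$

the fraction of the frame covered by episodes (`ε_n`): 2 cumulative hours of
episodes in a 4-hour frame give `B = 0.5`, whether as one long or many short
episodes. Burden trends evaluate `B` on consecutive 12-hour windows from
time zero (28 windows over 14 days); a trailing partial window is scored
over its actual length. Cohort summaries report episode count, mean episode
duration, and 14-day burden, compared between groups by Cohen's d with the
pooled sample standard deviation; trend bands use the t-distribution CI
`mean ± t·sd/√n` per window — the natural small-cohort choice.

## Range-based precision and recall

Detected and annotated episodes are *intervals*, so point-wise confusion
counts are ill-posed. Following the interval-metric family of Tatbul and
colleagues, each detected episode `P_i` scores the fraction of its duration
covered by the union of annotations, and precision is the unweighted mean
over detected episodes; recall is symmetric (annotated episodes against the
union of detections). Among the family's variants this package uses the
simplest member — flat positional bias, no existence bonus, cardinality
factor 1 — because only the outer averaging is pinned down by the method's
description; the inner per-episode function is isolated in one place if
another variant is wanted. Under this variant precision and recall are dual:
`precision(R, P) = recall(P, R)`, a property the test suite exercises.

When the reference set of a metric is empty the metric is *undefined* (`NA`
with a warning), not 0 or 1: any numeric convention there would silently
distort cohort averages.

## The synthetic simulator

`simulate_patient()` generates the clinical conditions the detectors target:

* **Baseline**: per-signal AR(1) Gaussian noise on the 0.5 Hz grid with
  lag-1 autocorrelation φ = 0.95 and marginal sd at the configured baseline
  spread (HR 80 ± 5 bpm, RR 14 ± 2, SBP 120 ± 8). AR(1) is the simplest
  process reproducing the slow wander of real trend data; φ = 0.95 at 2-s
  sampling gives a ~40 s correlation time, enough that 10-minute windows see
  realistic within-window structure.
* **Episodes**: Poisson arrivals at 4/day; durations log-normal,
  moment-matched to mean 42 min / sd 16 min and truncated to [2 min, 2 h] —
  the annotated-episode statistics the detectors were built against.
  (Clinical descriptions also mention occasional episodes of three or more
  hours, which a 16-min sd cannot produce; the simulator matches the stated
  moments and the typical 2 min–2 h phenomenology.) Candidate episodes that
  would overlap or leave an inter-episode gap under 2 min are rejected,
  thinning the realized count slightly below the nominal rate.
* **Elevation**: within an episode each signal's mean shifts by its delta
  (HR +35 bpm, RR +12, SBP +45 — simultaneous multi-signal elevation, as in
  the syndrome) with 30-s linear onset/offset ramps, and the noise sd is
  inflated ×2. The ground-truth intervals record the sustained cores,
  excluding ramps.

What it deliberately does **not** emulate: circadian rhythm, medication
effects, cardiorespiratory coupling, realistic artifact morphology, or
missing-data patterns. Passing recovery tests on this generator shows the
pipeline detects abrupt sustained elevations against an autocorrelated
baseline — it does not certify performance on real ICU data, where baseline
nonstationarity and artifacts are the dominant error sources.

## Problem sizes in the test suite

The unit and property tests run on seconds-to-hours of simulated signal;
oracle-equivalence properties use short irregular series with coarsened
window grids so the brute-force oracles stay tractable. The end-to-end
acceptance checks use full 14-day, 0.5 Hz patients (604,800 samples per
signal) and a 4-patient demo cohort — the same record length the cohort
methods summarize — which completes in about a minute on a single core
thanks to the sliding-statistics structure.

## Reproducibility

Every stochastic entry point takes an explicit seed: identical seeds give
bit-identical simulations, training sets, models (the underlying libsvm fit
is deterministic given data order), detected episodes, and demo reports.
Cohort simulation derives independent per-patient seeds from the master seed
so patients are reproducible individually.
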