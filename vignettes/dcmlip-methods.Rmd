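---
title: "Models and methods behind dcmlip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcmlip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmlip)
```

# The scientific problem

In a delayed-conjunction-matching (DCM) task, a monkey is cued by a sample
stimulus — a conjunction of a color (8 levels, yellow to red) and a motion
direction (8 levels, 45° apart), at one of two screen locations — and must
release a lever when a later test stimulus matches the sample in location,
color and direction. Two sample identities are used: A (yellow, downward) and
B (red, upward), so the same physical stimulus is a *target* on some trials
and an *opposite-target* (to be ignored) on others. Neurons in the lateral
intraparietal area (LIP) recorded during this task carry two distinct signals
about each test stimulus: *identity selectivity* (stimulus A vs B, regardless
of behavioral relevance) and *match selectivity* (target vs opposite-target,
regardless of physical identity). `dcmlip` implements the full analysis chain
that separates, times, decodes and relates these signals, together with a
task-driven spike-train simulator so that every stage is testable without
access to recorded data.

# The data model

A `dcm_neuron` bundles a trials table (sample, attention IN/OUT of the
receptive field, outcome, reaction time), an events table (one row per test
or distractor stimulus, with color, direction, onset and a match class
computed against the trial's sample) and one spike train per trial, in ms
from trial start. Two task variants are supported: two-location (450-ms
sample/delay/test epochs, up to 4 test stimuli, 20% catch trials, simultaneous
distractors in the opposite hemifield) and one-location (550-ms epochs, up to
3 tests, 25% catch, no distractors). All windowed analyses use half-open
windows `[t0, t1)` relative to an event onset; a spike exactly at the upper
bound falls in the next window. Datasets round-trip through a plain CSV
bundle (portable, human-readable) and an RDS container (hierarchical binary);
neither format is prescribed by any recording system — the schema is the
package's own.

# The synthetic generator

The generator is a first-class module, not a test fixture: its defaults *are*
the study conditions the analyses are meant to face.

Each simulated neuron draws spikes from an inhomogeneous Poisson process at
1-ms resolution with rate

```
rate(t) = floor0[ baseline * attention_gain^[attend IN]
                  * (1 + memory_gain * 1[preferred sample])
                  + identity_term(t) + match_term(t) + feature_terms(t) ]
```

* The **continuum weight** `w` maps one parameter onto the empirically
  observed continuum from identity- to match-selective cells:
  `amp_identity_eff = amp_identity * (1+w)/2`,
  `amp_match_eff = amp_match * (1-w)/2`. The map is monotone in the expected
  visuo-decision index (VDI), which is what parameter-recovery tests rely on.
* **Response onsets are steps** (optionally with a 20-ms linear rise).
  A parametric PSTH shape is not imposed; steps keep latency ground truth
  unambiguous, at the cost of sharper transients than real data.
* The **match term** steps on `latency_match + shared_jitter` ms after target
  onset. `shared_jitter` is a per-trial latent draw that also enters the
  reaction time as `rt = rt_mean + cp_coupling * shared_jitter + noise`
  (Gaussian, truncated at 150 ms by redrawing the independent component).
  This single latent variable is what produces negative choice-probability
  values for match-coupled cells: an earlier match response on a given trial
  predicts a shorter RT.
* **Feature terms** implement a linear color ramp (Hz per color step,
  centered on color 4.5) and a von-Mises-shaped direction tuning curve.
  Feature-based attention is modeled as a displacement of the tuning curve
  toward the currently relevant feature. For direction this is a rotation of
  the preferred angle (by `fba_direction_shift_deg`, along the shorter arc).
  For color, a pure translation of a *linear* ramp would leave its fitted
  slope unchanged — and the slope difference is precisely the measured
  statistic — so the displacement is implemented as a rotation of the ramp
  about the color-axis midpoint: under the sample whose relevant color is 1
  the effective slope decreases by `fba_color_shift`, under relevant color 8
  it increases. This yields `slope_A - slope_B < 0` for shifts toward the
  relevant color, the field's sign convention.
* **Behavioral model**: non-catch trials are hits/misses/false alarms with
  probabilities 0.90/0.06/0.04; target sequence position is drawn from
  configurable weights whose default over-represents position 1
  (0.40/0.22/0.20/0.18), reproducing the detection-rate artifact the
  choice-probability control is designed to catch. Pre-target test stimuli
  are opposite-targets with probability 0.25 and otherwise uniform draws from
  the remaining 62 conjunctions; neither the true RT distribution nor the
  true position-sampling law is published, so these are stated defaults, not
  fitted values. False-alarm trials truncate at the responded stimulus.
* A trial-schedule generator note: one modeling simplification worth knowing
  is that an identity "step" term that fires only for the preferred
  conjunction is itself a super-additive conjunction detector. When a test
  needs identity-selective cells that combine features *additively* (the
  additivity analyses), the identity drive should come from the feature
  terms, which is also the substantive model of identity selectivity in LIP
  (linear pooling of feature-tuned inputs). The helper profile used in the
  package's tests does exactly that.

What the generator does **not** emulate: correlated noise across neurons,
firing-rate adaptation, trial-history effects, saccade-related activity, or
non-Poisson spiking statistics. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the estimators under the task
structure — not that real LIP data will show any particular effect size.

# Equalization by randomized decimation

Sample-memory activity elevates firing throughout trials of the preferred
sample, which masquerades as pre-onset "identity selectivity"; space-based
attention similarly inflates attention-IN activity. Before selectivity
analysis, the higher-rate condition's spike trains are thinned: the ratio of
mean rates in the 200-ms pre-test windows (`[-200, 0)` ms before each test
stimulus) determines a removal fraction `1 - lower/higher`, and each spike in
the target condition's test period is independently retained with the
complementary probability. Bernoulli thinning (rather than removing an exact
count) preserves Poisson statistics exactly; an exact-count mode exists for
sensitivity checks. For the attention grouping, windows preceding the first
test stimulus are excluded from the ratio — they sample the delay epoch, not
visually driven activity. Decimation touches only test-period spikes
(from the first test onset to the trial end); the 200-ms window before the
*first* test stimulus lies in the delay and is not decimated, so pre-onset
equalization is exact only from sequence position 2 onward. Error trials are
excluded from the ratio (all analyses operate on correct trials).

# Sliding-ROC selectivity, latencies and the VDI

At every window center `t` (1-ms steps), spike counts in `[t-100, t+100)`
are compared between conditions with the area under the ROC curve
(Mann–Whitney U scaled to [0,1], ties counted ½) and a two-sided Wilcoxon
rank-sum test (normal approximation with tie and continuity corrections).
Significance is Bonferroni-corrected over the number of window centers in
the trace at familywise 0.01 — the family is per trace per neuron, a choice
that must be stated because no convention pins it down. The window's value is
assigned to its *center*; this is the only assignment consistent with
reporting latencies shorter than half the window. The cost is a known early
bias: a strong response step at latency L becomes detectable once enough of
the window overlaps it, up to ~half a window before L. The latency estimator
(earliest time in `[0, mean session RT]` starting ≥100 consecutive
significant ms) therefore recovers *orderings* faithfully but absolute
latencies with a negative bias that grows with effect size.

Identity traces are oriented preferred-vs-nonpreferred (preference fixed from
mean rates at 100–350 ms); match traces are oriented target vs
opposite-target. The VDI summarizes both over 100–350 ms:
`mean(2|ROC_id - 0.5|) - mean(2|ROC_match - 0.5|)`, +1 for purely
identity-coding and -1 for purely match-coding cells. "Corrected ROC" here
always means ROC computed after decimation-based equalization, not a
post-hoc transform.

# Population decoding

Pseudo-populations are built by resampling each neuron independently (the
neurons were recorded sequentially; no attempt is made to fabricate
simultaneity). For the identity scheme each class draws, per neuron, 70
target and 70 opposite-target presentations of the same stimulus for
training and 30+30 for testing; the match scheme pools targets (A and B)
against opposite-targets; the sample scheme uses 70/30 whole-trial draws.
Test draws come from source events never used in training: each
sub-condition's events are partitioned 70/30 into training and testing source
pools per iteration, and draws are with replacement within a pool. Features
are per-neuron window counts, standardized with training-set statistics only
(standardization and the 10-ms decoding step are stated choices — published
methods leave both open; a 1-ms step is available behind the `step_ms`
argument). The classifier is a linear SVM (`e1071`, cost 1). A time point is
significant when accuracy beats chance on strictly more than 99% of
iterations (the 990/1000 rule).

# Laterality of match signals

Match selectivity measured separately for targets inside vs outside the RF
(after attention equalization) yields a laterality index `ROC_in - ROC_out`.
The permutation test bootstraps 1000 ROC values per side (resampling trials
with replacement within condition) and asks whether strictly more than 95%
of the 10⁶ pairwise IN-minus-OUT differences are positive. The 10⁶
differences are never materialized: sorting one side and counting strict
exceedances with a binary search gives the exact tail fraction, and ties
count as not-positive (conservative). The neuron-level classification
aggregates over a single 100–350 ms window (the aggregation epoch is not
prescribed anywhere; it matches the VDI window and is a parameter). A
match-selective neuron without a significant IN/OUT difference is
*bilateral* — its match signal does not depend on stimulus location, which
rules out a purely retinotopic account but deliberately does not adjudicate
between decision, motor-preparation or reward interpretations.

# Conjunction additivity

Responses to the four stimulus classes — target (T), color-match (CM,
relevant color with an irrelevant direction), direction-match (DM), and
opposite-target (OT) — are averaged at 100–350 ms and normalized per neuron
by the mean rate over all test windows. The normalization affects display
only: the additivity index `(T - OT) - ((CM - OT) + (DM - OT))` is invariant
to adding a constant to all four terms, and is exactly zero whenever the
means decompose additively as `T = C + D + I`, `CM = C + I`, `DM = D + I`,
`OT = I`. The latent color/direction/irrelevant components are never
individually identifiable — only the index is. CM and DM use *any*
irrelevant partner feature (7 conjunctions each) rather than specifically
the opposite-target's partner: the strict definition would rest on a handful
of presentations per session. The population summary orders neurons by VDI
and applies a 31-neuron moving average (width is a display parameter).

# Choice probability

For each neuron, qualifying trials are hits with the target at sequence
position ≥ 2 (position 1 is over-presented and would couple RT to trial
epoch) on trials whose sample is the neuron's preferred identity. Each
trial's 1-ms rate is smoothed with a Gaussian kernel (σ = 15 ms, truncated at
±4σ, edge-renormalized), z-scored per time point across trials, and
correlated with RT at every millisecond after target onset. Z-scoring per
time point is the standard choice-probability convention (it removes the
PSTH); since Pearson correlation is invariant to per-time affine transforms,
it changes no r value but fixes the interpretation. The scalar summary is
the mean of r(t) over 100–350 ms, matching the VDI window. Time points with
zero across-trial variance are flagged degenerate and contribute r = 0.

# Numerical and degenerate-input conventions

* Rank-sum p-values use the normal approximation with tie correction; a
  window where every count is identical gets p = 1.
* A selectivity latency is absent (NA), not zero, when no qualifying run
  exists; absence is a valid result and propagates as NA through population
  statistics.
* Preferred direction is undefined (NA) when the resultant vector is shorter
  than 10⁻⁶ of the total rate mass (perfectly flat or silent tuning).
* The decimation plan refuses to decimate when one condition is silent
  (flagged, no change) and errors when both are.
* All stochastic steps (generation, thinning, resampling, decoding draws)
  take explicit seeds; identical config + seed reproduces byte-identical
  datasets and results.

# Problem sizes used in the shipped checks

The package's own test suite exercises the pipeline at desk scale, chosen to
make every calibration readable in minutes on a single core: sessions of
150–900 trials, populations of 5–30 neurons, 200 null neurons for familywise
calibration, 200–400 bootstrap/decoding iterations where the published
procedure uses 1000, and 20 seeded runs for latency-ordering recovery. The
1000-iteration defaults remain the package defaults; the reduced sizes are
test-time choices only.

# Specificity of the laterality rule

The ">95% of bootstrap differences" criterion deserves a calibration note:
it behaves as a one-sided test at roughly the 5% level per direction, and
the three-way classification applies it in both directions. A genuinely
bilateral neuron therefore has a ~10% chance of being called unilateral
(about 5% per side); simulations in the test suite reproduce this almost
exactly (90/100 bilateral, misclassifications split evenly between the two
unilateral labels). Treat the bilateral/unilateral split as a screening
classification with ~90% specificity, not a 95% one — only degenerate,
ceiling-response neurons do better, because bootstrap ties then suppress
both tails.

# Known limitations

* Absolute latencies carry the center-assignment bias discussed above;
  compare latencies, don't take them at face value.
* The Bernoulli thinning equates rates in expectation, not per realization;
  audits should use large trial counts.
* Pseudo-population decoding discards cross-neuron noise correlations by
  construction.
* The generator's behavioral model is minimal (no fixation breaks, no
  RT-dependent miss structure); behavior functions report what the schedule
  contains, nothing more.
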