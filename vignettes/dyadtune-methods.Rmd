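---
title: "Methods: classifying behaviorally tuned neurons in dyadic dominance contests"
author: "dyadtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying behaviorally tuned neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtune)
```

## The problem

When two rats compete in a tube test, six behaviors can be scored frame by
frame for *both* animals: MOVE FORWARD, PUSH, RESIST, RETREAT, WITHDRAWAL and
STILLNESS. A miniature endoscope records prefrontal calcium activity (dF/F,
20 Hz) from one animal per session. The scientific question is whether a given
cell's firing is informative about the imaged animal's *own* behavior, about
the *partner's* behavior, or only about their *conjunction* — and how reliable
and stable that tuning is.

`dyadtune` implements this analysis end to end: event detection from dF/F,
Gaussian rate convolution, a Kraskov-type mutual information score (MIS) per
cell and behavior calibrated against circular-shuffle nulls, a taxonomy of
tuned cells, and the derived reliability / consistency / event-rate /
dominance / population-activity summaries. A synthetic dyad generator with
planted ground-truth cells makes every stage testable without recordings.

## The data model

A `DyadExperiment` holds one dyad: per-session `SummarizedExperiment`s with
the imaged animal's traces (assay `"dff"`, cells x frames) and frame-level
annotations (`trial`, `behavior_own`, `behavior_other`), plus the dyad's bout
table and trial records. Frames are 0-based and half-open: frame `f` covers
`[f/20, (f+1)/20)` s, and a bout boundary falling exactly on a frame time
belongs to the later bout. Recordings alternate between the two animals on
odd/even sessions, mirroring a single-camera protocol. Intertrial frames are
stored but never analyzed.

## The synthetic dyad generator

The generator *defines* the study conditions; its defaults are fixed, not
tuning knobs:

* 10 sessions x 5 trials; trial durations uniform on 5-60 s (the observed
  range of tube-test encounters); intertrial intervals 10-20 s.
* Behavior is a semi-Markov chain driven by the trial winner with log-normal
  bout durations (medians 1.2-4 s; STILLNESS longest and most frequent). The
  partner's behavior is drawn per driver bout from a 6 x 6 coupling matrix
  `P(partner | driver)`. Defaults encode the qualitative dyadic structure:
  PUSH answered mostly by RESIST or RETREAT, driver RESIST implying partner
  PUSH, largely shared STILLNESS — while keeping all other conditionals away
  from 0/1 (see *Identifiability* below).
* Each trial ends with a scripted loser bout: RETREAT if the winner is
  advancing, WITHDRAWAL if the winner is still. Under the `strong` dominance
  profile the designated winner wins every trial and never retreats or
  withdraws — an all-or-none profile is the only one consistent with
  loser-only terminal behaviors; `moderate` uses a 0.7 win probability.
* Calcium transients rise linearly over 2 frames to peak 1 dF/F and decay
  exponentially with a 0.5 s time constant (truncated at five constants),
  with 20% multiplicative amplitude jitter and additive Gaussian noise
  (default sd 0.05 dF/F).
* Planted cells: `unique-own` / `unique-other` cells emit at least one event
  in a fraction `reliability` of the target behavior's bouts (own or
  partner's), `coincident` cells only within own x partner conjunction
  intervals, `mixed`/`nonspecific` cells across two / three behaviors,
  `untuned` cells as homogeneous Poisson trains. Default rates: 0.15
  events/s within bouts for tuned cells (the order of magnitude of observed
  per-behavior event rates) and 0.05 events/s for untuned background cells
  (sparse spontaneous activity, typical of GCaMP6f in cortex). Event times
  are uniform within the bout. A planted behavior absent from a session's script
  degenerates that cell to untuned, with a warning recorded in the ground
  truth.

What the generator does **not** emulate: imaging noise structure (motion,
neuropil contamination, cross-talk), cell-to-cell correlations beyond shared
behavior, session-to-session drift in tuning, or genotype effects. Passing
tests therefore demonstrate correctness of the *analysis* under a known
generative model, not robustness to every artifact of real recordings.

## Event detection

The OASIS deconvolution used with raw imaging data is replaced by a
transparent threshold detector operating on the smoothed
(moving-average, 5 frames), baseline-subtracted trace (running 20th
percentile over 30 s, for slow-drift removal). A transient is accepted when
the trace rises at least `s_min` above the running minimum since the previous
event — a prominence rule, so transients stacked on a decaying shoulder are
counted individually — and is stamped at the preceding upward threshold
crossing, with a one-rise (2-frame) refractory gap.

`s_min` defaults to 0.25 with a typical working band of 0.2-0.3. We interpret
it in dF/F units, matching the "minimum transient size" semantics of
deconvolution packages; `threshold_units = "noise"` instead scales by a
robust noise SD (1.4826 x MAD of first differences / sqrt(2)), which errors
on a zero-variance trace. The threshold is per cell and held fixed across all
of a cell's sessions (noise pooled longitudinally).

## Rate convolution and the 12.5 ms sigma

Event trains are convolved with a discrete Gaussian (sd `sigma`, truncated at
two sigma, renormalized to unit sum, scaled by the frame rate) giving an
instantaneous rate in events/s whose time integral equals the event count.
The conventional `sigma` = 12.5 ms is *smaller than one 50 ms frame at
20 Hz*, so the kernel support collapses to a single frame and the "rate" is
just `frame_rate x` the event indicator. We honor the printed value as the
default rather than silently substituting 12.5 frames or 125 ms, and expose
`sigma` so users can choose a physically wider kernel; results in this
package are insensitive to this choice because the MI estimator is
rank-based.

## Mutual information and its null

Pairing a continuous rate with a categorical behavior calls for the mixed
discrete-continuous k-nearest-neighbour estimator (the Ross variant of the
Kraskov-Stogbauer-Grassberger family), `k = 4` by default:

$$ I = \psi(N) - \langle \psi(N_y) \rangle + \psi(k) -
       \langle \psi(m_i) \rangle $$

where, for sample *i*, \(d_i\) is the distance to its k-th nearest neighbour
among same-label samples and \(m_i\) counts all samples strictly within
\(d_i\). Values are converted to bits and clipped at zero. Numerical
choices: heavy ties in the rate series are broken by a minute jitter
(1e-10 of the signal scale, drawn from the caller's RNG stream); labels with
a singleton class are dropped; classes smaller than `k + 1` fall back to
`k = class size - 1`; a single-class label is defined as MIS 0 with a
warning; a cell with no in-trial events scores 0 directly. The
implementation is in C++ with an O(n^2) brute-force R implementation in the
test suite as an independent cross-check, plus a quadrature oracle for a
two-Gaussian mixture.

Chance level is estimated per cell x target by circularly rotating the event
train over the concatenated in-trial frames by a uniform offset of at least
5 s (preserving the train's autocorrelation, unlike i.i.d. permutation),
reconvolving, and rescoring — 2,000 shuffles by default; series shorter than
twice the minimum shift fall back to event-time permutation with a warning.
A target is *significant* when its MIS exceeds the empirical 95th percentile
of its own null **and** events occur in strictly more than 34% of the
behavior's bouts (the occupancy gate; 34/100 bouts is rejected, 35/100
accepted). Because significance requires both conditions, the expensive null
is only computed for targets that pass the occupancy gate.

## Taxonomy

With `S` the number of significant marginal targets (6 own + 6 other
behaviors): `S = 1` gives `unique-own`/`unique-other`; `S = 2` within one
animal gives `mixed`; `S >= 3` gives `nonspecific`; `S = 0` with a
significant own x other conjunction gives `coincident`; otherwise `untuned`.
Two design points were genuinely open and are resolved as follows:

* **Precedence.** Coincident status requires *no* significant marginal —
  coincident cells fire only at the conjunction, and the own/other/coincident
  categories are presented as disjoint. All 36 conjunctions with at least one
  joint bout are candidates, but the joint pass is Sidak-corrected across the
  pairs a cell is actually tested on: testing dozens of conjunctions (often
  with single-digit bout denominators) each at the marginal 5% level would
  otherwise make spurious coincident calls the dominant error mode.
* **Cross-animal pairs.** `S = 2` split across the two animals has no name in
  the source taxonomy; it is reported separately as
  `mixed-across-animals` rather than silently folded into `mixed`.
* STILLNESS encoders are counted but flagged uninterpretable (stillness is
  the residual category), and `nonspecific` here means "three or more
  significant behaviors" (the strict reading), with `untuned` kept distinct.

## Identifiability of own vs. other

Dyadic behaviors are correlated: when PUSH by one animal is almost always
answered by RESIST of the other, a cell locked to own-PUSH *genuinely*
carries mutual information about partner-RESIST. Given enough data both
marginals clear their nulls and the cell lands in `mixed-across-animals` —
not an estimator failure but a limit of what the data can distinguish, the
same own-push/other-resist ambiguity that motivates the joint taxonomy in
the first place. Consequently the class-recovery experiment plants unique
cells mainly on behaviors whose partner conditionals are diffuse
(MOVE FORWARD for the imaged animal; MOVE FORWARD, RETREAT and WITHDRAWAL
for the partner), keeps only a few on the tightly coupled PUSH/RESIST pair,
and avoids STILLNESS entirely (see *Limitations*). Users should expect
own/other separation to degrade for tightly coupled behaviors.

## Derived metrics

* **Reliability** = 100 x occupancy within a session (shared code path).
* **Consistency** (cells registered in >= 2 sessions): percentage of a cell's
  sessions with any encoding classification (`unique-own`, `unique-other`,
  `coincident`, `mixed`), and per behavior the percentage with that specific
  target — a cell can be 100% consistent overall while the encoded behavior
  changes every session. `nonspecific` is not counted as encoding.
* **Event rate** = events within bouts / total bout seconds, pooled within a
  session and then averaged across sessions.
* **Population activity**: per-cell min-max normalization over a session's
  in-trial frames (zero-range traces defined as 0, with a warning; the
  min-max choice makes the summary invariant to per-cell affine rescaling of
  raw dF/F), averaged across cells, grouped by dominance strength x
  winner/loser and by won vs. lost trials. A z-score-based alternative would
  weight cells differently; min-max is the default because it bounds every
  cell's contribution to [0, 1].
* **Dominance**: the overall winner is the animal with most trial wins;
  `strong` requires winning at least 80% of trials (configurable) *and* a
  majority in every session; exact ties are reported as `tied`.

## Problem sizes, power, and runtime choices

The shipped tests run the full machinery at desk scale: null calibration
uses 200 untuned cells with 500-shuffle nulls on a ~5-trial session
(~2-3 x 10^3 in-trial frames); the class-recovery experiment plants
30 + 30 + 10 + 30 cells in one high-SNR 10-trial session (noise sd 0.02,
reliability 0.9) and runs the complete trace-to-taxonomy path; estimator
accuracy is checked at n = 5,000 against quadrature. These sizes give stable
statistics while keeping a laptop run in minutes; production analyses should
use the 2,000-shuffle default.

The recovery experiment's rates are set by an explicit power argument. For a
cell firing only during a behavior occupying a fraction \(p_b\) of in-trial
time, the true MI is roughly \(p_1 \log_2(1/p_b)\) with \(p_1\) the event
fraction of frames, while the 500-shuffle null's 95th percentile for a train
of the same sparsity sets the detection floor. At ~10 events per session the
two coincide (~0.01 bits) and planted tuning is undetectable by *any*
threshold at this significance level; at ~40 events (1.0 events/s within
bouts over 10 trials) the signal sits several-fold above the floor.
Conversely the untuned rate must keep \(P(\ge 1\) event per bout\()\) below
the 34% occupancy gate for the longest bouts (STILLNESS, ~4.8 s mean):
\(1 - e^{-0.05 \times 4.8} \approx 0.21\) at 0.05 events/s, so the gate
binds; at 0.15 events/s it would not (~0.45), and multiple-target testing
would inflate false positives far above the per-target 5%. Coincident cells
tied to rare conjunctions (a handful of occurrences per session) remain
largely undetectable at desk scale — an honest floor of the method, not of
the implementation.

## Known limitations

* The detector is intentionally simple; for low-SNR real data an AR-model
  deconvolution backend would be preferable (the event-table interface is
  the plug point).
* Occupancy with very few bouts is coarse (1 bout gives only 0% or 100%),
  so joint conjunctions with a single occurrence can pass the gate on one
  event; the MIS threshold still applies.
* The 12 marginal targets are each tested at the 5% level without
  multiplicity correction — faithful to the source procedure; the occupancy
  gate is what keeps the practical marginal false-positive rate near the
  per-test level. Only the joint pass carries a Sidak correction (above).
* Tuning to a behavior that dominates the session (STILLNESS) is close to
  undetectable by MI thresholding: the indicator of a prevalent behavior has
  little information to carry, so true MI falls below the null's resolution.
  STILLNESS encoders that do pass are flagged uninterpretable.
* Cross-session cell identity is taken as given (stable `cell_id`s);
  longitudinal registration is out of scope.
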