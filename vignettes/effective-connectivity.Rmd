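---
title: "Inferring effective connectivity from spike trains with cost-sensitive decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring effective connectivity from spike trains with cost-sensitive decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectree)
```

## The problem

Multielectrode recordings deliver simultaneous spike trains from dozens of
units whose anatomical relations are unknown. *Effective connectivity* asks
which of the recorded units influence the firing of a chosen **target**
unit — in the motivating preparation, a primary sensory afferent whose
antidromic (backfiring) discharges are driven by dorsal-horn interneurons.
connectree turns this question into a supervised-learning problem: can the
firing of the target over the next instant be predicted from the recent
activity of the other units, and which units does a parsimonious predictor
actually use?

## From spike trains to a categorical table

Every target spike at time $t$ defines a **positive interval**: the 50 ms
window $(t-50\,\mathrm{ms},\,t]$, labelled 1. The recording time outside the
union of positive windows is tiled, gap by gap, into 50 ms **negative
intervals** labelled 0 (each gap's terminal remainder shorter than 50 ms is
discarded; target spikes in the first 50 ms of the recording have no full
window and are dropped). Within each interval, every predictor unit's spikes
are coded by their 10 ms subinterval: `A` for offsets $[0,10)$ ms before the
timestamp through `E` for $[40,50)$ ms, concatenated alphabetically
(`"BBD"` = two spikes 10–20 ms back and one 30–40 ms back), `"0"` for
silence. Bins are half-open, so an offset of exactly 10 ms codes `B` and an
offset of exactly 50 ms falls outside the window; this removes all
double-counting ambiguity at bin edges. Overlapping positive windows (target
inter-spike intervals below 50 ms) each keep their own row — positives are
never merged.

These are deliberate conventions where the procedure leaves room: they are
stated here once and used everywhere (`extractIntervals()`).

## The classifier

The learner (`fitTree()`) is a categorical decision tree of the C4.5/C5.0
family, written for this package:

* **multiway splits**, one branch per category observed at the node; code
  strings such as `"BBD"` are atomic categories and are not decomposed;
* split selection by **gain ratio**, restricted to attributes whose
  information gain reaches the average gain of the valid candidates; a split
  is valid when at least two branches would receive `minCases` (default 2)
  cases;
* **pessimistic pruning** with the binomial upper confidence limit at
  confidence 0.25;
* **cost-sensitive leaf classes**: a leaf predicts firing when
  $n_1 \cdot c_{FN} > n_0 \cdot c_{FP}$, with default costs
  $c_{FN} = 3.5$, $c_{FP} = 1$ — missing a target spike is 3.5 times worse
  than a false alarm;
* categories unseen in training route to the **fallback branch** (the branch
  that received the most training cases), so prediction never fails;
* optional AdaBoost-style boosting (`trials > 1`), kept at a single tree by
  default because committees dilute the group-frequency histograms (see the
  combinatory analysis below).

One deliberate asymmetry: the cost matrix steers leaf-class assignment and
prediction, but the pruning estimate stays on raw error counts. Folding the
cost ratio into the pessimistic estimate systematically collapses exactly
the subtrees that separate coincident-input patterns (two units firing
within the same window) from single-spike patterns, and those conjunctions
are the structure the whole analysis relies on; with plain-error pruning the
complete-dataset MCC of the reference run rises by roughly 0.15.

Class imbalance is severe (a sparse target yields one positive per dozens of
negatives), so models are fit on **snap data**: all positives plus four
times as many randomly chosen negatives (`snapSample()`, ratio 1:4),
split 80/20 into training and validation, stratified by class with floor
rounding. Metrics — precision, recall and the Matthews correlation
coefficient (MCC) — are reported on training, validation, snap and the
complete dataset; the complete dataset is the realistic yardstick, and MCC,
being balanced, is the headline number. Zero denominators in any metric
fall back to 0. Because undersampling is random, summaries are repeated over
30 seeds (`runMultiSeed()`) and reported as mean ± SEM (sample SD / √n).

## The search procedures

* **Direct** (`directAnalysis()`): one model on all units; its *primary
  group* is the set of units with positive variable importance (C5.0's
  "usage" metric: the percentage of training cases that pass a split on the
  unit).
* **Individual** (`individualAnalysis()`): one single-unit model per unit,
  ranked by complete-set MCC; all units share one snap partition so the
  numbers are comparable.
* **Combinatory** (`combinatoryAnalysis()`): one model per nonempty unit
  subset — $2^n - 1$ fits, 8191 at $n = 13$ — ranked by complete-set MCC.
  The *relevant group* is read from the frequency with which units appear in
  the top percentile of the ranking: the first $\lceil 0.01 (2^n-1) \rceil$
  subsets after sorting by MCC (ties toward smaller subsets, then unit
  order), keeping units whose frequency reaches half the maximum. Within a
  seed all subsets share one snap partition so MCCs are comparable;
  `resample = TRUE` redraws it per subset. The 50%-of-maximum membership
  rule and the tie-breaks are package conventions — the underlying procedure
  identifies the group by inspecting the histogram.
* **Iterative** (`iterativeAnalysis()`): backward elimination; units are
  ranked by individual MCC and the worst survivor is dropped each epoch. The
  *critical point* is the smallest group whose MCC is within 0.01 of the
  trajectory maximum (again an explicit convention for what is visually
  identified on the trajectory plot).
* **Recursive** (`recursiveAnalysis()`): split the unit set into
  importance > 0 (primary) versus importance = 0 (secondary) children and
  recurse; when every unit has positive importance the set splits at the
  importance median, the upper half forming the primary child. Branches stop
  at singletons, at models that use no unit, or at `maxDepth`.

## The validation simulator

`buildCircuit()` + `simulateCircuit()` provide ground truth: a scaled-down
spiking cortical network of Izhikevich two-variable neurons — regular-spiking
excitatory cells ($a=0.02, d=8$) and fast-spiking inhibitory cells
($a=0.1, d=2$), $v' = 0.04v^2 + 5v + 140 - u + I$, spike at 30 mV, 1 ms
steps with two 0.5 ms half-steps for $v$. The reference circuit is two
disconnected 40-neuron subcircuits (30 excitatory + 10 inhibitory each), so
half the recorded units are guaranteed irrelevant, as in a blind recording.
Each neuron emits exactly 5 synapses within its subcircuit; inhibitory
neurons project only onto excitatory neurons with a fixed 1 ms delay and
weight −5; excitatory delays are uniform integers on 1–5 ms. Excitatory
weights start at 60% of the maximal strength `sMax` — so a single EPSP
cannot fire a resting cell but two coincident EPSPs can — and evolve by
additive STDP (τ = 20 ms, potentiation 0.1, depression 0.12, eligibility
consolidated once per simulated second with decay 0.9, clipped to
`[0, sMax]`).

Two departures from naive scaling, both load-bearing:

* **In-degree floor.** Uniform synapse sampling at this scale leaves about
  one neuron in ten with ≤ 1 excitatory afferent. Such a neuron is
  permanently silent once external input is withheld from it — impossible in
  the full-size network, where in-degree is near 100. The sampler therefore
  guarantees every neuron at least 3 excitatory in-synapses (capped by the
  out-degree budget) before filling the remaining slots uniformly.
* **Target choice.** The target is the lowest-id excitatory neuron of the
  first subcircuit with at least 4 excitatory monosynaptic inputs, so the
  recovery question is non-trivial by construction.

Spontaneous activity is sustained by a random external input: each
millisecond, with probability `inputRate` (default 1), one uniformly chosen
recipient receives a current pulse of `inputStrength`. The **uncertainty
level** decides who the recipients are: `high` — everyone, so some target
spikes are driven by unobservable input; `medium` — everyone but the target;
`low` — everyone except the target and its monosynaptic afferents, making
the target maximally explainable from the recorded units.

### Calibration

The drive knobs (`sMax`, `inputStrength`) behave very differently across
uncertainty levels, so `calibrateDrive()` scans a grid in ascending total
drive and accepts the first setting whose probe run keeps the target's mean
rate in 0.5–0.8 Hz. The band is chosen once, for two reasons: biological
target units fire well below 1 Hz, and a sparse target keeps the positive
windows a negligible share of the recording, so 1000 s still tiles into
about 20000 intervals. Probes last the full production duration with a
100 s burn-in excluded from the rate estimate, because STDP drifts rates
upward over the first tens of seconds; pipelines calibrate with the same
seed as the production run, so the accepted probe *is* the analyzed
recording. Under low uncertainty the scan additionally prefers settings
where every monosynaptic unit stays above 0.4 Hz — a quiescent presynaptic
pool is not the regime the analysis studies. If both conditions cannot be
met the target band alone decides, with a warning.

### Structural versus effective ground truth

`groundTruth()` labels every unit by its shortest synaptic path to the
target (over all synapses); `monosynapticUnits()` restricts to excitatory
direct afferents, which is the set the analyses are expected to recover.
STDP occasionally depresses one of those synapses to a negligible weight
during the recording; the unit is then structurally monosynaptic but
contributes nothing to the data (its individual MCC is exactly 0), and no
effective-connectivity method can or should recover it.
`effectiveMonosynapticUnits()` therefore drops units whose final synaptic
weight fell below 10% of `sMax` or that fired below 0.1 Hz; validation
compares primary groups against this effective set. Typical runs lose 0–1
unit this way.

### What the simulator does and does not emulate

The generator reproduces the features the method depends on: sparse target
firing driven by coincidences of observable presynaptic spikes, irrelevant
but active units, plasticity, and a tunable share of unexplainable target
spikes. It does not emulate spike-sorting errors, electrode drift,
non-stationary behavioural states, or conduction-delay jitter beyond the
integer-millisecond grid. Passing the validation suite therefore shows the
procedures recover known structure under these idealised conditions; on real
recordings the uncertainty level is unknown and typically high, where the
direct primary group over-includes units and the combinatory/iterative
procedures are the more reliable readout. One emergent caveat: the two
"disconnected" subcircuits share the per-millisecond external input budget
and both develop gamma-range population rhythms, which weakly phase-lock —
disconnected units show a zero-lag cross-correlogram peak with the target
while all lagged bins stay at chance. Zero-lag synchrony carries no directed
information, and the classifier correctly assigns those units zero
predictive value.

## Numerical and degenerate-input choices

* Interval timestamps sit on the recording's millisecond grid; window
  comparisons use a 1 ns slack so binary rounding can never move a spike
  across a bin edge.
* Single-class training input yields a warned-about single-leaf model;
  prediction then returns the one class. A model that uses no attribute
  (empty primary group) is the "could not fit" marker consumed by the
  recursive workflow.
* Equal expected leaf costs resolve toward class 0; equal gain ratios toward
  the earlier attribute column; MCC with a zero margin is 0.
* Boosting stops early at training error 0 or ≥ 0.5.
* Extracted rules reproduce `predict()` exactly on rows whose categories
  were seen at each node; rows needing fallback routing match no rule and
  are reported as `NA` by `applyRules()`.

## Problem sizes

The shipped tests and the acceptance script run the reference analysis at
the scale the package documents: 80 neurons, 1000 s recordings
(~20000 intervals), 30 undersampling seeds, five independent circuits for
the recovery properties, and the full 8191-subset combinatory search at
n = 13. Property-style tests (uncertainty ordering, correlogram nulls) use
400 s probes and three circuits — large enough for the effects, small enough
to keep the suite quick on one CPU.

## Limitations

* The tree learner is a faithful re-implementation of the C4.5/C5.0 recipe,
  not the C5.0 binary; split-level decisions can differ, so reported metrics
  on a given dataset match the original analysis to within the seed-level
  variability, not digit-for-digit.
* The combinatory search is exponential and guarded at 16 units; beyond
  that, the iterative and recursive procedures are the intended tools.
* Inhibitory effective connections are not recovered: a unit whose only
  influence is suppressing target firing leaves little trace in positive
  windows under this encoding.
* Sensitivity is one synapse deep: disynaptic units surface reliably only
  through the recursive procedure under low uncertainty.
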