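# connectree

Effective connectivity inference from multi-unit spike trains with
cost-sensitive decision trees.

Multielectrode recordings yield simultaneous spike trains from many units
whose wiring is unknown. Given one unit designated as the **target** (for
example a primary afferent undergoing antidromic backfiring driven by
dorsal-horn neurons), connectree asks which of the other recorded units
effectively drive it. The recording is encoded as a table of 50 ms
intervals: each target spike defines a positive interval, the remaining time
tiles into negative intervals, and every predictor unit's spikes in the
50 ms before the interval timestamp are coded by 10 ms bins
(`A` = 0–10 ms back, …, `E` = 40–50 ms back; `"BBD"` = two spikes at
10–20 ms plus one at 30–40 ms; `"0"` = silence). A cost-sensitive
categorical decision tree of the C4.5/C5.0 family — written in this package,
with gain-ratio multiway splits, pessimistic pruning and
minimum-expected-cost leaves (FN:FP = 3.5:1) — is trained to predict target
firing from an undersampled "snap" set (all positives + 1:4 negatives,
80/20 train/validation split), and performance is summarised by precision,
recall and the Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

on the complete dataset. On top of the single **direct** fit, the package
implements **individual** (one model per unit), **combinatory** (all
2^n − 1 unit subsets, ranked by MCC, with a top-percentile frequency
histogram defining the *relevant group*), **iterative** (backward
elimination by individual MCC, reporting the *critical point*) and
**recursive** (importance-based bipartition) searches.

A scaled-down Izhikevich spiking-network simulator with STDP supplies
ground truth: two disconnected 40-neuron subcircuits (30 excitatory + 10
inhibitory each, 5 synapses per neuron, 1–5 ms delays), a calibrated random
external input, and three *uncertainty levels* that control how much of the
target's firing is explainable from the recorded units. See the vignette
(`vignettes/effective-connectivity.Rmd`) for the model, the conventions and
their rationale.

## Worked example

Simulate the reference circuit under low uncertainty, encode, and run a
direct analysis:

```r
library(connectree)

circ <- buildCircuit(circuitParams(), seed = 1)
cal  <- calibrateDrive(circ, "low", seed = 201)
sts  <- simulateCircuit(circ, "low", seed = 201,
                        inputStrength = cal$inputStrength, sMax = cal$sMax)
monosynapticUnits(circ)
#> [1] "U13" "U15" "U20" "U5"

tab <- extractIntervals(sts, targetUnit(circ))
tab
#> IntervalTable: 19689 intervals ( 626 positive / 19063 negative ),
#>   79 predictor units, target U2
#>   window 50 ms, bin 10 ms

runOnce(tab, seed = 1)
#> RunResult (seed 1)
#>       subset precision recall   mcc
#> 1   complete     0.755  0.978 0.854
#> 2       snap     0.979  0.978 0.973
#> 3   training     0.982  0.986 0.980
#> 4 validation     0.967  0.944 0.945
#> primary group: U5, U13, U14, U15, U20, U26
```

A 1000 s recording at a sparse target rate tiles into ~20000 intervals. The
tree predicts target firing on the complete dataset with MCC 0.854, and its
primary group — the units actually used to build rules — contains all four
monosynaptic afferents (U5, U13, U15, U20) plus two closely connected
units. `individualAnalysis()`, `combinatoryAnalysis()` (8191 subsets at
n = 13), `iterativeAnalysis()` and `recursiveAnalysis()` refine this to the
smallest group that explains the achievable MCC.

Real recordings enter through `readSpikeCSV()` (long format
`unit_id,spike_time_s`), and `runExperiment()` /
`inst/cli/connectree` (`simulate`, `encode`, `analyze`, `run-all`) drive the
whole pipeline from a YAML config with one master seed.

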