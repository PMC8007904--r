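test_that("generated circuits satisfy all structural invariants across seeds", {
  p <- circuitParams(duration = 10)
  for (seed in 1:8) {
    circ <- buildCircuit(p, seed = seed)
    expect_true(validObject(circ))
    nn <- neurons(circ)
    sy <- synapses(circ)
    expect_equal(nrow(nn), 80L)
    expect_equal(nrow(sy), 400L)
    # no cross-subcircuit edges
    expect_true(all(nn$subcircuit[sy$pre] == nn$subcircuit[sy$post]))
    # inhibitory neurons project only onto excitatory neurons, delay 1 ms
    inh <- nn$kind[sy$pre] == "inhibitory"
    expect_true(all(nn$kind[sy$post[inh]] == "excitatory"))
    expect_true(all(sy$delay[inh] == 1L))
    expect_true(all(sy$delay[!inh] %in% 1:5))
    expect_true(all(tabulate(sy$pre, 80) == 5L))
    # guaranteed excitatory in-degree
    excIn <- tabulate(sy$post[!inh], 80)
    expect_true(all(excIn >= 3L))
  }
})

test_that("the smallest legal circuit is built correctly", {
  p <- circuitParams(nSubcircuits = 1, nExcPerSub = 3, nInhPerSub = 1,
                     mOut = 1, duration = 1)
  circ <- buildCircuit(p, seed = 3, minTargetInputs = 0L)
  expect_equal(nrow(neurons(circ)), 4L)
  expect_equal(nrow(synapses(circ)), 4L)
  sy <- synapses(circ)
  nn <- neurons(circ)
  inhEdge <- sy[nn$kind[sy$pre] == "inhibitory", ]
  expect_equal(nn$kind[inhEdge$post], "excitatory")
})

test_that("infeasible out-degree is rejected", {
  p <- circuitParams(nSubcircuits = 1, nExcPerSub = 3, nInhPerSub = 1,
                     mOut = 4, duration = 1)
  expect_error(buildCircuit(p, seed = 1), "eligible postsynaptic")
})

test_that("circuit construction is deterministic given the seed", {
  p <- circuitParams(duration = 10)
  a <- buildCircuit(p, seed = 11)
  b <- buildCircuit(p, seed = 11)
  expect_identical(synapses(a), synapses(b))
  expect_identical(targetUnit(a), targetUnit(b))
  expect_false(identical(synapses(a), synapses(buildCircuit(p, seed = 12))))
})

test_that("ground truth follows shortest synaptic paths (chain example)", {
  # A -> B -> T, plus T -> A to close the out-degree budget
  p <- circuitParams(nSubcircuits = 1, nExcPerSub = 3, nInhPerSub = 0,
                     mOut = 1, duration = 1)
  nn <- data.frame(id = 1:3, unit = c("UA", "UB", "UT"),
                   kind = "excitatory", subcircuit = 1L,
                   stringsAsFactors = FALSE)
  sy <- data.frame(pre = c(1L, 2L, 3L), post = c(2L, 3L, 1L),
                   weight = 6, delay = 1L)
  circ <- new("Circuit", neurons = nn, synapses = sy, target = 3L, params = p)
  gt <- groundTruth(circ)
  expect_equal(gt$label[gt$unit == "UB"], "monosynaptic")
  expect_equal(gt$label[gt$unit == "UA"], "disynaptic")
  expect_equal(gt$label[gt$unit == "UT"], "target")
})

test_that("ground-truth labels agree with an independent BFS oracle", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 9)) {
    circ <- buildCircuit(circuitParams(duration = 10), seed = seed)
    gt <- groundTruth(circ)
    g <- igraph::graph_from_data_frame(
      synapses(circ)[, c("pre", "post")], directed = TRUE,
      vertices = data.frame(name = neurons(circ)$id))
    d <- igraph::distances(g, to = as.character(circ@target), mode = "out")
    lab <- c("target", "monosynaptic", "disynaptic", "trisynaptic")
    expected <- ifelse(is.infinite(d), "disconnected",
                       ifelse(d <= 3, lab[d + 1], "other_connected"))
    expect_equal(gt$label, as.vector(expected))
    # units of the second subcircuit are all disconnected
    sub2 <- neurons(circ)$unit[neurons(circ)$subcircuit == 2L]
    expect_true(all(gt$label[gt$unit %in% sub2] == "disconnected"))
  }
})

test_that("a circuit with zero weights and no external input stays silent", {
  circ <- buildCircuit(circuitParams(duration = 5), seed = 4)
  sts <- simulateCircuit(circ, "low", seed = 1, duration = 5, sMax = 0,
                         recipients = integer(0))
  expect_true(all(vapply(spikeTrains(sts), length, integer(1)) == 0L))
})

test_that("one subthreshold EPSP does not fire a resting cell, a coincident pair does", {
  p <- circuitParams(nSubcircuits = 1, nExcPerSub = 3, nInhPerSub = 0,
                     mOut = 2, sMax = 20, duration = 5)
  nn <- data.frame(id = 1:3, unit = c("UA", "UB", "UT"),
                   kind = "excitatory", subcircuit = 1L,
                   stringsAsFactors = FALSE)
  # A sends two simultaneous 8 mV synapses to T; B sends a single one
  sy <- data.frame(pre = c(1L, 1L, 2L, 2L, 3L, 3L),
                   post = c(3L, 3L, 3L, 1L, 1L, 2L),
                   weight = c(8, 8, 8, 0, 0, 0), delay = 1L)
  circ <- new("Circuit", neurons = nn, synapses = sy, target = 3L, params = p)
  # drive only B: T receives isolated 8 mV pulses and must stay silent
  stsB <- simulateCircuit(circ, seed = 2, recipients = 2L, stdp = FALSE,
                          inputStrength = 30)
  expect_gt(length(spikeTrains(stsB)$UB), 0L)
  expect_equal(length(spikeTrains(stsB)$UT), 0L)
  # drive only A: T receives 16 mV coincident pairs and must fire
  stsA <- simulateCircuit(circ, seed = 2, recipients = 1L, stdp = FALSE,
                          inputStrength = 30)
  expect_gt(length(spikeTrains(stsA)$UA), 0L)
  expect_gt(length(spikeTrains(stsA)$UT), 0L)
})

test_that("simulation is reproducible from the seed and bounded by sMax", {
  circ <- buildCircuit(circuitParams(duration = 30), seed = 5)
  a <- simulateCircuit(circ, "medium", seed = 7, duration = 30)
  b <- simulateCircuit(circ, "medium", seed = 7, duration = 30)
  expect_identical(spikeTrains(a), spikeTrains(b))
  fw <- attr(a, "finalWeights")
  exc <- neurons(circ)$kind[fw$pre] == "excitatory"
  expect_true(all(fw$weight[exc] >= 0 & fw$weight[exc] <= attr(a, "sMax")))
  expect_true(all(fw$weight[!exc] == -5))
  # all spike times within [0, duration)
  expect_true(all(vapply(spikeTrains(a), function(x)
    !length(x) || (min(x) >= 0 && max(x) < 30), logical(1))))
})

test_that("uncertainty levels define the documented input recipients", {
  circ <- buildCircuit(circuitParams(duration = 10), seed = 6)
  ids <- neurons(circ)$id
  presyn <- unique(synapses(circ)$pre[synapses(circ)$post == circ@target])
  expect_setequal(uncertaintyRecipients(circ, "high"), ids)
  expect_setequal(uncertaintyRecipients(circ, "medium"),
                  setdiff(ids, circ@target))
  expect_setequal(uncertaintyRecipients(circ, "low"),
                  setdiff(ids, c(circ@target, presyn)))
})

test_that("exportSubset restricts trains and is idempotent", {
  circ <- buildCircuit(circuitParams(duration = 10), seed = 2)
  sts <- simulateCircuit(circ, "high", seed = 3, duration = 10)
  ids13 <- neurons(circ)$unit[c(1:7, 41:46)]
  sub <- exportSubset(sts, ids13)
  expect_equal(unitIds(sub), ids13)
  expect_equal(recordingDuration(sub), recordingDuration(sts))
  expect_identical(spikeTrains(exportSubset(sts, unitIds(sts))),
                   spikeTrains(sts))
  expect_identical(spikeTrains(exportSubset(sub, ids13[1:3])),
                   spikeTrains(exportSubset(sts, ids13[1:3])))
  expect_error(exportSubset(sts, "U999"), "U999")
})

test_that("reducedUnitSet mixes connectivity degrees and excludes the target", {
  circ <- buildCircuit(circuitParams(duration = 10), seed = 1)
  units <- reducedUnitSet(circ)
  expect_length(units, 13L)
  expect_false(targetUnit(circ) %in% units)
  gt <- groundTruth(circ)
  lab <- gt$label[match(units, gt$unit)]
  expect_true(all(monosynapticUnits(circ) %in% units))
  expect_true(any(lab == "disconnected"))
  noMono <- reducedUnitSet(circ, includeMono = FALSE)
  expect_false(any(monosynapticUnits(circ) %in% noMono))
})

test_that("disconnected-subcircuit trains are uncorrelated with the target", {
  std <- standardRun(1)
  tgt <- spikeTrains(std$spikes)[[std$target]]
  sub2 <- neurons(std$circuit)$unit[neurons(std$circuit)$subcircuit == 2L]
  rates <- vapply(spikeTrains(std$spikes)[sub2], length, integer(1))
  pick <- sub2[order(-rates)][1:3]          # the three most active ones
  dur <- recordingDuration(std$spikes)
  set.seed(101)
  # lagged bins only: zero-lag population synchrony (both subnets share the
  # per-millisecond external input budget and oscillate in the gamma range)
  # carries no directed information and is not what connectivity inference
  # reads out
  lagged <- function(h) max(h$count[abs(h$lag_ms) >= 1])
  for (u in pick) {
    other <- spikeTrains(std$spikes)[[u]]
    obs <- crossCorrelogram(tgt, other, binMs = 1, windowMs = 50)
    # circular-shift surrogates preserve each train's ISI structure while
    # destroying any temporal relation between the two
    nullMax <- vapply(1:100, function(i) {
      shifted <- sort((other + runif(1, 10, dur - 10)) %% dur)
      lagged(crossCorrelogram(tgt, shifted, binMs = 1, windowMs = 50))
    }, numeric(1))
    expect_lte(lagged(obs), quantile(nullMax, 0.99) + 1e-9)
  }
})

test_that("monosynaptic units are easier to read out under low than high uncertainty", {
  lowM <- highM <- numeric(3)
  for (s in 1:3) {
    circ <- buildCircuit(circuitParams(), seed = s)
    mono <- monosynapticUnits(circ)
    for (lev in c("low", "high")) {
      cal <- suppressWarnings(
        calibrateDrive(circ, lev, seed = s + 300L, probeDuration = 400,
                       burnIn = 100))
      sts <- simulateCircuit(circ, lev, seed = s + 300L, duration = 400,
                             inputStrength = cal$inputStrength,
                             sMax = cal$sMax)
      tab <- extractIntervals(sts, targetUnit(circ))
      ind <- individualAnalysis(tab, units = mono, seed = 5)
      if (lev == "low") lowM[s] <- mean(ind$mcc) else highM[s] <- mean(ind$mcc)
    }
  }
  expect_gt(mean(lowM), mean(highM))
})
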