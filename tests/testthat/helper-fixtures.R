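# Shared fixtures. Heavy simulation products are memoized so that several
# test files can reuse the same 1000 s reference run.

.fixtureCache <- new.env(parent = emptyenv())

# The reference validation run: 80-neuron circuit, low uncertainty,
# calibrated drive, 1000 s recording, 50 ms / 10 ms encoding.
standardRun <- function(simSeed = 1L) {
  key <- paste0("std", simSeed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  circ <- buildCircuit(circuitParams(), seed = simSeed)
  cal <- suppressWarnings(calibrateDrive(circ, "low", seed = simSeed + 200L))
  sts <- simulateCircuit(circ, "low", seed = simSeed + 200L, duration = 1000,
                         inputStrength = cal$inputStrength, sMax = cal$sMax)
  tab <- extractIntervals(sts, targetUnit(circ))
  out <- list(circuit = circ, calibration = cal, spikes = sts, table = tab,
              target = targetUnit(circ),
              mono = monosynapticUnits(circ),
              effMono = effectiveMonosynapticUnits(circ, sts),
              labels = groundTruth(circ))
  .fixtureCache[[key]] <- out
  out
}

# deterministic toy spike trains: U2 fires 50 ms after every U1 spike,
# U3 is independent
toySpikes <- function(duration = 20) {
  u1 <- seq(0.2, duration - 0.5, by = 0.5)
  spikeTrainSet(list(U1 = u1, U2 = u1 + 0.02, U3 = seq(0.13, duration - 0.5, by = 0.71)),
                duration = duration)
}

# random interval table with independent uniform codes (no signal unless
# perfect = TRUE, in which case unit 1's code determines the class)
randomTable <- function(n = 200, p = 3, seed = 1, posRate = 0.3,
                        perfect = FALSE,
                        codePool = c("0", "A", "B", "C", "AB", "BBD")) {
  set.seed(seed)
  fired <- as.integer(runif(n) < posRate)
  codes <- matrix(sample(codePool, n * p, replace = TRUE), n, p,
                  dimnames = list(NULL, paste0("U", seq_len(p) + 1L)))
  if (perfect) codes[, 1] <- ifelse(fired == 1L, "A", "0")
  new("IntervalTable", timestamps = seq_len(n) * 0.05, codes = codes,
      fired = fired, units = colnames(codes), target = "U1",
      window = 50, bin = 10)
}

# independent entropy / gain-ratio calculations used as an oracle for the
# split chosen by the tree learner
oracleEntropy <- function(y) {
  p <- table(factor(y, levels = c(0, 1))) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracleGainRatio <- function(x, y) {
  n <- length(y)
  tabs <- split(seq_len(n), x)
  h <- oracleEntropy(y)
  hSplit <- sum(vapply(tabs, function(i) length(i) / n * oracleEntropy(y[i]),
                       numeric(1)))
  frac <- vapply(tabs, length, numeric(1)) / n
  splitInfo <- -sum(frac * log2(frac))
  gain <- h - hSplit
  c(gain = gain, ratio = if (splitInfo > 0) gain / splitInfo else NA_real_)
}
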