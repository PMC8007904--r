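#' Parameters of the simulated spiking circuit
#'
#' Describes the scaled-down spiking cortical network used to generate
#' ground-truth spike trains: a number of mutually disconnected subcircuits,
#' each with a 3:1 ratio of excitatory to inhibitory neurons, a fixed
#' out-degree per neuron, integer conduction delays and plastic excitatory
#' synapses bounded by a maximal strength.
#'
#' @slot nSubcircuits number of mutually disconnected subcircuits.
#' @slot nExcPerSub excitatory neurons per subcircuit.
#' @slot nInhPerSub inhibitory neurons per subcircuit.
#' @slot mOut outgoing synapses per neuron.
#' @slot excDelayRange integer range (ms) for excitatory conduction delays.
#' @slot inhDelay fixed inhibitory conduction delay (ms).
#' @slot sMax maximal excitatory synaptic strength (mV-equivalent drive).
#' @slot inputStrength amplitude of the random external current pulse.
#' @slot inputRate probability of one external input event per 1 ms step.
#' @slot duration recording duration in seconds.
#' @slot dt integration step in ms (fixed at 1 ms, with half-step updates
#'   of the membrane potential).
#'
#' @exportClass CircuitParams
setClass("CircuitParams", representation(
  nSubcircuits = "integer",
  nExcPerSub = "integer",
  nInhPerSub = "integer",
  mOut = "integer",
  excDelayRange = "integer",
  inhDelay = "integer",
  sMax = "numeric",
  inputStrength = "numeric",
  inputRate = "numeric",
  duration = "numeric",
  dt = "numeric"
))

setValidity("CircuitParams", function(object) {
  msg <- character()
  if (object@nSubcircuits < 1L) msg <- c(msg, "nSubcircuits must be >= 1")
  if (object@nExcPerSub < 1L || object@nInhPerSub < 0L)
    msg <- c(msg, "neuron counts must be positive")
  if (object@mOut < 1L) msg <- c(msg, "mOut must be >= 1")
  if (length(object@excDelayRange) != 2L ||
      object@excDelayRange[1] < 1L || object@excDelayRange[2] > 5L ||
      object@excDelayRange[1] > object@excDelayRange[2])
    msg <- c(msg, "excDelayRange must be an increasing integer range within [1, 5] ms")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@inputRate < 0 || object@inputRate > 1)
    msg <- c(msg, "inputRate must be a probability per 1 ms step")
  if (length(msg)) msg else TRUE
})

#' Construct circuit parameters
#'
#' Defaults describe the reference validation circuit: two disconnected
#' 40-neuron subcircuits (30 excitatory + 10 inhibitory each), 5 outgoing
#' synapses per neuron, excitatory delays uniform on 1--5 ms, inhibitory
#' delay fixed at 1 ms. `sMax` and `inputStrength` are the drive knobs that
#' [calibrateDrive()] adjusts per uncertainty level.
#'
#' @param nSubcircuits,nExcPerSub,nInhPerSub,mOut circuit topology, see
#'   [CircuitParams-class].
#' @param excDelayRange,inhDelay conduction delays in ms.
#' @param sMax maximal excitatory synaptic strength.
#' @param inputStrength external input pulse amplitude.
#' @param inputRate probability of one external event per ms.
#' @param duration recording duration in seconds.
#' @return A [CircuitParams-class] object.
#' @examples
#' p <- circuitParams(duration = 10)
#' @export
circuitParams <- function(nSubcircuits = 2L, nExcPerSub = 30L, nInhPerSub = 10L,
                          mOut = 5L, excDelayRange = c(1L, 5L), inhDelay = 1L,
                          sMax = 10, inputStrength = 20, inputRate = 1,
                          duration = 1000) {
  new("CircuitParams",
      nSubcircuits = as.integer(nSubcircuits),
      nExcPerSub = as.integer(nExcPerSub),
      nInhPerSub = as.integer(nInhPerSub),
      mOut = as.integer(mOut),
      excDelayRange = as.integer(excDelayRange),
      inhDelay = as.integer(inhDelay),
      sMax = as.numeric(sMax),
      inputStrength = as.numeric(inputStrength),
      inputRate = as.numeric(inputRate),
      duration = as.numeric(duration),
      dt = 1)
}

#' A spiking circuit with known structure
#'
#' Directed, weighted, delayed synapse graph over typed neurons, plus a
#' designated target unit. Inhibitory neurons project only onto excitatory
#' neurons of the same subcircuit; no synapse crosses subcircuits.
#'
#' @slot neurons data.frame with columns `id` (integer), `unit` (character
#'   label "U<id>"), `kind` ("excitatory"/"inhibitory"), `subcircuit`
#'   (integer, 1-based).
#' @slot synapses data.frame with columns `pre`, `post` (neuron ids),
#'   `weight` (initial strength; negative for inhibitory synapses) and
#'   `delay` (integer ms).
#' @slot target id of the target neuron (excitatory, first subcircuit).
#' @slot params the [CircuitParams-class] used to build the circuit.
#'
#' @exportClass Circuit
setClass("Circuit", representation(
  neurons = "data.frame",
  synapses = "data.frame",
  target = "integer",
  params = "CircuitParams"
))

setValidity("Circuit", function(object) {
  nn <- object@neurons
  sy <- object@synapses
  msg <- character()
  if (!all(c("id", "unit", "kind", "subcircuit") %in% names(nn)))
    return("neurons must have columns id, unit, kind, subcircuit")
  if (!all(c("pre", "post", "weight", "delay") %in% names(sy)))
    return("synapses must have columns pre, post, weight, delay")
  sub <- nn$subcircuit[match(sy$pre, nn$id)]
  if (any(sub != nn$subcircuit[match(sy$post, nn$id)]))
    msg <- c(msg, "synapses must not cross subcircuits")
  kind_pre <- nn$kind[match(sy$pre, nn$id)]
  kind_post <- nn$kind[match(sy$post, nn$id)]
  inh <- kind_pre == "inhibitory"
  if (any(kind_post[inh] != "excitatory"))
    msg <- c(msg, "inhibitory neurons may project only onto excitatory neurons")
  if (any(sy$delay[inh] != object@params@inhDelay))
    msg <- c(msg, "inhibitory delays must equal inhDelay")
  rng <- object@params@excDelayRange
  if (any(sy$delay[!inh] < rng[1] | sy$delay[!inh] > rng[2]))
    msg <- c(msg, "excitatory delays must lie in excDelayRange")
  if (any(sy$weight[!inh] < 0 | sy$weight[!inh] > object@params@sMax))
    msg <- c(msg, "excitatory weights must lie in [0, sMax]")
  if (any(sy$pre == sy$post)) msg <- c(msg, "self-synapses are forbidden")
  if (!all(tabulate(sy$pre, nbins = max(nn$id)) [nn$id] == object@params@mOut))
    msg <- c(msg, "every neuron must have exactly mOut outgoing synapses")
  tk <- nn[match(object@target, nn$id), ]
  if (nrow(tk) != 1L || tk$kind != "excitatory" || tk$subcircuit != 1L)
    msg <- c(msg, "target must be an excitatory neuron of the first subcircuit")
  if (length(msg)) msg else TRUE
})

#' Per-unit spike trains over a fixed recording duration
#'
#' @slot trains named list, one strictly increasing numeric vector of spike
#'   times (seconds) per unit.
#' @slot duration recording duration in seconds; all times lie in
#'   `[0, duration)`.
#'
#' @exportClass SpikeTrainSet
setClass("SpikeTrainSet", representation(
  trains = "list",
  duration = "numeric"
))

setValidity("SpikeTrainSet", function(object) {
  msg <- character()
  if (is.null(names(object@trains)) || anyDuplicated(names(object@trains)))
    msg <- c(msg, "trains must be a uniquely named list")
  for (u in names(object@trains)) {
    tr <- object@trains[[u]]
    if (!is.numeric(tr)) { msg <- c(msg, paste0("train ", u, " is not numeric")); next }
    if (length(tr) && (any(diff(tr) <= 0)))
      msg <- c(msg, paste0("train ", u, " is not strictly increasing"))
    if (length(tr) && (tr[1] < 0 || tr[length(tr)] >= object@duration))
      msg <- c(msg, paste0("train ", u, " has times outside [0, duration)"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a spike-train set
#'
#' @param trains named list of strictly increasing spike-time vectors
#'   (seconds).
#' @param duration recording duration in seconds.
#' @return A [SpikeTrainSet-class] object.
#' @examples
#' s <- spikeTrainSet(list(U1 = c(0.1, 0.5), U2 = numeric(0)), duration = 1)
#' @export
spikeTrainSet <- function(trains, duration) {
  new("SpikeTrainSet", trains = trains, duration = as.numeric(duration))
}

#' Categorical interval table
#'
#' One row per 50 ms interval. Positive rows end at a target spike
#' (class 1); negative rows tile the remaining recording time (class 0).
#' Each predictor unit's activity in the 50 ms preceding the row timestamp is
#' summarised as a categorical code: `"0"` for no spike, otherwise one letter
#' per spike, `A` for the 10 ms bin nearest the timestamp through `E` for the
#' most remote bin, letters sorted alphabetically (`"BBD"` = two spikes
#' 10--20 ms back, one 30--40 ms back).
#'
#' @slot timestamps interval timestamps in seconds (interval end).
#' @slot codes character matrix, rows = intervals, columns = predictor units.
#' @slot fired integer class vector (1 = target fired at the timestamp).
#' @slot units ordered predictor unit ids (target excluded).
#' @slot target id of the target unit.
#' @slot window interval length in ms.
#' @slot bin code bin width in ms.
#'
#' @exportClass IntervalTable
setClass("IntervalTable", representation(
  timestamps = "numeric",
  codes = "matrix",
  fired = "integer",
  units = "character",
  target = "character",
  window = "numeric",
  bin = "numeric"
))

setValidity("IntervalTable", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (nrow(object@codes) != n || length(object@fired) != n)
    msg <- c(msg, "timestamps, codes and fired must agree in length")
  if (ncol(object@codes) != length(object@units))
    msg <- c(msg, "codes must have one column per unit")
  if (!all(object@fired %in% c(0L, 1L)))
    msg <- c(msg, "fired must be 0/1")
  if (object@window <= 0 || object@bin <= 0 ||
      object@window %% object@bin != 0)
    msg <- c(msg, "window must be a positive multiple of bin")
  maxLetter <- LETTERS[object@window / object@bin]
  bad <- !grepl(paste0("^0$|^[A-", maxLetter, "]+$"), object@codes)
  if (any(bad)) msg <- c(msg, "codes must be \"0\" or letters within the bin alphabet")
  if (length(msg)) msg else TRUE
})

#' Misclassification cost matrix
#'
#' Costs for the two error types when predicting target firing; correct
#' classifications cost nothing. The default penalises a missed target spike
#' (false negative) 3.5 times more than a false alarm.
#'
#' @slot fnCost cost of a false negative.
#' @slot fpCost cost of a false positive.
#'
#' @exportClass CostMatrix
setClass("CostMatrix", representation(fnCost = "numeric", fpCost = "numeric"))

setValidity("CostMatrix", function(object) {
  if (object@fnCost < 0 || object@fpCost < 0) "costs must be non-negative" else TRUE
})

#' @rdname CostMatrix-class
#' @param fnCost,fpCost non-negative misclassification costs.
#' @return A [CostMatrix-class] object.
#' @examples
#' costMatrix()          # the default 3.5 : 1 cost matrix
#' @export
costMatrix <- function(fnCost = 3.5, fpCost = 1) {
  new("CostMatrix", fnCost = as.numeric(fnCost), fpCost = as.numeric(fpCost))
}

#' Tree-fitting configuration
#'
#' @slot trials number of boosting trials; 1 fits a single tree.
#' @slot pruneConfidence confidence level of pessimistic pruning.
#' @slot minCases minimum cases per branch for a split to be considered.
#'
#' @exportClass FitConfig
setClass("FitConfig", representation(
  trials = "integer",
  pruneConfidence = "numeric",
  minCases = "integer"
))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@trials < 1L) msg <- c(msg, "trials must be >= 1")
  if (object@pruneConfidence <= 0 || object@pruneConfidence >= 1)
    msg <- c(msg, "pruneConfidence must lie in (0, 1)")
  if (object@minCases < 1L) msg <- c(msg, "minCases must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname FitConfig-class
#' @param trials boosting trials (default 1, a single tree).
#' @param pruneConfidence pessimistic-pruning confidence (default 0.25).
#' @param minCases minimum cases per branch (default 2).
#' @return A [FitConfig-class] object.
#' @examples
#' fitConfig(trials = 5)
#' @export
fitConfig <- function(trials = 1L, pruneConfidence = 0.25, minCases = 2L) {
  new("FitConfig", trials = as.integer(trials),
      pruneConfidence = as.numeric(pruneConfidence),
      minCases = as.integer(minCases))
}

#' Fitted categorical decision-tree model
#'
#' A single multiway categorical decision tree, or a boosted committee of
#' them, with per-attribute variable importance (the C5.0 "usage" metric:
#' the percentage of training cases that pass through at least one split on
#' the attribute).
#'
#' @slot trees list of flat node tables, one per boosting trial. Each is a
#'   list with node vectors (`is_leaf`, `attr`, `cls`, `n`, `n0`, `n1`,
#'   `fallback`) and branch vectors (`branch_node`, `branch_level`,
#'   `branch_child`).
#' @slot treeWeights committee voting weights, one per tree.
#' @slot attributes attribute (unit) names, in training-column order.
#' @slot levels list of category label vectors, one per attribute.
#' @slot importance named percentage vector over attributes.
#' @slot costs the [CostMatrix-class] used.
#' @slot config the [FitConfig-class] used.
#'
#' @exportClass TreeModel
setClass("TreeModel", representation(
  trees = "list",
  treeWeights = "numeric",
  attributes = "character",
  levels = "list",
  importance = "numeric",
  costs = "CostMatrix",
  config = "FitConfig"
))
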