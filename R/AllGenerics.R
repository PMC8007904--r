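#' @name accessors
#' @title Accessors for connectree classes
#' @description Slot accessors for the core data containers.
#' @param object a connectree object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("neurons", function(object) standardGeneric("neurons"))

#' @rdname accessors
#' @export
setGeneric("synapses", function(object) standardGeneric("synapses"))

#' @rdname accessors
#' @export
setGeneric("targetUnit", function(object) standardGeneric("targetUnit"))

#' @rdname accessors
#' @export
setGeneric("spikeTrains", function(object) standardGeneric("spikeTrains"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(object) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))

#' @rdname accessors
#' @export
setGeneric("intervalCodes", function(object) standardGeneric("intervalCodes"))

#' @rdname accessors
#' @export
setGeneric("intervalClasses", function(object) standardGeneric("intervalClasses"))

#' @rdname accessors
#' @export
setGeneric("intervalTimestamps", function(object) standardGeneric("intervalTimestamps"))

#' Variable importance of a fitted tree model
#'
#' The C5.0-style "usage" importance: for each attribute, the percentage of
#' training cases that traverse at least one node splitting on it. Attributes
#' used in no tree score 0.
#'
#' @param model a [TreeModel-class].
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
setGeneric("variableImportance", function(model) standardGeneric("variableImportance"))

#' Primary group of a fitted model
#'
#' The set of attributes (units) with variable importance greater than zero,
#' i.e. the units the model actually used to build rules.
#'
#' @param model a [TreeModel-class].
#' @return Character vector of unit ids.
#' @export
setGeneric("primaryGroup", function(model) standardGeneric("primaryGroup"))

#' Extract the rule set of a single decision tree
#'
#' One rule per leaf: the conjunction of attribute = category tests on the
#' path from the root, the predicted class, and the number of training cases
#' covered. Applying the rules reproduces [predict()] exactly on rows whose
#' categories were observed at each node (rows with unseen categories are
#' routed by fallback branches inside [predict()] and match no rule). Only
#' defined for single-tree models (`trials = 1`).
#'
#' @param model a [TreeModel-class] with one tree.
#' @return data.frame with columns `rule`, `class`, `coverage`.
#' @export
setGeneric("extractRules", function(model) standardGeneric("extractRules"))

setMethod("neurons", "Circuit", function(object) object@neurons)
setMethod("synapses", "Circuit", function(object) object@synapses)
setMethod("targetUnit", "Circuit", function(object)
  object@neurons$unit[match(object@target, object@neurons$id)])
setMethod("targetUnit", "IntervalTable", function(object) object@target)
setMethod("spikeTrains", "SpikeTrainSet", function(object) object@trains)
setMethod("recordingDuration", "SpikeTrainSet", function(object) object@duration)
setMethod("unitIds", "SpikeTrainSet", function(object) names(object@trains))
setMethod("unitIds", "Circuit", function(object) object@neurons$unit)
setMethod("unitIds", "IntervalTable", function(object) object@units)
setMethod("intervalCodes", "IntervalTable", function(object) object@codes)
setMethod("intervalClasses", "IntervalTable", function(object) object@fired)
setMethod("intervalTimestamps", "IntervalTable", function(object) object@timestamps)

#' Number of intervals in a table
#' @param x an [IntervalTable-class].
#' @export
setMethod("length", "IntervalTable", function(x) length(x@timestamps))

setMethod("show", "CircuitParams", function(object) {
  cat("CircuitParams:", object@nSubcircuits, "subcircuit(s) of",
      object@nExcPerSub, "excitatory +", object@nInhPerSub, "inhibitory neurons\n")
  cat("  out-degree", object@mOut,
      "| exc delays", paste(object@excDelayRange, collapse = "-"),
      "ms | inh delay", object@inhDelay, "ms\n")
  cat("  sMax", object@sMax, "| input", object@inputStrength,
      "@ rate", object@inputRate, "/ms | duration", object@duration, "s\n")
})

setMethod("show", "Circuit", function(object) {
  cat("Circuit:", nrow(object@neurons), "neurons,",
      nrow(object@synapses), "synapses, target", targetUnit(object), "\n")
  tab <- table(object@neurons$kind, object@neurons$subcircuit)
  print(tab)
})

setMethod("show", "SpikeTrainSet", function(object) {
  ns <- vapply(object@trains, length, integer(1))
  cat("SpikeTrainSet:", length(object@trains), "units over",
      object@duration, "s;", sum(ns), "spikes\n")
  cat("  rates (Hz):", paste0(head(names(ns), 5), "=",
      sprintf("%.2f", head(ns, 5) / object@duration), collapse = " "),
      if (length(ns) > 5) "..." else "", "\n")
})

setMethod("show", "IntervalTable", function(object) {
  cat("IntervalTable:", length(object@timestamps), "intervals (",
      sum(object@fired == 1L), "positive /", sum(object@fired == 0L),
      "negative ),", length(object@units), "predictor units, target",
      object@target, "\n")
  cat("  window", object@window, "ms, bin", object@bin, "ms\n")
})

setMethod("show", "CostMatrix", function(object) {
  cat("CostMatrix: FN =", object@fnCost, ", FP =", object@fpCost, "\n")
})

setMethod("show", "FitConfig", function(object) {
  cat("FitConfig: trials =", object@trials,
      ", pruneConfidence =", object@pruneConfidence,
      ", minCases =", object@minCases, "\n")
})

setMethod("show", "TreeModel", function(object) {
  nl <- vapply(object@trees, function(tr) sum(tr$is_leaf == 1L), integer(1))
  cat("TreeModel:", length(object@trees), "tree(s);",
      paste(nl, collapse = "/"), "leaves;",
      sum(object@importance > 0), "of", length(object@attributes),
      "attributes used\n")
})
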