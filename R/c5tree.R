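# internal: integer-code a character code matrix column-wise.
# Levels are taken from the training data; unseen codes map to 0 and are
# routed through fallback branches at prediction time.
.codeLevels <- function(codes) {
  lapply(seq_len(ncol(codes)), function(j) sort(unique(codes[, j])))
}

.encodeMatrix <- function(codes, levels) {
  n <- nrow(codes)
  x <- matrix(0L, n, ncol(codes))
  for (j in seq_len(ncol(codes))) {
    m <- match(codes[, j], levels[[j]])
    m[is.na(m)] <- 0L
    x[, j] <- m
  }
  x
}

# internal: fit on pre-coded integer data; the hot path shared by fitTree
# and the combinatory search
.fitCore <- function(x, nlev, y, costs, config) {
  n <- nrow(x)
  trees <- list()
  tw <- numeric(0)
  wt <- rep(1, n)
  for (trial in seq_len(config@trials)) {
    # costs steer leaf-class assignment only; the pessimistic pruning
    # estimate stays on raw error counts (cost-weighted pruning collapses
    # the subtrees that separate coincident-input patterns from single-spike
    # patterns, which is exactly the structure the analysis relies on)
    tr <- cpp_fit_tree(x, y, wt, nlev, costs@fnCost, costs@fpCost,
                       config@minCases, config@pruneConfidence, TRUE, FALSE)
    pred <- cpp_predict_tree(x, tr$is_leaf, tr$attr, tr$cls, tr$fallback,
                             tr$branch_node, tr$branch_level, tr$branch_child)
    err <- sum(wt[pred != y]) / sum(wt)
    if (trial > 1L && err >= 0.5) break      # boosting cannot continue
    trees[[length(trees) + 1L]] <- tr
    tw[length(tw) + 1L] <-
      if (err <= 0 || err >= 0.5) 1 else log((1 - err) / err)
    if (err <= 0 || err >= 0.5) break        # perfect or unusable fit
    beta <- err / (1 - err)                  # < 1: down-weight correct cases
    wt[pred == y] <- wt[pred == y] * beta
    wt <- wt * (n / sum(wt))
  }
  # committee importance: voting-weight-weighted mean of per-tree usage
  w <- tw / sum(tw)
  imp <- Reduce(`+`, Map(function(tr, wi) wi * tr$usage, trees, w))
  list(trees = trees, treeWeights = tw, importance = imp)
}

#' Fit a cost-sensitive categorical decision tree
#'
#' Grows a multiway decision tree (or a boosted committee when
#' `trials > 1`) on the categorical interval codes, predicting whether the
#' target fired. Splits are chosen by gain ratio among attributes whose
#' information gain is at least the average gain of the candidates; trees are
#' pessimistically pruned; leaf classes minimise expected misclassification
#' cost under `costs` (ties toward class 0). Deterministic given its inputs.
#'
#' @param table an [IntervalTable-class] (typically the training rows of a
#'   snap partition, see [snapSample()]).
#' @param units optional predictor subset; default all units of `table`.
#' @param costs a [CostMatrix-class].
#' @param config a [FitConfig-class].
#' @return A [TreeModel-class].
#' @examples
#' sts <- spikeTrainSet(list(U1 = c(0.06, 0.26), U2 = c(0.07, 0.27)),
#'                      duration = 1)
#' tab <- extractIntervals(sts, "U2")
#' fitTree(tab)
#' @export
fitTree <- function(table, units = NULL, costs = costMatrix(),
                    config = fitConfig()) {
  stopifnot(is(table, "IntervalTable"), is(costs, "CostMatrix"),
            is(config, "FitConfig"))
  if (!is.null(units)) table <- subsetUnits(table, units)
  y <- table@fired
  if (length(y) < 2L) stop("need at least 2 rows to fit a tree")
  if (length(unique(y)) < 2L)
    warning("single-class input; fitting a degenerate single-leaf model")
  codes <- table@codes
  levels <- .codeLevels(codes)
  x <- .encodeMatrix(codes, levels)
  nlev <- vapply(levels, length, integer(1))
  fit <- .fitCore(x, nlev, y, costs, config)
  imp <- as.numeric(fit$importance)
  names(imp) <- table@units
  new("TreeModel", trees = fit$trees, treeWeights = fit$treeWeights,
      attributes = table@units, levels = stats::setNames(levels, table@units),
      importance = imp, costs = costs, config = config)
}

#' Predict target firing for interval rows
#'
#' Routes each row down the tree(s) by its categorical codes; categories not
#' seen in training follow the fallback branch (the branch that received the
#' most training cases). Committees vote with their per-trial weights and the
#' vote is thresholded at minimum expected cost.
#'
#' @param object a [TreeModel-class].
#' @param newdata an [IntervalTable-class] or a character code matrix with
#'   the model's attributes as columns.
#' @param ... unused.
#' @return Integer vector of predicted classes (0/1).
#' @export
setMethod("predict", "TreeModel", function(object, newdata, ...) {
  codes <- if (is(newdata, "IntervalTable")) newdata@codes else newdata
  missing <- setdiff(object@attributes, colnames(codes))
  if (length(missing))
    stop("missing attribute column(s): ", paste(missing, collapse = ", "))
  codes <- codes[, object@attributes, drop = FALSE]
  x <- .encodeMatrix(codes, object@levels)
  votes <- numeric(nrow(x))
  for (k in seq_along(object@trees)) {
    tr <- object@trees[[k]]
    p <- cpp_predict_tree(x, tr$is_leaf, tr$attr, tr$cls, tr$fallback,
                          tr$branch_node, tr$branch_level, tr$branch_child)
    votes <- votes + object@treeWeights[k] * p
  }
  p1 <- votes / sum(object@treeWeights)
  # expected cost of predicting 0 is p1 * fnCost, of predicting 1 (1-p1) * fpCost
  as.integer(p1 * object@costs@fnCost > (1 - p1) * object@costs@fpCost)
})

#' @rdname variableImportance
#' @export
setMethod("variableImportance", "TreeModel", function(model) model@importance)

#' @rdname primaryGroup
#' @export
setMethod("primaryGroup", "TreeModel", function(model)
  model@attributes[model@importance > 0])

#' @rdname extractRules
#' @export
setMethod("extractRules", "TreeModel", function(model) {
  if (length(model@trees) != 1L)
    stop("rule extraction is only supported for single-tree models (trials = 1)")
  tr <- model@trees[[1]]
  nn <- length(tr$is_leaf)
  parent <- rep(NA_integer_, nn)
  viaLevel <- rep(NA_integer_, nn)
  for (j in seq_along(tr$branch_node)) {
    parent[tr$branch_child[j]] <- tr$branch_node[j]
    viaLevel[tr$branch_child[j]] <- tr$branch_level[j]
  }
  leaves <- which(tr$is_leaf == 1L)
  rules <- character(0); cls <- integer(0); cov <- numeric(0)
  tests <- list()
  for (lf in leaves) {
    path <- list()
    node <- lf
    while (!is.na(parent[node])) {
      pa <- parent[node]
      attr <- model@attributes[tr$attr[pa]]
      lev <- model@levels[[tr$attr[pa]]][viaLevel[node]]
      path[[length(path) + 1L]] <- c(attr = attr, level = lev)
      node <- pa
    }
    path <- rev(path)
    txt <- if (length(path))
      paste(vapply(path, function(p) paste0(p["attr"], " = ", p["level"]),
                   character(1)), collapse = " & ")
    else "TRUE"
    rules <- c(rules, txt)
    cls <- c(cls, tr$cls[lf])
    cov <- c(cov, tr$n[lf])
    tests[[length(tests) + 1L]] <- path
  }
  out <- data.frame(rule = rules, class = cls, coverage = cov,
                    stringsAsFactors = FALSE)
  attr(out, "tests") <- tests
  out
})

#' Classify rows with an extracted rule set
#'
#' Applies the rules of [extractRules()] to interval rows; over categories
#' seen in training, exactly one rule matches each row and the result equals
#' [predict()]. Rows matching no rule (unseen categories) return `NA`.
#'
#' @param rules the data.frame returned by [extractRules()].
#' @param newdata an [IntervalTable-class] or character code matrix.
#' @return Integer vector of classes, `NA` where no rule matches.
#' @export
applyRules <- function(rules, newdata) {
  codes <- if (is(newdata, "IntervalTable")) newdata@codes else newdata
  tests <- attr(rules, "tests")
  out <- rep(NA_integer_, nrow(codes))
  for (i in seq_along(tests)) {
    ok <- rep(TRUE, nrow(codes))
    for (p in tests[[i]])
      ok <- ok & codes[, p["attr"]] == p["level"]
    out[ok & is.na(out)] <- rules$class[i]
  }
  out
}

#' Serialize a tree model to versioned JSON
#'
#' @param model a [TreeModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTreeModel <- function(model, path) {
  obj <- list(
    format = "connectree-treemodel", version = 1L,
    attributes = model@attributes,
    levels = model@levels,
    treeWeights = model@treeWeights,
    trees = model@trees,
    importance = as.list(model@importance),
    costs = list(fnCost = model@costs@fnCost, fpCost = model@costs@fpCost),
    config = list(trials = model@config@trials,
                  pruneConfidence = model@config@pruneConfidence,
                  minCases = model@config@minCases))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized tree model
#'
#' @param path a file written by [writeTreeModel()].
#' @return A [TreeModel-class].
#' @export
readTreeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "connectree-treemodel"))
    stop("not a connectree tree-model file: ", path)
  trees <- lapply(seq_len(length(obj$treeWeights)), function(k) {
    tr <- lapply(obj$trees[[k]], function(v) v)
    tr$is_leaf <- as.integer(tr$is_leaf)
    tr$attr <- as.integer(tr$attr)
    tr$cls <- as.integer(tr$cls)
    tr$fallback <- as.integer(tr$fallback)
    tr$branch_node <- as.integer(tr$branch_node)
    tr$branch_level <- as.integer(tr$branch_level)
    tr$branch_child <- as.integer(tr$branch_child)
    tr
  })
  levels <- obj$levels
  if (is.null(names(levels))) names(levels) <- obj$attributes
  levels <- lapply(levels, as.character)
  imp <- unlist(obj$importance)
  new("TreeModel", trees = trees, treeWeights = as.numeric(obj$treeWeights),
      attributes = as.character(obj$attributes),
      levels = levels,
      importance = stats::setNames(as.numeric(imp), obj$attributes),
      costs = costMatrix(obj$costs$fnCost, obj$costs$fpCost),
      config = fitConfig(obj$config$trials, obj$config$pruneConfidence,
                         obj$config$minCases))
}
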