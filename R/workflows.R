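#' Direct analysis: a single run (or multi-seed summary) over a unit set
#'
#' The baseline procedure: undersample, fit one cost-sensitive tree on all
#' requested units, report metrics and the primary group (the units actually
#' used to build rules).
#'
#' @inheritParams runOnce
#' @param nSeeds if `> 1`, repeat over that many undersampling seeds and
#'   also return the multi-seed summary.
#' @return For `nSeeds = 1` a `RunResult`; otherwise the [runMultiSeed()]
#'   list with an extra element `primaryGroups` (one per seed).
#' @export
directAnalysis <- function(table, units = NULL, costs = costMatrix(),
                           config = fitConfig(), seed, nSeeds = 1, ratio = 4) {
  if (nSeeds <= 1)
    return(runOnce(table, units = units, costs = costs, config = config,
                   seed = seed, ratio = ratio))
  res <- runMultiSeed(table, units = units, costs = costs, config = config,
                      nSeeds = nSeeds, seed = seed, ratio = ratio)
  res$primaryGroups <- lapply(res$runs, `[[`, "primaryGroup")
  res
}

#' Individual analysis: one single-unit model per unit
#'
#' Fits a model per unit, with that unit as the only predictor, and ranks
#' units by the MCC obtained on the complete dataset. All units share the
#' same snap partition (same seed) so their metrics are comparable.
#'
#' @inheritParams runOnce
#' @return data.frame with columns `unit`, `precision`, `recall`, `mcc`
#'   (complete-dataset metrics), sorted by decreasing MCC.
#' @export
individualAnalysis <- function(table, units = NULL, costs = costMatrix(),
                               config = fitConfig(), seed, ratio = 4) {
  stopifnot(is(table, "IntervalTable"))
  if (is.null(units)) units <- table@units
  if (!length(units)) stop("need at least one unit")
  rows <- lapply(units, function(u) {
    r <- suppressWarnings(
      runOnce(table, units = u, costs = costs, config = config,
              seed = seed, ratio = ratio))
    m <- r$metrics[r$metrics$subset == "complete", ]
    data.frame(unit = u, precision = m$precision, recall = m$recall,
               mcc = m$mcc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mcc, match(out$unit, units)), , drop = FALSE]
}

#' Number of nonempty unit subsets
#'
#' The number of models the combinatory analysis fits for `n` units: the sum
#' of binomial coefficients choose(n, r) over r = 1..n, i.e. `2^n - 1`.
#'
#' @param n number of units (>= 1).
#' @return `2^n - 1`.
#' @examples
#' countSubsets(13)  # 8191
#' @export
countSubsets <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  2^n - 1
}

#' Combinatory analysis: exhaustive search over unit subsets
#'
#' Fits one model for every nonempty subset of the units (all `2^n - 1` of
#' them) and ranks subsets by complete-dataset MCC. Within one seed all
#' subsets share the same snap partition so their MCCs are comparable
#' (`resample = TRUE` redraws negatives per subset instead). The relevant
#' group is read off the frequency with which each unit appears in the top
#' `cutoff` fraction of ranked subsets: units whose frequency reaches half
#' the maximum frequency are retained.
#'
#' @inheritParams runOnce
#' @param cutoff top fraction of the ranking used for the frequency
#'   histogram (default 0.01, the first percentile).
#' @param maxUnits guard on `n`; the search is exponential, use the
#'   iterative or recursive procedures for larger sets.
#' @param resample redraw the snap partition per subset.
#' @return List of class `GroupRanking`: `ranking` (data.frame `subset`,
#'   `size`, `mcc`, units separated by `+`), `frequency` (named counts over
#'   the top percentile), `relevantGroup`, `topN`, `seed`.
#' @export
combinatoryAnalysis <- function(table, units = NULL, costs = costMatrix(),
                                config = fitConfig(), seed, cutoff = 0.01,
                                ratio = 4, maxUnits = 16, resample = FALSE) {
  stopifnot(is(table, "IntervalTable"))
  if (is.null(units)) units <- table@units
  n <- length(units)
  if (n > maxUnits)
    stop("combinatory search over ", n, " units would need ", countSubsets(n),
         " fits; use iterativeAnalysis() or recursiveAnalysis() instead")
  tab <- subsetUnits(table, units)
  part <- snapSample(tab, ratio = ratio, seed = seed)
  y <- tab@fired
  yTrain <- y[part$training]
  levels <- .codeLevels(tab@codes[part$training, , drop = FALSE])
  xTrain <- .encodeMatrix(tab@codes[part$training, , drop = FALSE], levels)
  xAll <- .encodeMatrix(tab@codes, levels)
  nlev <- vapply(levels, length, integer(1))

  total <- countSubsets(n)
  mcc <- numeric(total)
  size <- integer(total)
  members <- vector("list", total)
  bits <- 2L^(seq_len(n) - 1L)
  for (mask in seq_len(total)) {
    cols <- which(bitwAnd(mask, bits) != 0L)
    if (resample) {
      p2 <- snapSample(tab, ratio = ratio, seed = seed + mask)
      yTr <- y[p2$training]
      xTr <- xAll[p2$training, cols, drop = FALSE]
    } else {
      yTr <- yTrain
      xTr <- xTrain[, cols, drop = FALSE]
    }
    fit <- .fitCore(xTr, nlev[cols], yTr, costs, config)
    tr <- fit$trees[[1]]
    if (length(fit$trees) == 1L) {
      pred <- cpp_predict_tree(xAll[, cols, drop = FALSE], tr$is_leaf, tr$attr,
                               tr$cls, tr$fallback, tr$branch_node,
                               tr$branch_level, tr$branch_child)
    } else {
      votes <- numeric(nrow(xAll))
      for (k in seq_along(fit$trees)) {
        trk <- fit$trees[[k]]
        votes <- votes + fit$treeWeights[k] *
          cpp_predict_tree(xAll[, cols, drop = FALSE], trk$is_leaf, trk$attr,
                           trk$cls, trk$fallback, trk$branch_node,
                           trk$branch_level, trk$branch_child)
      }
      p1 <- votes / sum(fit$treeWeights)
      pred <- as.integer(p1 * costs@fnCost > (1 - p1) * costs@fpCost)
    }
    mcc[mask] <- computeMetrics(confusionMatrix(pred, y))[["mcc"]]
    size[mask] <- length(cols)
    members[[mask]] <- cols
  }

  # rank: decreasing MCC, ties toward smaller groups, then unit order
  lex <- vapply(members, function(m) paste(sprintf("%02d", m), collapse = ""),
                character(1))
  ord <- order(-mcc, size, lex)
  ranking <- data.frame(
    subset = vapply(members[ord], function(m) paste(units[m], collapse = "+"),
                    character(1)),
    size = size[ord], mcc = mcc[ord], stringsAsFactors = FALSE)
  topN <- ceiling(cutoff * total)
  freq <- integer(n)
  for (mask in seq_len(topN))
    freq[members[[ord[mask]]]] <- freq[members[[ord[mask]]]] + 1L
  names(freq) <- units
  relevant <- units[freq >= 0.5 * max(freq)]
  structure(list(ranking = ranking, frequency = freq,
                 relevantGroup = relevant, topN = topN, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "GroupRanking")
}

#' @export
print.GroupRanking <- function(x, ...) {
  cat("GroupRanking:", nrow(x$ranking), "subsets; top", x$topN,
      "used for frequencies\n")
  print(head(x$ranking, 5), digits = 3)
  cat("relevant group:", paste(x$relevantGroup, collapse = ", "), "\n")
  invisible(x)
}

#' Iterative analysis: backward elimination by individual MCC
#'
#' Ranks units by their individual MCC, then repeatedly drops the
#' lowest-ranked remaining unit, refitting the model on the survivors at
#' each epoch and recording complete-dataset metrics. The critical point is
#' the smallest group whose MCC is within `tolerance` of the trajectory
#' maximum.
#'
#' @inheritParams runOnce
#' @param prefilter drop units with individual MCC <= 0 before iterating.
#' @param tolerance MCC slack defining the critical point (default 0.01).
#' @return List of class `IterativeTrajectory`: `steps` (data.frame `epoch`,
#'   `size`, `units`, `precision`, `recall`, `mcc`), `subsets` (list),
#'   `individual` (the individual ranking used), `criticalPoint` (epoch
#'   index), `criticalGroup`.
#' @export
iterativeAnalysis <- function(table, units = NULL, costs = costMatrix(),
                              config = fitConfig(), seed, ratio = 4,
                              prefilter = FALSE, tolerance = 0.01) {
  stopifnot(is(table, "IntervalTable"))
  if (is.null(units)) units <- table@units
  if (length(units) < 2) stop("need at least 2 units")
  indiv <- individualAnalysis(table, units = units, costs = costs,
                              config = config, seed = seed, ratio = ratio)
  current <- indiv$unit                 # best first
  if (prefilter) current <- indiv$unit[indiv$mcc > 0]
  steps <- list()
  subsets <- list()
  epoch <- 0L
  while (length(current) >= 1L) {
    epoch <- epoch + 1L
    r <- tryCatch(
      suppressWarnings(runOnce(table, units = current, costs = costs,
                               config = config, seed = seed, ratio = ratio)),
      error = function(e) NULL)
    m <- if (is.null(r)) c(precision = 0, recall = 0, mcc = 0)
         else unlist(r$metrics[r$metrics$subset == "complete",
                               c("precision", "recall", "mcc")])
    steps[[epoch]] <- data.frame(epoch = epoch, size = length(current),
                                 units = paste(current, collapse = "+"),
                                 precision = m[["precision"]],
                                 recall = m[["recall"]], mcc = m[["mcc"]],
                                 stringsAsFactors = FALSE)
    subsets[[epoch]] <- current
    current <- current[-length(current)]   # drop the worst-ranked survivor
  }
  steps <- do.call(rbind, steps)
  best <- max(steps$mcc)
  eligible <- which(steps$mcc >= best - tolerance)
  crit <- eligible[which.min(steps$size[eligible])]
  structure(list(steps = steps, subsets = subsets, individual = indiv,
                 criticalPoint = crit, criticalGroup = subsets[[crit]],
                 seed = as.integer(seed)),
            class = "IterativeTrajectory")
}

#' @export
print.IterativeTrajectory <- function(x, ...) {
  cat("IterativeTrajectory:", nrow(x$steps), "epochs; critical point at epoch",
      x$criticalPoint, "(", length(x$criticalGroup), "units )\n")
  cat("critical group:", paste(x$criticalGroup, collapse = ", "), "\n")
  invisible(x)
}

#' Recursive analysis: split units by variable importance
#'
#' Fits a model on the current unit set and splits it into the primary group
#' (variable importance > 0) and the secondary group (importance 0), then
#' recurses into both. When every unit has positive importance, the set is
#' split at the importance median instead (upper half primary). Branches
#' stop at single units, at fits that use no unit at all (fit failure), or
#' at `maxDepth`.
#'
#' @inheritParams runOnce
#' @param maxDepth maximal recursion depth.
#' @return A tree of nodes (class `RecursiveNode`); each node is a list with
#'   `units`, `mcc`, `importance`, `fitFailed`, `depth` and children
#'   `primary`/`secondary` (or `NULL`).
#' @export
recursiveAnalysis <- function(table, units = NULL, costs = costMatrix(),
                              config = fitConfig(), seed, ratio = 4,
                              maxDepth = Inf) {
  stopifnot(is(table, "IntervalTable"))
  if (is.null(units)) units <- table@units
  if (!length(units)) stop("need at least one unit")
  recurse <- function(us, depth) {
    r <- tryCatch(
      suppressWarnings(runOnce(table, units = us, costs = costs,
                               config = config, seed = seed, ratio = ratio)),
      error = function(e) NULL)
    node <- list(units = us, depth = depth, fitFailed = is.null(r),
                 mcc = NA_real_, importance = NULL,
                 primary = NULL, secondary = NULL)
    if (is.null(r)) return(structure(node, class = "RecursiveNode"))
    node$mcc <- r$metrics$mcc[r$metrics$subset == "complete"]
    imp <- variableImportance(r$model)
    node$importance <- imp
    if (length(us) == 1L || all(imp == 0) || depth >= maxDepth)
      return(structure(node, class = "RecursiveNode"))
    if (any(imp == 0)) {
      primary <- us[imp > 0]
      secondary <- us[imp == 0]
    } else {
      med <- stats::median(imp)
      primary <- us[imp > med]
      if (!length(primary)) primary <- us[imp >= med]
      secondary <- setdiff(us, primary)
    }
    if (length(primary) && length(primary) < length(us))
      node$primary <- recurse(primary, depth + 1L)
    if (length(secondary))
      node$secondary <- recurse(secondary, depth + 1L)
    structure(node, class = "RecursiveNode")
  }
  recurse(units, 1L)
}

#' @export
print.RecursiveNode <- function(x, ...) {
  rec <- function(node, indent) {
    cat(strrep("  ", indent), "[", length(node$units), " units] ",
        if (node$fitFailed) "fit failed"
        else sprintf("MCC %.3f", node$mcc), ": ",
        paste(head(node$units, 8), collapse = ","),
        if (length(node$units) > 8) ",..." else "", "\n", sep = "")
    if (!is.null(node$primary)) rec(node$primary, indent + 1)
    if (!is.null(node$secondary)) rec(node$secondary, indent + 1)
  }
  rec(x, 0)
  invisible(x)
}

#' Flatten a recursive-analysis tree
#'
#' @param node a `RecursiveNode` from [recursiveAnalysis()].
#' @return data.frame with one row per node: `depth`, `branch`, `size`,
#'   `units`, `mcc`, `fitFailed`.
#' @export
recursionTable <- function(node) {
  rows <- list()
  rec <- function(nd, branch) {
    rows[[length(rows) + 1L]] <<- data.frame(
      depth = nd$depth, branch = branch, size = length(nd$units),
      units = paste(nd$units, collapse = "+"),
      mcc = nd$mcc, fitFailed = nd$fitFailed, stringsAsFactors = FALSE)
    if (!is.null(nd$primary)) rec(nd$primary, "primary")
    if (!is.null(nd$secondary)) rec(nd$secondary, "secondary")
  }
  rec(node, "root")
  do.call(rbind, rows)
}
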