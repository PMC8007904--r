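#' Confusion matrix of a binary prediction
#'
#' @param predicted,actual integer vectors of 0/1 classes.
#' @return Named numeric vector with elements `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusionMatrix(c(1, 0, 1), c(1, 0, 0))
#' @export
confusionMatrix <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  c(tp = sum(predicted == 1 & actual == 1),
    tn = sum(predicted == 0 & actual == 0),
    fp = sum(predicted == 1 & actual == 0),
    fn = sum(predicted == 0 & actual == 1))
}

#' Precision, recall and Matthews correlation coefficient
#'
#' `precision = TP / (FP + TP)`, `recall = TP / (FN + TP)`, and
#' `MCC = (TP * TN - FP * FN) / sqrt((TP + FP)(TP + FN)(TN + FP)(TN + FN))`.
#' When a denominator is zero the corresponding metric is defined as 0 (the
#' usual convention for degenerate margins).
#'
#' @param cm a named vector with `tp`, `tn`, `fp`, `fn`, as returned by
#'   [confusionMatrix()].
#' @return Named numeric vector `precision`, `recall`, `mcc`.
#' @examples
#' computeMetrics(c(tp = 10, tn = 40, fp = 0, fn = 0))
#' @export
computeMetrics <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); tn <- as.numeric(cm[["tn"]])
  fp <- as.numeric(cm[["fp"]]); fn <- as.numeric(cm[["fn"]])
  if (tp + tn + fp + fn <= 0) stop("empty confusion matrix")
  precision <- if (tp + fp > 0) tp / (fp + tp) else 0
  recall <- if (tp + fn > 0) tp / (fn + tp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(precision = precision, recall = recall, mcc = mcc)
}

#' Undersample negatives into a snap partition
#'
#' Builds the working ("snap") dataset: all positive intervals plus
#' `ratio` times as many negatives, sampled uniformly without replacement
#' (all negatives, with a warning, if fewer are available). The snap set is
#' then split 80/20 into training and validation, stratified by class:
#' `floor(0.8 * n)` of each class to training, the remainder to validation,
#' with random assignment.
#'
#' @param table an [IntervalTable-class].
#' @param ratio negatives per positive in the snap set (default 4).
#' @param seed integer RNG seed; the partition is reproducible from it.
#' @param trainFraction fraction of each class assigned to training.
#' @return List with integer row-index vectors `snap`, `training`,
#'   `validation` (indices into `table`), plus `positives`, `negatives`,
#'   `ratio` and `seed`.
#' @export
snapSample <- function(table, ratio = 4, seed, trainFraction = 0.8) {
  stopifnot(is(table, "IntervalTable"))
  pos <- which(table@fired == 1L)
  neg <- which(table@fired == 0L)
  if (!length(pos)) stop("no positive intervals in the table")
  set.seed(as.integer(seed))
  nNeg <- round(ratio * length(pos))
  if (length(neg) < nNeg) {
    warning("only ", length(neg), " negatives available; keeping all of them")
    negS <- neg
  } else {
    negS <- sort(sample(neg, nNeg))
  }
  trainPos <- sort(sample(pos, floor(trainFraction * length(pos))))
  trainNeg <- sort(sample(negS, floor(trainFraction * length(negS))))
  training <- sort(c(trainPos, trainNeg))
  snap <- sort(c(pos, negS))
  list(snap = snap, training = training,
       validation = setdiff(snap, training),
       positives = pos, negatives = negS,
       ratio = ratio, seed = as.integer(seed))
}

# internal: row subset of an IntervalTable
.subsetRows <- function(table, idx) {
  new("IntervalTable", timestamps = table@timestamps[idx],
      codes = table@codes[idx, , drop = FALSE],
      fired = table@fired[idx], units = table@units, target = table@target,
      window = table@window, bin = table@bin)
}

#' One modelling run: snap, fit, evaluate
#'
#' Draws a snap partition, fits a tree on the training rows, and evaluates
#' the fitted model on the training, validation, snap and complete datasets.
#'
#' @param table an [IntervalTable-class].
#' @param units optional predictor subset.
#' @param costs a [CostMatrix-class].
#' @param config a [FitConfig-class].
#' @param seed integer seed controlling the snap partition.
#' @param ratio undersampling ratio, see [snapSample()].
#' @return List of class `RunResult`: `model` ([TreeModel-class]),
#'   `metrics` (data.frame with one row per subset), `confusion` (list of
#'   confusion matrices), `primaryGroup`, `partition`, `seed`.
#' @examples
#' sts <- spikeTrainSet(list(U1 = c(0.06, 0.26), U2 = c(0.07, 0.27)),
#'                      duration = 1)
#' tab <- extractIntervals(sts, "U2")
#' r <- runOnce(tab, seed = 1)
#' r$metrics
#' @export
runOnce <- function(table, units = NULL, costs = costMatrix(),
                    config = fitConfig(), seed, ratio = 4) {
  stopifnot(is(table, "IntervalTable"))
  if (!is.null(units)) table <- subsetUnits(table, units)
  part <- snapSample(table, ratio = ratio, seed = seed)
  model <- fitTree(.subsetRows(table, part$training),
                   costs = costs, config = config)
  pred <- predict(model, table)
  subsets <- list(complete = seq_along(table@fired), snap = part$snap,
                  training = part$training, validation = part$validation)
  confusion <- lapply(subsets, function(idx)
    confusionMatrix(pred[idx], table@fired[idx]))
  metrics <- do.call(rbind, lapply(confusion, computeMetrics))
  metrics <- data.frame(subset = names(subsets), metrics,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model, metrics = metrics, confusion = confusion,
                 primaryGroup = primaryGroup(model), partition = part,
                 seed = as.integer(seed)),
            class = "RunResult")
}

#' @export
print.RunResult <- function(x, ...) {
  cat("RunResult (seed ", x$seed, ")\n", sep = "")
  print(x$metrics, digits = 3)
  cat("primary group:", paste(x$primaryGroup, collapse = ", "), "\n")
  invisible(x)
}

#' Repeat a run over many undersampling seeds
#'
#' Runs [runOnce()] with `nSeeds` different snap-partition seeds, derived
#' reproducibly from the master seed, and summarises each metric per subset
#' as mean and standard error of the mean (sample SD / sqrt(n)).
#'
#' @inheritParams runOnce
#' @param nSeeds number of repetitions (default 30).
#' @param seed master seed from which the repetition seeds are drawn.
#' @return List with `summary` (data.frame: subset, metric means and SEMs),
#'   `runs` (list of `RunResult`), and `seeds`.
#' @export
runMultiSeed <- function(table, units = NULL, costs = costMatrix(),
                         config = fitConfig(), nSeeds = 30, seed, ratio = 4) {
  stopifnot(nSeeds >= 2)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max %/% 2L, nSeeds)
  runs <- lapply(seeds, function(s)
    runOnce(table, units = units, costs = costs, config = config,
            seed = s, ratio = ratio))
  subsets <- runs[[1]]$metrics$subset
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  summary <- do.call(rbind, lapply(seq_along(subsets), function(i) {
    vals <- vapply(runs, function(r)
      unlist(r$metrics[i, c("precision", "recall", "mcc")]), numeric(3))
    data.frame(subset = subsets[i],
               precision_mean = mean(vals[1, ]), precision_sem = sem(vals[1, ]),
               recall_mean = mean(vals[2, ]), recall_sem = sem(vals[2, ]),
               mcc_mean = mean(vals[3, ]), mcc_sem = sem(vals[3, ]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, runs = runs, seeds = seeds)
}

#' Cross-correlogram between two spike trains
#'
#' Histogram of time lags from each trigger spike to the other unit's spikes
#' within `windowMs` of it. A peak at negative lags means the other unit
#' tends to fire before the trigger.
#'
#' @param trigger,other numeric spike-time vectors in seconds.
#' @param binMs histogram bin width (ms).
#' @param windowMs maximal absolute lag (ms).
#' @return data.frame with bin centre `lag_ms` and `count`.
#' @export
crossCorrelogram <- function(trigger, other, binMs = 1, windowMs = 50) {
  if (!length(trigger) || !length(other)) {
    warning("empty spike train; returning an empty histogram")
    return(data.frame(lag_ms = numeric(0), count = integer(0)))
  }
  w <- windowMs / 1000
  other <- sort(other)
  lo <- findInterval(trigger - w, other)
  hi <- findInterval(trigger + w, other)
  cnt <- hi - lo
  rows <- which(cnt > 0L)
  lags <- numeric(0)
  if (length(rows)) {
    rr <- rep.int(rows, cnt[rows])
    si <- sequence(cnt[rows]) + rep.int(lo[rows], cnt[rows])
    lags <- (other[si] - trigger[rr]) * 1000
  }
  breaks <- seq(-windowMs, windowMs, by = binMs)
  lags <- lags[lags > -windowMs & lags <= windowMs]
  h <- tabulate(findInterval(lags, breaks, left.open = TRUE,
                             rightmost.closed = FALSE),
                nbins = length(breaks) - 1)
  data.frame(lag_ms = breaks[-length(breaks)] + binMs / 2, count = h)
}
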