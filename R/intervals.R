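#' Encode spike offsets as a categorical interval code
#'
#' Each spike preceding an interval timestamp by an offset in `[0, window)`
#' ms receives one letter: `A` for offsets in `[0, bin)`, `B` for
#' `[bin, 2 bin)`, and so on; bins are half-open, so an offset of exactly
#' 10 ms codes `B` and an offset of 50 ms falls outside the window. Letters
#' are concatenated in alphabetical order; no spike gives `"0"`.
#'
#' @param offsetsMs numeric vector of offsets before the timestamp, in ms.
#' @param binMs bin width in ms.
#' @param windowMs window length in ms.
#' @return A single code string.
#' @examples
#' encodeCode(numeric(0))        # "0"
#' encodeCode(c(12, 15, 33))     # "BBD"
#' @export
encodeCode <- function(offsetsMs, binMs = 10, windowMs = 50) {
  if (!length(offsetsMs)) return("0")
  if (any(offsetsMs < 0 | offsetsMs >= windowMs))
    stop("offsets must lie in [0, ", windowMs, ") ms")
  k <- floor(offsetsMs / binMs)
  paste(sort(LETTERS[k + 1]), collapse = "")
}

#' Extract the categorical interval table from spike trains
#'
#' Implements the interval definition used throughout the package. Every
#' target spike at time `t >= window` defines a positive interval with
#' timestamp `t` (class 1); the predictor units' spikes within the preceding
#' `window` ms are encoded with [encodeCode()]. The recording time outside
#' the union of the positive windows is tiled forward, gap by gap, into
#' `window`-sized negative intervals (class 0) whose timestamp is the block
#' end; each gap's terminal remainder shorter than `window` is discarded.
#' The target's own spikes never appear as predictor codes.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param target unit id of the target.
#' @param windowMs interval length in ms (must be a multiple of `binMs`).
#' @param binMs code bin width in ms.
#' @return An [IntervalTable-class].
#' @examples
#' sts <- spikeTrainSet(list(U1 = c(0.012, 0.24), U2 = c(0.25)), duration = 1)
#' tab <- extractIntervals(sts, "U2")
#' @export
extractIntervals <- function(spikes, target, windowMs = 50, binMs = 10) {
  stopifnot(is(spikes, "SpikeTrainSet"))
  if (!target %in% names(spikes@trains))
    stop("target unit ", target, " not present in the spike-train set")
  if (windowMs %% binMs != 0) stop("windowMs must be a multiple of binMs")
  w <- windowMs / 1000
  duration <- spikes@duration
  units <- setdiff(names(spikes@trains), target)

  if (duration < w) {
    warning("recording shorter than one window; returning an empty table")
    return(new("IntervalTable", timestamps = numeric(0),
               codes = matrix(character(0), 0, length(units),
                              dimnames = list(NULL, units)),
               fired = integer(0), units = units, target = target,
               window = windowMs, bin = binMs))
  }

  tSpikes <- spikes@trains[[target]]
  posTs <- tSpikes[tSpikes >= w]          # spikes in the initial window dropped

  # union of positive windows (t - w, t], merged over overlapping spikes
  negTs <- numeric(0)
  if (length(tSpikes)) {
    lo <- tSpikes - w
    hi <- tSpikes
    # merge overlapping positive windows; spikes are sorted, so each merged
    # block starts at the first member's lo and ends at the last member's hi
    newBlock <- c(TRUE, lo[-1] > hi[-length(hi)] + 1e-12)
    starts <- which(newBlock)
    ends <- c(starts[-1] - 1L, length(hi))
    gapStart <- pmax(c(0, hi[ends]), 0)
    gapEnd <- c(lo[starts], duration)
  } else {
    gapStart <- 0
    gapEnd <- duration
  }
  for (g in seq_along(gapStart)) {
    len <- gapEnd[g] - gapStart[g]
    nb <- floor(len / w + 1e-9)
    if (nb >= 1) negTs <- c(negTs, gapStart[g] + w * seq_len(nb))
  }

  ts <- c(posTs, negTs)
  fired <- c(rep(1L, length(posTs)), rep(0L, length(negTs)))
  ord <- order(ts, -fired)
  ts <- ts[ord]; fired <- fired[ord]
  n <- length(ts)

  codes <- matrix("0", n, length(units), dimnames = list(NULL, units))
  if (n) {
    nBins <- windowMs / binMs
    for (j in seq_along(units)) {
      sp <- spikes@trains[[units[j]]]
      if (!length(sp)) next
      # 1e-9 s slack absorbs double rounding; spike times have >= 1 ms
      # resolution so no real spike sits within it
      lo <- findInterval(ts - w + 1e-9, sp)  # spikes <= ts - w excluded
      hi <- findInterval(ts + 1e-9, sp)      # spikes <= ts included
      cnt <- hi - lo
      rows <- which(cnt > 0L)
      if (!length(rows)) next
      rr <- rep.int(rows, cnt[rows])
      si <- sequence(cnt[rows]) + rep.int(lo[rows], cnt[rows])
      offMs <- round((ts[rr] - sp[si]) * 1000, 3)
      bin <- floor(offMs / binMs + 1e-9)
      bin[bin >= nBins] <- nBins - 1      # fp guard at the far edge
      lt <- LETTERS[bin + 1]
      # spikes ascend within a row, so offsets descend: reversing the
      # per-row letter order yields alphabetically sorted codes
      dt <- data.table::data.table(r = rr, lt = lt)
      agg <- dt[, list(code = paste(rev(lt), collapse = "")), by = "r"]
      codes[agg$r, j] <- agg$code
    }
  }

  new("IntervalTable", timestamps = ts, codes = codes, fired = fired,
      units = units, target = target,
      window = as.numeric(windowMs), bin = as.numeric(binMs))
}

#' Restrict an interval table to a subset of predictor units
#'
#' @param table an [IntervalTable-class].
#' @param units character vector of predictor unit ids to keep.
#' @return An [IntervalTable-class] with the selected code columns.
#' @export
subsetUnits <- function(table, units) {
  stopifnot(is(table, "IntervalTable"))
  missing <- setdiff(units, table@units)
  if (length(missing))
    stop("unknown unit id(s): ", paste(missing, collapse = ", "))
  new("IntervalTable", timestamps = table@timestamps,
      codes = table@codes[, units, drop = FALSE], fired = table@fired,
      units = units, target = table@target,
      window = table@window, bin = table@bin)
}
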