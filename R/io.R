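#' Write spike trains to long-format CSV
#'
#' One row per spike, header `unit_id,spike_time_s`, times in seconds.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpikeCSV <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeTrainSet"))
  ns <- vapply(spikes@trains, length, integer(1))
  df <- data.frame(unit_id = rep(names(spikes@trains), ns),
                   spike_time_s = unlist(spikes@trains, use.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains from long-format CSV
#'
#' Expects the header `unit_id,spike_time_s`. Unsorted times are accepted
#' and sorted with a warning; non-numeric times or duplicate times within a
#' unit raise an error naming the offending line.
#'
#' @param path CSV file path.
#' @param duration recording duration in seconds; defaults to the last spike
#'   time rounded up to the next whole second.
#' @param units optional unit ids to guarantee in the result (silent units
#'   get empty trains).
#' @return A [SpikeTrainSet-class].
#' @export
readSpikeCSV <- function(path, duration = NULL, units = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df)[1:2], c("unit_id", "spike_time_s")))
    stop("malformed header in ", path,
         ": expected 'unit_id,spike_time_s', got '",
         paste(names(df), collapse = ","), "'")
  t <- suppressWarnings(as.numeric(df$spike_time_s))
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop("non-numeric spike time at line ", bad + 1L, " of ", path)
  }
  ids <- df$unit_id
  if (is.null(duration)) duration <- if (length(t)) ceiling(max(t) + 1e-9) else 1
  allUnits <- if (is.null(units)) unique(ids) else units
  trains <- stats::setNames(
    lapply(allUnits, function(u) t[ids == u]), allUnits)
  for (u in allUnits) {
    tr <- trains[[u]]
    if (is.unsorted(tr)) {
      warning("spike times for unit ", u, " are not sorted; sorting")
      trains[[u]] <- tr <- sort(tr)
    }
    if (anyDuplicated(tr)) {
      dup <- tr[duplicated(tr)][1]
      line <- which(ids == u & t == dup)[2]
      stop("duplicate spike time for unit ", u, " at line ", line + 1L,
           " of ", path)
    }
  }
  new("SpikeTrainSet", trains = trains, duration = as.numeric(duration))
}

#' Write ground-truth connectivity labels to CSV
#'
#' Header `unit_id,label`.
#'
#' @param labels the data.frame from [groundTruth()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthCSV <- function(labels, path) {
  df <- data.frame(unit_id = labels$unit, label = labels$label)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interval table to CSV
#'
#' Header `timestamp_s,<unit...>,R`; one row per interval, codes as strings,
#' `R` the 0/1 class.
#'
#' @param table an [IntervalTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIntervalCSV <- function(table, path) {
  stopifnot(is(table, "IntervalTable"))
  df <- data.frame(timestamp_s = table@timestamps,
                   table@codes, R = table@fired, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interval table from CSV
#'
#' Inverse of [writeIntervalCSV()]. The target unit id is not stored in the
#' file and can be supplied for bookkeeping.
#'
#' @param path CSV file path.
#' @param target target unit id to record in the table.
#' @param windowMs,binMs encoding parameters to record in the table.
#' @return An [IntervalTable-class].
#' @export
readIntervalCSV <- function(path, target = "target", windowMs = 50, binMs = 10) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (names(df)[1] != "timestamp_s" || names(df)[ncol(df)] != "R")
    stop("malformed header in ", path,
         ": expected 'timestamp_s,<units...>,R'")
  ts <- suppressWarnings(as.numeric(df$timestamp_s))
  if (anyNA(ts)) stop("non-numeric timestamp at line ", which(is.na(ts))[1] + 1L)
  units <- setdiff(names(df), c("timestamp_s", "R"))
  codes <- as.matrix(df[, units, drop = FALSE])
  rownames(codes) <- NULL
  new("IntervalTable", timestamps = ts, codes = codes,
      fired = as.integer(df$R), units = units, target = target,
      window = as.numeric(windowMs), bin = as.numeric(binMs))
}

#' Write a metrics report to CSV
#'
#' Accepts either the `metrics` data.frame of a single run
#' (`subset,precision,recall,mcc`) or the multi-seed `summary` with mean and
#' SEM columns.
#'
#' @param metrics a metrics data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetricsCSV <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
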