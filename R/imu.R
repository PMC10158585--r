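## Hit-event detection from inertial sensors, cross-correlation alignment
## of externally annotated relative events, reference filtering, and
## swing-cycle construction.

#' Resultant acceleration of a triaxial trace
#'
#' @param trace an [ImuTrace].
#' @return numeric vector, `sqrt(ax^2 + ay^2 + az^2)` per sample, in g.
#' @examples
#' tr <- new("ImuTrace", acc = cbind(3, 4, 0), fs = 100, label = "paddle",
#'           participant = "P01", condition = "machine")
#' resultantAcceleration(tr)  # 5
#' @export
resultantAcceleration <- function(trace) {
  stopifnot(is(trace, "ImuTrace"))
  if (ncol(trace@acc) != 3 || any(!is.finite(trace@acc)))
    scStop("trace must have three finite acceleration axes")
  sqrt(rowSums(trace@acc^2))
}

#' Detect hit events from a resultant-acceleration series
#'
#' Marks an event wherever the per-sample forward difference of the
#' resultant acceleration strictly exceeds `threshold` (in g).  The event
#' onset is the first sample of each suprathreshold excursion; excursions
#' closer than `refractory` seconds to the previous event are merged into
#' it (one event per swing).
#'
#' @param resultant numeric series in g (see [resultantAcceleration()]).
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold on the first difference, g
#'   (default 0.75; the comparison is strict).
#' @param refractory merge window, seconds.
#' @param condition,source labels for the returned table.
#' @return an [eventTable()] of `participant_hit` events.
#' @export
detectHits <- function(resultant, fs, threshold = 0.75, refractory = 0.5,
                       condition = NA_character_, source = "imu") {
  if (fs <= 0) scStop("fs must be positive")
  if (length(resultant) < 2)
    return(eventTable(type = "participant_hit"))
  d <- diff(resultant)
  above <- which(d > threshold)
  if (!length(above)) return(eventTable(type = "participant_hit"))
  ## onset = the sample the signal jumps to (first sample of the excursion)
  onsets <- above / fs
  keep <- c(TRUE, diff(onsets) > refractory)
  eventTable(onset = onsets[keep], type = "participant_hit",
             condition = condition, source = source)
}

#' Align relative event annotations to detected events by cross-correlation
#'
#' Both event trains are binned into 1 ms impulse trains and the lag
#' maximising their cross-correlation within `searchWindow` is applied to
#' the relative events.  Used to place video-derived hit annotations (known
#' only relative to the first hit) on the recording time base.
#'
#' @param relativeEvents numeric vector of event times, seconds, on an
#'   arbitrary time base.
#' @param detected an event table of detected hits (see [detectHits()]).
#' @param searchWindow maximum |lag| scanned, seconds.
#' @param binWidth correlation bin width, seconds.
#' @return list with `lag` (seconds, to add to `relativeEvents`) and
#'   `aligned` (event table of shifted events).
#' @export
alignByXcorr <- function(relativeEvents, detected, searchWindow = 30,
                         binWidth = 0.001) {
  det <- detected$onset
  if (length(relativeEvents) < 3 || length(det) < 3)
    scStop("need at least 3 events in each train to align")
  lags <- seq(-searchWindow, searchWindow, by = binWidth)
  t0 <- min(c(relativeEvents + min(lags), det)) - binWidth
  t1 <- max(c(relativeEvents + max(lags), det)) + binWidth
  nb <- ceiling((t1 - t0) / binWidth) + 1
  binOf <- function(x) pmin(nb, pmax(1, floor((x - t0) / binWidth) + 1))
  detTrain <- tabulate(binOf(det), nb)
  ## cross-correlation of impulse trains == for each lag, count coincident
  ## bins; computed sparsely over the relative events
  score <- vapply(lags, function(L) {
    sum(detTrain[binOf(relativeEvents + L)])
  }, numeric(1))
  if (max(score) == 0)
    scStop("alignment failure: no event overlap within the search window")
  lag <- lags[which.max(score)]
  list(lag = lag,
       aligned = eventTable(onset = relativeEvents + lag,
                            type = "participant_hit", source = "reference"))
}

#' Filter detected events against reference markers
#'
#' Keeps only events whose onset lies within `tol` seconds (inclusive) of
#' the nearest reference event; events further away are discarded as
#' mislabeled (e.g. an accidental paddle-table contact).
#'
#' @param events event table to filter.
#' @param reference event table of trusted markers.
#' @param tol tolerance, seconds (default 0.200, inclusive).
#' @return the retained subset of `events`.
#' @export
filterByReference <- function(events, reference, tol = 0.200) {
  if (!nrow(reference)) {
    warning("empty reference table: all events removed")
    return(events[integer(0), , drop = FALSE])
  }
  keep <- vapply(events$onset, function(o)
    min(abs(o - reference$onset)) <= tol + sqrt(.Machine$double.eps),
    logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build swing cycles from appear and hit events
#'
#' A swing cycle is the event triplet (ball appears, participant hits,
#' next ball appears).  Each ball-appear event must be followed by exactly
#' one hit before the next ball-appear; cycles violating this are dropped
#' and counted.  Median hit and next-appear latencies across all retained
#' cycles form the canonical warp template.
#'
#' @param appear event table of `ball_appear` events (or any onsets).
#' @param hits event table of `participant_hit` events.
#' @return list with `cycles` (data.frame `t_appear`, `t_hit`, `t_next`),
#'   `medianLatencies` (named numeric: `appear` = 0, `hit`, `next`), and
#'   `nDropped`.
#' @export
buildSwingCycles <- function(appear, hits) {
  ap <- sort(appear$onset)
  ht <- sort(hits$onset)
  if (length(ap) < 2) scStop("need at least two ball-appear events")
  rows <- list(); dropped <- 0L
  for (i in seq_len(length(ap) - 1)) {
    inCyc <- ht[ht > ap[i] & ht < ap[i + 1]]
    if (length(inCyc) == 1)
      rows[[length(rows) + 1]] <- c(ap[i], inCyc, ap[i + 1])
    else dropped <- dropped + 1L
  }
  if (!length(rows)) scStop("no valid swing cycles found")
  cyc <- as.data.frame(do.call(rbind, rows))
  names(cyc) <- c("t_appear", "t_hit", "t_next")
  list(cycles = cyc,
       medianLatencies = c(appear = 0,
                           hit = median(cyc$t_hit - cyc$t_appear),
                           next_appear = median(cyc$t_next - cyc$t_appear)),
       nDropped = dropped)
}
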