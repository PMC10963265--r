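## Segmentation of raw traces into translocation events plus the quality
## filters applied before decoding: the >15 pA in-event noise filter and
## automated fold classification (replacing by-eye curation with a
## deterministic rule).

#' Estimate the open-pore baseline of a trace
#'
#' Robust open-pore level and noise scale from the dominant mode of the
#' sample distribution, by iterative exclusion of in-event (downward)
#' deflections: starting from the median/MAD, samples more than 4 sigma
#' below the level are excluded and the estimates recomputed until stable.
#' Deterministic.
#'
#' If the trace metadata records a nominal baseline (as the simulator and
#' the HDF5 container do), an estimate further than `max(50, 10 sigma)` pA
#' from it is rejected: such a trace has no open-pore baseline to estimate
#' (for example one long uninterrupted event).
#'
#' @param trace A [CurrentTrace] with at least `minSamples` samples.
#' @param minSamples Minimum trace length (default 1000).
#' @param maxIter Exclusion iterations (default 5).
#' @return Named numeric vector `c(level = , sigma = )` in pA.
#' @export
estimateBaseline <- function(trace, minSamples = 1000, maxIter = 5) {
  stopifnot(is(trace, "CurrentTrace"))
  x <- traceCurrent(trace)
  if (length(x) < minSamples)
    stop(sprintf("trace has %d samples; at least %d required for baseline estimation",
                 length(x), minSamples), call. = FALSE)
  keep <- rep(TRUE, length(x))
  level <- stats::median(x)
  sigma <- stats::mad(x)
  for (it in seq_len(maxIter)) {
    newKeep <- x >= level - 4 * sigma
    if (identical(newKeep, keep) && it > 1L) break
    keep <- newKeep
    if (!any(keep)) break
    level <- stats::median(x[keep])
    sigma <- stats::mad(x[keep])
  }
  nominal <- traceMetadata(trace)$baseline
  if (!is.null(nominal) && abs(level - nominal) > max(50, 10 * sigma))
    stop(sprintf(paste0("estimated level %.1f pA is far from the nominal ",
                        "baseline %.1f pA: trace appears to contain no ",
                        "open-pore baseline"), level, nominal), call. = FALSE)
  c(level = level, sigma = sigma)
}

## High-frequency in-event noise: SD of first differences / sqrt(2).
## Insensitive to the level structure (blockade steps, spikes) that is
## signal rather than noise.
.eventNoise <- function(x) {
  if (length(x) < 8L) return(stats::sd(x))
  core <- x[3:(length(x) - 2L)]
  stats::sd(diff(core)) / sqrt(2)
}

#' Find translocation events in a trace
#'
#' Segments the trace into maximal runs where the downward deflection
#' exceeds `thresholdSigma * sigma` below the estimated baseline, extends
#' each run outward to the baseline re-crossing, and keeps runs of at least
#' `minDuration`. Resulting intervals are disjoint, sorted, and carry the
#' local baseline and in-event noise; fold state starts `"unclassified"`.
#'
#' @param trace A [CurrentTrace].
#' @param thresholdSigma Detection threshold in baseline-noise sigmas
#'   (default 5).
#' @param minDuration Minimum event duration in seconds (default 2e-4).
#' @return An [EventSet] (possibly with zero events).
#' @export
findEvents <- function(trace, thresholdSigma = 5, minDuration = 2e-4) {
  stopifnot(is(trace, "CurrentTrace"))
  bl <- estimateBaseline(trace)
  level <- bl[["level"]]
  sigma <- bl[["sigma"]]
  x <- traceCurrent(trace)
  defl <- level - x
  thr <- max(thresholdSigma * sigma, 1e-9)
  recross <- max(sigma, 0.01)

  above <- defl > thr
  if (!any(above)) return(.eventSet(trace, .emptyEventTable()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  ## vectorized extension to baseline re-crossing (defl <= recross)
  isBase <- defl <= recross
  n <- length(x)
  idx <- seq_len(n)
  lastBase <- cummax(ifelse(isBase, idx, 0L))              # 0 if none before
  nextBase <- rev(n + 1L - cummax(rev(ifelse(isBase, n + 1L - idx, 0L))))
  extStart <- pmax(lastBase[starts[runs]] + 1L, 1L)
  extEnd <- pmin(nextBase[ends[runs]] - 1L, n)
  ## nextBase yields n+1 when no baseline sample follows
  extEnd[extEnd < extStart] <- extStart[extEnd < extStart]

  ## merge overlapping/adjacent extended intervals
  o <- order(extStart)
  extStart <- extStart[o]; extEnd <- extEnd[o]
  ms <- me <- integer(0)
  for (i in seq_along(extStart)) {
    if (length(ms) > 0L && extStart[i] <= me[length(me)] + 1L) {
      me[length(me)] <- max(me[length(me)], extEnd[i])
    } else {
      ms <- c(ms, extStart[i]); me <- c(me, extEnd[i])
    }
  }
  minLen <- as.integer(ceiling(minDuration * samplingRate(trace)))
  keep <- (me - ms + 1L) >= minLen
  ms <- ms[keep]; me <- me[keep]
  if (length(ms) == 0L) return(.eventSet(trace, .emptyEventTable()))

  noise <- vapply(seq_along(ms),
                  function(i) .eventNoise(x[ms[i]:me[i]]), numeric(1))
  ev <- data.frame(start = ms, end = me, baseline = level,
                   noise_pA = noise, fold_state = "unclassified",
                   stringsAsFactors = FALSE)
  .eventSet(trace, ev)
}

.emptyEventTable <- function() {
  data.frame(start = integer(0), end = integer(0), baseline = numeric(0),
             noise_pA = numeric(0), fold_state = character(0),
             stringsAsFactors = FALSE)
}

#' Discard events with high in-event noise
#'
#' Partitions an [EventSet] by the in-event noise criterion: events with
#' `noise_pA` above `maxNoisePA` (default 15 pA) are discarded and never
#' reach decoding. The partition is exhaustive and disjoint.
#'
#' @param events An [EventSet].
#' @param maxNoisePA Noise ceiling in pA (default 15).
#' @return List with elements `kept` and `discarded`, both [EventSet]s.
#' @export
filterNoisyEvents <- function(events, maxNoisePA = 15) {
  stopifnot(is(events, "EventSet"))
  tab <- eventTable(events)
  keep <- tab$noise_pA <= maxNoisePA
  list(kept = .eventSet(events@trace, tab[keep, , drop = FALSE]),
       discarded = .eventSet(events@trace, tab[!keep, , drop = FALSE]))
}

#' Classify the fold state of one event
#'
#' An event is folded iff the fraction of its samples deeper than
#' `foldedLevelFactor * dsDnaLevel` below baseline exceeds `minFraction`.
#' Narrow spikes (a few percent of samples at twice the blockade) do not
#' trigger the rule; a doubled-over carrier (tens of percent) does. Only
#' unfolded events proceed to barcode decoding.
#'
#' @param samples Event current samples, pA.
#' @param baselineLevel Open-pore level, pA.
#' @param dsDnaLevel Single-strand blockade depth, pA (> 0).
#' @param foldedLevelFactor Depth multiple defining "deep" (default 1.5).
#' @param minFraction Sample fraction above which the event is folded
#'   (default 0.2).
#' @return `"folded"` or `"unfolded"`.
#' @export
classifyFoldState <- function(samples, baselineLevel, dsDnaLevel,
                              foldedLevelFactor = 1.5, minFraction = 0.2) {
  stopifnot(dsDnaLevel > 0)
  depth <- baselineLevel - samples
  frac <- mean(depth > foldedLevelFactor * dsDnaLevel)
  if (frac > minFraction) "folded" else "unfolded"
}

#' Classify fold states for all events in a set
#'
#' Applies [classifyFoldState()] to every event. If `dsDnaLevel` is not
#' given it is calibrated from the data as the median over events of the
#' per-event median depth (robust when folded events are no more than ~70%
#' of the population and fold durations are symmetric).
#'
#' @param events An [EventSet].
#' @param dsDnaLevel dsDNA blockade depth in pA, or `NULL` to calibrate.
#' @inheritParams classifyFoldState
#' @return The [EventSet] with `fold_state` filled in.
#' @export
classifyFoldStates <- function(events, dsDnaLevel = NULL,
                               foldedLevelFactor = 1.5, minFraction = 0.2) {
  stopifnot(is(events, "EventSet"))
  tab <- eventTable(events)
  if (nrow(tab) == 0L) return(events)
  if (is.null(dsDnaLevel)) {
    med <- vapply(seq_len(nrow(tab)), function(i) {
      stats::median(tab$baseline[i] - eventSamples(events, i))
    }, numeric(1))
    dsDnaLevel <- stats::median(med)
  }
  tab$fold_state <- vapply(seq_len(nrow(tab)), function(i) {
    classifyFoldState(eventSamples(events, i), tab$baseline[i], dsDnaLevel,
                      foldedLevelFactor, minFraction)
  }, character(1))
  .eventSet(events@trace, tab)
}
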