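## Spike calling inside unfolded events, orientation-aware barcode
## assignment against a declared code library, and per-overhang dCas9
## binding calls. Positions are fractions of the event duration in [0, 1];
## the default slot layout is symmetric about 0.5, so a reverse
## translocation reads the barcode as the reversed bit string.

#' Peak-calling parameters
#'
#' Thresholds for spike calling on the extra-blockade profile (depth beyond
#' the dsDNA level): `threshold` is the minimum extra depth for a sample to
#' be considered at all, `height` the minimum extra depth of a called peak,
#' `prominence` the minimum topographic prominence, and `minDistance` the
#' minimum mutual separation as a fraction of the event duration (within a
#' violating pair the deeper spike wins; ties go to the earlier position).
#'
#' @slot threshold,height,prominence pA, non-negative.
#' @slot minDistance Fraction of event duration, non-negative.
#'
#' @param threshold,height,minDistance,prominence See slots; defaults
#'   30 pA, 60 pA, 0.05, 60 pA.
#' @return A `PeakParams` object.
#' @export peakParams
#' @exportClass PeakParams
#' @aliases PeakParams-class PeakParams
setClass("PeakParams",
         slots = c(threshold = "numeric", height = "numeric",
                   minDistance = "numeric", prominence = "numeric"))

setValidity("PeakParams", function(object) {
  for (fld in c("threshold", "height", "minDistance", "prominence"))
    if (slot(object, fld) < 0) return(sprintf("%s must be >= 0", fld))
  TRUE
})

peakParams <- function(threshold = 30, height = 60, minDistance = 0.05,
                       prominence = 60) {
  new("PeakParams", threshold = threshold, height = height,
      minDistance = minDistance, prominence = prominence)
}

setMethod("show", "PeakParams", function(object) {
  cat(sprintf("PeakParams: threshold %g pA, height %g pA, distance %g, prominence %g pA\n",
              object@threshold, object@height, object@minDistance,
              object@prominence))
})

## topographic prominence of candidate i on profile e: height above the
## highest of the two key cols toward the nearest higher terrain (or the
## profile boundary)
.prominence <- function(e, i) {
  n <- length(e)
  leftMin <- e[i]
  j <- i - 1L
  while (j >= 1L && e[j] <= e[i]) {
    if (e[j] < leftMin) leftMin <- e[j]
    j <- j - 1L
  }
  if (j < 1L) leftMin <- min(e[seq_len(i)])
  rightMin <- e[i]
  j <- i + 1L
  while (j <= n && e[j] <= e[i]) {
    if (e[j] < rightMin) rightMin <- e[j]
    j <- j + 1L
  }
  if (j > n) rightMin <- min(e[i:n])
  e[i] - max(leftMin, rightMin)
}

#' Call spikes within an unfolded event
#'
#' Local maxima of the extra blockade (depth beyond the dsDNA level)
#' satisfying the height, prominence and minimum-distance criteria of
#' [peakParams()]. Within any pair closer than `minDistance`, the deeper
#' spike wins (tie: earlier position). Calls are sorted by position.
#'
#' @param samples Event current samples, pA.
#' @param baselineLevel Open-pore level for this event, pA.
#' @param dsDnaLevel dsDNA blockade depth, pA; if `NULL`, the median event
#'   depth is used.
#' @param params A [PeakParams].
#' @return `data.frame` with columns `position` (fraction of the event in
#'   `[0, 1]`), `depth` (pA beyond the dsDNA level) and `index` (sample
#'   index within the event). Zero rows is a valid result.
#' @export
detectSpikes <- function(samples, baselineLevel, dsDnaLevel = NULL,
                         params = peakParams()) {
  stopifnot(is(params, "PeakParams"))
  depth <- baselineLevel - samples
  if (is.null(dsDnaLevel)) dsDnaLevel <- stats::median(depth)
  e <- depth - dsDnaLevel
  n <- length(e)
  if (n < 3L) return(.emptySpikes())
  inner <- 2:(n - 1L)
  cand <- inner[e[inner] >= e[inner - 1L] & e[inner] >= e[inner + 1L]]
  cand <- cand[e[cand] >= params@height & e[cand] > params@threshold]
  if (length(cand) == 0L) return(.emptySpikes())
  prom <- vapply(cand, function(i) .prominence(e, i), numeric(1))
  cand <- cand[prom >= params@prominence]
  if (length(cand) == 0L) return(.emptySpikes())

  ## greedy suppression: deeper wins, ties to the earlier position
  minSep <- params@minDistance * n
  ord <- order(-e[cand], cand)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(kept - i) >= minSep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(position = (kept - 1) / max(n - 1L, 1L),
             depth = e[kept], index = kept)
}

.emptySpikes <- function() {
  data.frame(position = numeric(0), depth = numeric(0), index = integer(0))
}

#' Assign a barcode from called spikes
#'
#' Bins spikes falling inside barcode-slot windows (slot centre +/-
#' `slotTolerance` of the inter-slot spacing) into a slot occupancy vector
#' and compares it to every library code in forward and reversed
#' orientation. A unique exact match fixes the barcode and orientation; a
#' code that matches in both orientations (a palindrome) is assigned with
#' orientation `"ambiguous"`; matches to two different codes leave the
#' barcode `"unclassified"`; so does no exact match at all.
#'
#' @param spikes Spike calls from [detectSpikes()].
#' @param slotPositions Fractional barcode-slot centres, strictly
#'   increasing (equally spaced by default design).
#' @param library Character vector of admissible bit-string codes.
#' @param slotTolerance Window half-width as a fraction of the inter-slot
#'   spacing (default 0.4; values `>= 0.5` would overlap and are rejected).
#' @return List with `barcode` (code or `"unclassified"`), `orientation`
#'   (`"forward"`, `"reverse"` or `"ambiguous"`), `occupancy` (bit string as
#'   read), and `consumed` (logical per spike: used by a barcode slot).
#' @export
assignBarcode <- function(spikes, slotPositions, library,
                          slotTolerance = 0.4) {
  if (length(library) == 0L) stop("barcode library is empty", call. = FALSE)
  if (slotTolerance >= 0.5)
    stop("slotTolerance >= 0.5 makes adjacent slot windows overlap",
         call. = FALSE)
  spacing <- if (length(slotPositions) > 1L) min(diff(slotPositions)) else 0.1
  hw <- slotTolerance * spacing

  occ <- rep(0L, length(slotPositions))
  consumed <- rep(FALSE, nrow(spikes))
  if (nrow(spikes) > 0L) {
    for (si in seq_len(nrow(spikes))) {
      d <- abs(slotPositions - spikes$position[si])
      j <- which.min(d)
      if (d[j] <= hw) {
        occ[j] <- 1L
        consumed[si] <- TRUE
      }
    }
  }
  occStr <- paste(occ, collapse = "")

  revStr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  fwd <- library[library == occStr]
  bwd <- library[vapply(library, revStr, character(1)) == occStr]
  codes <- unique(c(fwd, bwd))
  if (length(codes) == 0L) {
    list(barcode = "unclassified", orientation = "ambiguous",
         occupancy = occStr, consumed = consumed)
  } else if (length(codes) > 1L) {
    ## different codes match in the two orientations: not unique
    list(barcode = "unclassified", orientation = "ambiguous",
         occupancy = occStr, consumed = consumed)
  } else {
    orientation <- if (length(fwd) > 0L && length(bwd) > 0L) "ambiguous"
                   else if (length(fwd) > 0L) "forward" else "reverse"
    list(barcode = codes, orientation = orientation,
         occupancy = occStr, consumed = consumed)
  }
}

#' Call per-overhang dCas9 binding from non-barcode spikes
#'
#' A site is bound iff at least one spike not consumed by a barcode slot
#' falls inside the site's window (centre +/- `windowHalfwidth`); windows
#' are mirrored (`p -> 1 - p`) under reverse orientation and the union of
#' both windows is used when the orientation is ambiguous. Spikes outside
#' every window are counted as off-window artifacts.
#'
#' @param spikes Spike calls from [detectSpikes()].
#' @param overhangPositions Fractional overhang-site positions (forward
#'   frame).
#' @param orientation `"forward"`, `"reverse"` or `"ambiguous"`.
#' @param consumed Logical per spike: already used by a barcode slot.
#' @param windowHalfwidth Fractional window half-width (default 0.04).
#' @return List with `bound` (logical per site) and `offWindow` (count).
#' @export
callDcas9 <- function(spikes, overhangPositions, orientation,
                      consumed = rep(FALSE, nrow(spikes)),
                      windowHalfwidth = .WINDOW_HALFWIDTH) {
  free <- spikes[!consumed, , drop = FALSE]
  nSites <- length(overhangPositions)
  bound <- logical(nSites)
  inAny <- rep(FALSE, nrow(free))
  for (j in seq_len(nSites)) {
    centres <- switch(orientation,
                      forward = overhangPositions[j],
                      reverse = 1 - overhangPositions[j],
                      ambiguous = c(overhangPositions[j],
                                    1 - overhangPositions[j]))
    hit <- rep(FALSE, nrow(free))
    for (ctr in centres)
      hit <- hit | abs(free$position - ctr) <= windowHalfwidth
    bound[j] <- any(hit)
    inAny <- inAny | hit
  }
  list(bound = bound, offWindow = sum(!inAny))
}

## Disjointness of the joint window layout (slots + overhangs in both
## orientations); an overlapping layout is a configuration error.
.checkWindowLayout <- function(slotPositions, overhangPositions,
                               slotTolerance, windowHalfwidth) {
  spacing <- if (length(slotPositions) > 1L) min(diff(slotPositions)) else 0.1
  slotHw <- slotTolerance * spacing
  ctr <- c(slotPositions, overhangPositions, 1 - overhangPositions)
  hw <- c(rep(slotHw, length(slotPositions)),
          rep(windowHalfwidth, 2L * length(overhangPositions)))
  o <- order(ctr)
  ctr <- ctr[o]; hw <- hw[o]
  ## identical centres (a site at exactly 0.5) collapse to one window
  dup <- duplicated(signif(ctr, 10))
  ctr <- ctr[!dup]; hw <- hw[!dup]
  if (length(ctr) > 1L) {
    lo <- (ctr + hw)[-length(ctr)]
    hi <- (ctr - hw)[-1L]
    if (any(lo > hi))
      stop("overlapping decode windows: reduce slotTolerance/windowHalfwidth or respace the design",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Decode all unfolded events in an event set
#'
#' Runs spike calling, barcode assignment and per-overhang dCas9 calling on
#' every unfolded event. Events still `"unclassified"` in fold state are
#' first classified with [classifyFoldStates()]. All designs in a run must
#' share the same slot layout; after the barcode is assigned, the matching
#' design's own overhang windows are used for the binding calls. Folded
#' events and events whose occupancy matches no library code are excluded
#' from binding calls (their rows carry `NA` flags).
#'
#' @param events An [EventSet] (after the noise filter).
#' @param designs List of [NanostructureDesign]s (the declared library).
#' @param params A [PeakParams].
#' @param slotTolerance,windowHalfwidth See [assignBarcode()] and
#'   [callDcas9()].
#' @param dsDnaLevel Optional dsDNA blockade depth for fold classification.
#' @return `data.frame` with one row per unfolded event: `event_id` (row in
#'   the event table), `barcode`, `orientation`, `n_spikes`, `bound` (per
#'   site, comma string), `n_bound`, `any_bound`, `off_window_count`.
#' @export
decodeEvents <- function(events, designs, params = peakParams(),
                         slotTolerance = 0.4,
                         windowHalfwidth = .WINDOW_HALFWIDTH,
                         dsDnaLevel = NULL) {
  stopifnot(is(events, "EventSet"))
  if (is(designs, "NanostructureDesign")) designs <- list(designs)
  codes <- vapply(designs, barcode, character(1))
  if (anyDuplicated(codes))
    stop("designs must carry distinct barcodes", call. = FALSE)
  names(designs) <- codes
  slots0 <- slotPositions(designs[[1L]])
  for (d in designs) {
    if (!isTRUE(all.equal(slotPositions(d), slots0)))
      stop("all designs in a run must share the same slot layout",
           call. = FALSE)
    .checkWindowLayout(slots0,
                       vapply(overhangSites(d), function(s) s$position,
                              numeric(1)),
                       slotTolerance, windowHalfwidth)
  }

  tab <- eventTable(events)
  if (nrow(tab) > 0L && any(tab$fold_state == "unclassified")) {
    events <- classifyFoldStates(events, dsDnaLevel)
    tab <- eventTable(events)
  }
  idx <- which(tab$fold_state == "unfolded")
  rows <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    i <- idx[r]
    x <- eventSamples(events, i)
    spikes <- detectSpikes(x, tab$baseline[i], params = params)
    asg <- assignBarcode(spikes, slots0, codes, slotTolerance)
    if (asg$barcode == "unclassified") {
      rows[[r]] <- data.frame(event_id = i, barcode = "unclassified",
                              orientation = asg$orientation,
                              n_spikes = nrow(spikes), bound = NA_character_,
                              n_bound = NA_integer_, any_bound = NA,
                              off_window_count = sum(!asg$consumed),
                              stringsAsFactors = FALSE)
    } else {
      des <- designs[[asg$barcode]]
      pos <- vapply(overhangSites(des), function(s) s$position, numeric(1))
      call <- callDcas9(spikes, pos, asg$orientation, asg$consumed,
                        windowHalfwidth)
      rows[[r]] <- data.frame(event_id = i, barcode = asg$barcode,
                              orientation = asg$orientation,
                              n_spikes = nrow(spikes),
                              bound = paste(as.integer(call$bound),
                                            collapse = ","),
                              n_bound = sum(call$bound),
                              any_bound = any(call$bound),
                              off_window_count = call$offWindow,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event_id = integer(0), barcode = character(0),
                      orientation = character(0), n_spikes = integer(0),
                      bound = character(0), n_bound = integer(0),
                      any_bound = logical(0), off_window_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
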