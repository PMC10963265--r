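#' @include AllGenerics.R
NULL

## S4 classes for the carrier/guide domain model and the signal containers.
## Sequence conventions used throughout:
##   * spacer / protospacer strings are written PAM-proximal first, i.e. the
##     character at string position 1 is target position 1 (1 nt from the PAM),
##     and position 20 is PAM-distal.
##   * spacers are RNA over {A,C,G,U}; protospacers/PAMs are DNA over {A,C,G,T}.
##   * all sequence and sample indexing is 1-based; event intervals are
##     1-based inclusive [start, end].

.DNA_BASES <- c("A", "C", "G", "T")
.RNA_BASES <- c("A", "C", "G", "U")

.checkAlphabet <- function(seq, alphabet, what) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) %s in %s (allowed: %s)",
                 paste(sQuote(bad), collapse = ", "), what,
                 paste(alphabet, collapse = "")), call. = FALSE)
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------- GuideProbe

#' Guide probe (crRNA spacer)
#'
#' A dCas9 guide probe described by its 20-nt crRNA spacer. The spacer is an
#' RNA sequence over `{A,C,G,U}` written PAM-proximal first: string position 1
#' is the base that pairs opposite target position 1 (one nucleotide from the
#' PAM).
#'
#' @slot name Probe label.
#' @slot spacer 20-character RNA spacer, PAM-proximal first.
#'
#' @param name Probe label.
#' @param spacer 20-nt RNA spacer (case-insensitive; `T` is rejected).
#' @return A `GuideProbe` object.
#' @examples
#' guideProbe("probe1", "ACGUACGUACGUACGUACGU")
#' @export guideProbe
#' @exportClass GuideProbe
#' @aliases GuideProbe-class GuideProbe
setClass("GuideProbe", slots = c(name = "character", spacer = "character"))

setValidity("GuideProbe", function(object) {
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (length(object@spacer) != 1L) return("'spacer' must be a single string")
  if (nchar(object@spacer) != 20L)
    return(sprintf("spacer must be exactly 20 nt, got %d", nchar(object@spacer)))
  chars <- strsplit(object@spacer, "")[[1]]
  bad <- setdiff(unique(chars), .RNA_BASES)
  if (length(bad) > 0L)
    return(sprintf("invalid character(s) %s in spacer (RNA alphabet ACGU)",
                   paste(sQuote(bad), collapse = ", ")))
  TRUE
})

guideProbe <- function(name, spacer) {
  new("GuideProbe", name = as.character(name), spacer = toupper(spacer))
}

#' @rdname accessors
#' @export
setMethod("spacer", "GuideProbe", function(x) x@spacer)

setMethod("show", "GuideProbe", function(object) {
  cat("GuideProbe", sQuote(object@name), "\n  spacer (PAM-proximal first):",
      object@spacer, "\n")
})

## ---------------------------------------------------------------- TargetSite

#' Target site (protospacer + PAM)
#'
#' A 20-bp DNA protospacer with its adjacent 3-nt PAM. Sequences are written
#' PAM-proximal first (string position 1 = target position 1). The PAM is
#' valid iff it matches `NGG`; dCas9 engagement requires a valid PAM.
#'
#' @slot protospacer 20-character DNA sequence, PAM-proximal first.
#' @slot pam 3-character DNA sequence.
#'
#' @param protospacer 20-bp DNA protospacer.
#' @param pam 3-nt PAM sequence (default `"TGG"`, a valid NGG PAM).
#' @return A `TargetSite` object. [hasValidPam()] reports whether the PAM
#'   matches `NGG`.
#' @examples
#' ts <- targetSite(strrep("ACGT", 5), "TGG")
#' hasValidPam(ts)
#' @export targetSite
#' @exportClass TargetSite
#' @aliases TargetSite-class TargetSite
setClass("TargetSite", slots = c(protospacer = "character", pam = "character"))

setValidity("TargetSite", function(object) {
  if (nchar(object@protospacer) != 20L)
    return(sprintf("protospacer must be exactly 20 nt, got %d",
                   nchar(object@protospacer)))
  if (nchar(object@pam) != 3L)
    return(sprintf("pam must be exactly 3 nt, got %d", nchar(object@pam)))
  for (fld in c("protospacer", "pam")) {
    chars <- strsplit(slot(object, fld), "")[[1]]
    bad <- setdiff(unique(chars), .DNA_BASES)
    if (length(bad) > 0L)
      return(sprintf("invalid character(s) %s in %s (DNA alphabet ACGT)",
                     paste(sQuote(bad), collapse = ", "), fld))
  }
  TRUE
})

targetSite <- function(protospacer, pam = "TGG") {
  new("TargetSite", protospacer = toupper(protospacer), pam = toupper(pam))
}

#' @rdname accessors
#' @export
setMethod("protospacer", "TargetSite", function(x) x@protospacer)

#' @rdname accessors
#' @export
setMethod("pam", "TargetSite", function(x) x@pam)

#' @rdname accessors
#' @export
setMethod("hasValidPam", "TargetSite", function(x) {
  grepl("^[ACGT]GG$", x@pam)
})

setMethod("show", "TargetSite", function(object) {
  cat("TargetSite\n  protospacer (PAM-proximal first):", object@protospacer,
      "\n  PAM:", object@pam,
      if (hasValidPam(object)) "(valid NGG)" else "(no valid NGG)", "\n")
})

## ----------------------------------------------------------- MismatchProfile

#' Mismatch profile of a guide against a target site
#'
#' Positions at which an RNA spacer fails to pair its DNA protospacer, with
#' the base identities and a wobble flag for each mismatch. Positions are
#' counted from the PAM (1 = PAM-proximal). The seed boundary records which
#' positions are considered seed (`<= seedBoundary`).
#'
#' @slot entries `data.frame` with columns `position` (integer, 1-20,
#'   strictly increasing), `rna`, `dna` (single bases) and `wobble` (logical).
#' @slot seedBoundary Last seed position (default 12).
#'
#' @seealso [mismatchProfile()], [isWobblePair()]
#' @exportClass MismatchProfile
#' @aliases MismatchProfile-class MismatchProfile
setClass("MismatchProfile",
         slots = c(entries = "data.frame", seedBoundary = "numeric"))

setValidity("MismatchProfile", function(object) {
  e <- object@entries
  need <- c("position", "rna", "dna", "wobble")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) > 0L) {
    if (any(e$position < 1L | e$position > 20L))
      return("positions must lie in [1, 20]")
    if (any(diff(e$position) <= 0L))
      return("positions must be strictly increasing")
    expect <- isWobblePair(e$rna, e$dna)
    if (!identical(unname(expect), unname(as.logical(e$wobble))))
      return("wobble flags inconsistent with isWobblePair()")
  }
  if (length(object@seedBoundary) != 1L ||
      object@seedBoundary < 1 || object@seedBoundary > 20)
    return("seedBoundary must be a single value in [1, 20]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("mismatchEntries", "MismatchProfile", function(x) x@entries)

setMethod("show", "MismatchProfile", function(object) {
  n <- nrow(object@entries)
  cat("MismatchProfile:", n, if (n == 1L) "mismatch" else "mismatches",
      sprintf("(seed boundary %d)\n", as.integer(object@seedBoundary)))
  if (n > 0L) print(object@entries, row.names = FALSE)
})

## -------------------------------------------------------- BindingModelParams

#' Binding model parameters
#'
#' Parameters of the position-dependent multiplicative binding model used to
#' turn a [MismatchProfile] into a binding probability. A perfectly matched
#' target with a valid PAM binds with `baselineEfficiency`; every mismatch at
#' position `p` multiplies the probability by the table entry for
#' `(p, wobble)`; a target without a valid NGG PAM binds with
#' `noPamProbability`. The result is clamped to `[0, 1]`.
#'
#' The shipped default ratio table (seed mismatch 0.1, seed wobble 0.6,
#' distal 0.9) is an illustrative placeholder, not a measured truth: the
#' underlying study reports position-wise binding only graphically, so table
#' values are user configuration.
#'
#' @slot baselineEfficiency Probability of binding to a perfect-match target
#'   (default 0.337, the matched-target control efficiency).
#' @slot ratioTable `data.frame` with columns `position` (1-20), `wobble`
#'   (logical) and `ratio` (multiplier, `>= 0`).
#' @slot noPamProbability Probability of binding without a valid PAM
#'   (default 0).
#'
#' @param baselineEfficiency,noPamProbability Probabilities in `[0, 1]`.
#' @param ratioTable Mismatch multiplier table; see [defaultMismatchRatios()].
#' @return A `BindingModelParams` object.
#' @examples
#' bindingModelParams()
#' @export bindingModelParams
#' @exportClass BindingModelParams
#' @aliases BindingModelParams-class BindingModelParams
setClass("BindingModelParams",
         slots = c(baselineEfficiency = "numeric", ratioTable = "data.frame",
                   noPamProbability = "numeric"))

setValidity("BindingModelParams", function(object) {
  if (object@baselineEfficiency < 0 || object@baselineEfficiency > 1)
    return("baselineEfficiency must lie in [0, 1]")
  if (object@noPamProbability < 0 || object@noPamProbability > 1)
    return("noPamProbability must lie in [0, 1]")
  rt <- object@ratioTable
  need <- c("position", "wobble", "ratio")
  if (!all(need %in% names(rt)))
    return(sprintf("ratioTable must have columns %s", paste(need, collapse = ", ")))
  if (nrow(rt) > 0L && any(rt$ratio < 0))
    return("ratios must be non-negative")
  if (anyDuplicated(rt[c("position", "wobble")]))
    return("duplicated (position, wobble) entries in ratioTable")
  TRUE
})

bindingModelParams <- function(baselineEfficiency = 0.337,
                               ratioTable = defaultMismatchRatios(),
                               noPamProbability = 0) {
  new("BindingModelParams",
      baselineEfficiency = baselineEfficiency,
      ratioTable = as.data.frame(ratioTable),
      noPamProbability = noPamProbability)
}

setMethod("show", "BindingModelParams", function(object) {
  cat(sprintf("BindingModelParams: baseline %.3f, no-PAM %.3f, %d table entries\n",
              object@baselineEfficiency, object@noPamProbability,
              nrow(object@ratioTable)))
})

## ------------------------------------------------------------------ SimConfig

#' Simulator configuration
#'
#' Phenomenological parameters of the synthetic nanopore recording. Defaults
#' emulate a quartz-nanopipette measurement of DNA carriers: a positive
#' open-pore baseline with Gaussian noise, negative square-pulse dsDNA
#' blockades, short extra-blockade spikes for barcode dumbbell groups and
#' bound dCas9, ~70% folded events, bidirectional translocation, and rare
#' knot artifacts on unbound overhangs.
#'
#' @slot samplingRate Samples per second (default 250000).
#' @slot baselineCurrent Open-pore current, pA (default 10000).
#' @slot noiseSd Gaussian noise SD, pA (default 6).
#' @slot dsDnaBlockade dsDNA blockade depth below baseline, pA (default 120).
#' @slot spikeExtraBlockade Extra spike depth on top of the dsDNA level, pA
#'   (default 120).
#' @slot dwellMean Mean translocation dwell time, s (default 2e-3).
#' @slot dwellSdLog Log-scale SD of the log-normal dwell distribution
#'   (default 0.25).
#' @slot eventRate Event rate, events/s; inter-event gaps are exponential
#'   with this rate (default 100).
#' @slot foldedFraction Probability that an event is folded (default 0.7).
#' @slot knotRate Probability of one spurious in-window knot spike per
#'   unbound overhang site (default 0.045).
#' @slot lowpassCutoff Low-pass corner frequency, Hz, emulated by zero-phase
#'   first-order smoothing of pulse edges (default 50000).
#' @slot spikeWidth Spike width in samples at the nominal dwell; internally a
#'   fraction of event duration so geometry is dwell-invariant (default 10).
#' @slot seed RNG seed used by [simulateTrace()].
#'
#' @param ... Named values overriding the defaults above.
#' @return A `SimConfig` object.
#' @examples
#' simConfig(noiseSd = 4, foldedFraction = 0)
#' @export simConfig
#' @exportClass SimConfig
#' @aliases SimConfig-class SimConfig
setClass("SimConfig",
         slots = c(samplingRate = "numeric", baselineCurrent = "numeric",
                   noiseSd = "numeric", dsDnaBlockade = "numeric",
                   spikeExtraBlockade = "numeric", dwellMean = "numeric",
                   dwellSdLog = "numeric", eventRate = "numeric",
                   foldedFraction = "numeric", knotRate = "numeric",
                   lowpassCutoff = "numeric", spikeWidth = "numeric",
                   seed = "numeric"))

setValidity("SimConfig", function(object) {
  for (fld in c("foldedFraction", "knotRate")) {
    v <- slot(object, fld)
    if (v < 0 || v > 1) return(sprintf("%s must lie in [0, 1]", fld))
  }
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@dwellMean <= 0) return("dwellMean must be > 0")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (object@eventRate <= 0) return("eventRate must be > 0")
  if (object@baselineCurrent <= 0) return("baselineCurrent must be > 0")
  if (object@spikeWidth <= 0) return("spikeWidth must be > 0")
  TRUE
})

simConfig <- function(...) {
  defaults <- list(samplingRate = 250000, baselineCurrent = 10000,
                   noiseSd = 6, dsDnaBlockade = 120, spikeExtraBlockade = 120,
                   dwellMean = 2e-3, dwellSdLog = 0.25, eventRate = 100,
                   foldedFraction = 0.7, knotRate = 0.045,
                   lowpassCutoff = 50000, spikeWidth = 10, seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- utils::modifyList(defaults, override)
  do.call(new, c(list("SimConfig"), vals))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %g kHz sampling, baseline %g pA (noise %g pA)\n",
                     "  blockade %g pA + spikes %g pA, dwell ~%g ms, ",
                     "folded %g%%, knot rate %g\n"),
              object@samplingRate / 1000, object@baselineCurrent,
              object@noiseSd, object@dsDnaBlockade, object@spikeExtraBlockade,
              object@dwellMean * 1000, object@foldedFraction * 100,
              object@knotRate))
})

## ---------------------------------------------------- NanostructureDesign

#' Barcoded DNA nanostructure design
#'
#' Layout of one linear DNA carrier: a 5-bit (by default) dumbbell barcode at
#' fixed fractional positions along the carrier, plus dsDNA overhang sites
#' presenting dCas9 target sequences. Fractional positions are in `(0, 1)`
#' measured along the carrier; default slots sit at 0.3-0.7, symmetric about
#' the carrier midpoint so that a reverse translocation reads the barcode as
#' the reversed bit string.
#'
#' @slot name Design label.
#' @slot barcode Bit string over `{0,1}`, e.g. `"11001"`.
#' @slot slotPositions Fractional positions of the barcode slots, strictly
#'   increasing in `(0, 1)`, one per bit.
#' @slot overhangSites List of overhang sites; each element is a list with
#'   `position` (fraction in `(0, 1)`) and `site` (a [TargetSite]).
#' @slot concentrationWeight Non-negative relative abundance in a mixture.
#'
#' @param name,barcode,concentrationWeight See slots.
#' @param slotPositions Default: equally spaced `seq(0.3, 0.7, length.out =
#'   nchar(barcode))`.
#' @param overhangSites Either a list as above or a single [TargetSite]
#'   placed at fraction 0.1.
#' @return A `NanostructureDesign` object.
#' @examples
#' nanostructureDesign("wt", "11111", overhangSites = targetSite(strrep("A", 20)))
#' @export nanostructureDesign
#' @exportClass NanostructureDesign
#' @aliases NanostructureDesign-class NanostructureDesign
setClass("NanostructureDesign",
         slots = c(name = "character", barcode = "character",
                   slotPositions = "numeric", overhangSites = "list",
                   concentrationWeight = "numeric"))

setValidity("NanostructureDesign", function(object) {
  if (!grepl("^[01]+$", object@barcode))
    return("barcode must be a non-empty string over {0,1}")
  if (nchar(object@barcode) != length(object@slotPositions))
    return("barcode length must equal the number of slot positions")
  sp <- object@slotPositions
  if (any(sp <= 0 | sp >= 1)) return("slot positions must lie in (0, 1)")
  if (length(sp) > 1L && any(diff(sp) <= 0))
    return("slot positions must be strictly increasing")
  if (length(object@overhangSites) > 0L) {
    pos <- vapply(object@overhangSites, function(s) s$position, numeric(1))
    if (any(pos <= 0 | pos >= 1))
      return("overhang positions must lie in (0, 1)")
    if (length(pos) > 1L && any(diff(pos) <= 0))
      return("overhang positions must be strictly increasing")
    ok <- vapply(object@overhangSites, function(s) is(s$site, "TargetSite"),
                 logical(1))
    if (!all(ok)) return("each overhang site must carry a TargetSite")
  }
  if (object@concentrationWeight < 0)
    return("concentrationWeight must be non-negative")
  TRUE
})

nanostructureDesign <- function(name, barcode,
                                slotPositions = NULL,
                                overhangSites = list(),
                                concentrationWeight = 1) {
  if (is.null(slotPositions))
    slotPositions <- seq(0.3, 0.7, length.out = nchar(barcode))
  if (is(overhangSites, "TargetSite"))
    overhangSites <- list(list(position = 0.1, site = overhangSites))
  new("NanostructureDesign", name = as.character(name), barcode = barcode,
      slotPositions = slotPositions, overhangSites = overhangSites,
      concentrationWeight = concentrationWeight)
}

#' @rdname accessors
#' @export
setMethod("barcode", "NanostructureDesign", function(x) x@barcode)

#' @rdname accessors
#' @export
setMethod("slotPositions", "NanostructureDesign", function(x) x@slotPositions)

#' @rdname accessors
#' @export
setMethod("overhangSites", "NanostructureDesign", function(x) x@overhangSites)

#' @rdname accessors
#' @export
setMethod("concentrationWeight", "NanostructureDesign",
          function(x) x@concentrationWeight)

setMethod("show", "NanostructureDesign", function(object) {
  cat("NanostructureDesign", sQuote(object@name), "\n  barcode:",
      object@barcode, "at", paste(object@slotPositions, collapse = ", "),
      "\n  overhang sites:", length(object@overhangSites),
      "| weight:", object@concentrationWeight, "\n")
})

## --------------------------------------------------------------- CurrentTrace

#' Ionic current trace
#'
#' A sampled ionic-current recording in pA with its sampling rate and source
#' metadata (nominal open-pore baseline, seed, provenance).
#'
#' @slot current Numeric vector of current samples, pA.
#' @slot samplingRate Samples per second.
#' @slot metadata Named list; the simulator records `baseline`, `seed`.
#'
#' @param current,samplingRate,metadata See slots.
#' @return A `CurrentTrace` object.
#' @export currentTrace
#' @exportClass CurrentTrace
#' @aliases CurrentTrace-class CurrentTrace
setClass("CurrentTrace",
         slots = c(current = "numeric", samplingRate = "numeric",
                   metadata = "list"))

setValidity("CurrentTrace", function(object) {
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (anyNA(object@current) || any(!is.finite(object@current)))
    return("current samples must be finite")
  TRUE
})

currentTrace <- function(current, samplingRate, metadata = list()) {
  new("CurrentTrace", current = as.numeric(current),
      samplingRate = samplingRate, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("samplingRate", "CurrentTrace", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("traceCurrent", "CurrentTrace", function(x) x@current)

#' @rdname accessors
#' @export
setMethod("traceMetadata", "CurrentTrace", function(x) x@metadata)

setMethod("length", "CurrentTrace", function(x) length(x@current))

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples at %g kHz (%.3f s)\n",
              length(object@current), object@samplingRate / 1000,
              length(object@current) / object@samplingRate))
  if (!is.null(object@metadata$baseline))
    cat(sprintf("  nominal baseline: %g pA\n", object@metadata$baseline))
})

## ------------------------------------------------------------------ EventSet

#' Set of translocation events
#'
#' Translocation events segmented from one [CurrentTrace]. The per-event
#' table records the 1-based inclusive interval `[start, end]`, the local
#' baseline, the in-event noise (`noise_pA`, the high-frequency residual SD)
#' and the fold state (`"unfolded"`, `"folded"` or `"unclassified"`).
#'
#' @slot trace The parent [CurrentTrace].
#' @slot events `data.frame` with columns `start`, `end`, `baseline`,
#'   `noise_pA`, `fold_state`.
#'
#' @seealso [findEvents()], [filterNoisyEvents()], [classifyFoldStates()]
#' @exportClass EventSet
#' @aliases EventSet-class EventSet
setClass("EventSet", slots = c(trace = "CurrentTrace", events = "data.frame"))

setValidity("EventSet", function(object) {
  ev <- object@events
  need <- c("start", "end", "baseline", "noise_pA", "fold_state")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ev) > 0L) {
    if (any(ev$end <= ev$start)) return("event intervals require end > start")
    if (any(ev$noise_pA < 0)) return("noise_pA must be >= 0")
    if (any(ev$start < 1) || any(ev$end > length(object@trace)))
      return("event intervals must lie within the trace")
    if (nrow(ev) > 1L && any(ev$start[-1L] <= ev$end[-nrow(ev)]))
      return("event intervals must be disjoint and sorted")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("nEvents", "EventSet", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setMethod("eventTable", "EventSet", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("eventSamples", "EventSet", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nrow(x@events))
  x@trace@current[x@events$start[i]:x@events$end[i]]
})

setMethod("show", "EventSet", function(object) {
  fs <- table(factor(object@events$fold_state,
                     levels = c("unfolded", "folded", "unclassified")))
  cat(sprintf("EventSet: %d events (%d unfolded, %d folded, %d unclassified)\n",
              nrow(object@events), fs[["unfolded"]], fs[["folded"]],
              fs[["unclassified"]]))
})

.eventSet <- function(trace, events) {
  new("EventSet", trace = trace, events = events)
}
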