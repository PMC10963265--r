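## File interfaces: the HDF5 trace and event containers, FASTA import of
## overhang sequences, YAML guide/target definitions, and the declared (but
## unimplemented) TDMS import hook.

#' Write / read the HDF5 trace container
#'
#' The trace container is an HDF5 file with a float dataset `current` (pA)
#' carrying attributes `sampling_rate`, and, when known, `baseline` and
#' `seed`.
#'
#' @param trace A [CurrentTrace].
#' @param path Output path (overwritten).
#' @return `writeTrace` returns `path` invisibly; `readTrace` returns a
#'   [CurrentTrace].
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(traceCurrent(trace), path, "current")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  did <- rhdf5::H5Dopen(fid, "current")
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(samplingRate(trace), did, "sampling_rate")
  md <- traceMetadata(trace)
  if (!is.null(md$baseline))
    rhdf5::h5writeAttribute(md$baseline, did, "baseline")
  if (!is.null(md$seed))
    rhdf5::h5writeAttribute(md$seed, did, "seed")
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  current <- as.numeric(rhdf5::h5read(path, "current"))
  at <- rhdf5::h5readAttributes(path, "current")
  md <- list()
  if (!is.null(at$baseline)) md$baseline <- as.numeric(at$baseline)
  if (!is.null(at$seed)) md$seed <- as.numeric(at$seed)
  md$source <- path
  currentTrace(current, as.numeric(at$sampling_rate), md)
}

#' Write / read the HDF5 event container
#'
#' One group per event under `/events`, each with a `samples` dataset
#' (baseline-subtracted view is not applied; samples are raw pA) and
#' attributes `start`, `end`, `baseline`, `noise_pA`, `fold_state`.
#'
#' @param events An [EventSet].
#' @param path Output path (overwritten).
#' @return `writeEvents` returns `path` invisibly; `readEvents` returns a
#'   list with `table` (the event table) and `samples` (list of numeric
#'   vectors).
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventSet"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "events")
  tab <- eventTable(events)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  for (i in seq_len(nrow(tab))) {
    grp <- sprintf("events/event_%05d", i)
    rhdf5::h5createGroup(fid, grp)
    rhdf5::h5write(eventSamples(events, i), fid, paste0(grp, "/samples"))
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(tab$start[i], gid, "start")
    rhdf5::h5writeAttribute(tab$end[i], gid, "end")
    rhdf5::h5writeAttribute(tab$baseline[i], gid, "baseline")
    rhdf5::h5writeAttribute(tab$noise_pA[i], gid, "noise_pA")
    rhdf5::h5writeAttribute(tab$fold_state[i], gid, "fold_state")
    rhdf5::H5Gclose(gid)
  }
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  groups <- rhdf5::h5ls(path, recursive = TRUE)
  evGroups <- sort(groups$name[groups$group == "/events" &
                                 groups$otype == "H5I_GROUP"])
  samples <- vector("list", length(evGroups))
  rows <- vector("list", length(evGroups))
  for (i in seq_along(evGroups)) {
    grp <- paste0("events/", evGroups[i])
    samples[[i]] <- as.numeric(rhdf5::h5read(path, paste0(grp, "/samples")))
    at <- rhdf5::h5readAttributes(path, grp)
    rows[[i]] <- data.frame(start = as.integer(at$start),
                            end = as.integer(at$end),
                            baseline = as.numeric(at$baseline),
                            noise_pA = as.numeric(at$noise_pA),
                            fold_state = as.character(at$fold_state),
                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else .emptyEventTable()
  list(table = tab, samples = samples)
}

#' Import overhang sequences from FASTA
#'
#' Reads a standard FASTA file of overhang DNA sequences and returns them
#' as an uppercase named character vector.
#'
#' @param path FASTA file path.
#' @return Named character vector of DNA sequences.
#' @export
readOverhangFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Read guide/target definitions from YAML
#'
#' Structured configuration with two optional blocks: `probes` (each with
#' `name`, `spacer`) and `targets` (each with `name`, `protospacer`,
#' `pam`).
#'
#' @param path YAML file path.
#' @return List with `probes` (named list of [GuideProbe]) and `targets`
#'   (named list of [TargetSite]).
#' @export
readGuideConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("probes", "targets"))
  if (length(unknown) > 0L)
    stop("unknown guide-config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  probes <- lapply(cfg$probes, function(p) guideProbe(p$name, p$spacer))
  names(probes) <- vapply(cfg$probes, `[[`, character(1), "name")
  targets <- lapply(cfg$targets, function(t)
    targetSite(t$protospacer, if (is.null(t$pam)) "TGG" else t$pam))
  names(targets) <- vapply(cfg$targets, `[[`, character(1), "name")
  list(probes = probes, targets = targets)
}

#' Load a mismatch multiplier table from YAML
#'
#' Reads the region-level multipliers (`seed_boundary`, `seed_mismatch`,
#' `seed_wobble`, `distal_mismatch`, `distal_wobble`) and expands them to
#' the full `(position, wobble)` table. The packaged default lives at
#' `system.file("extdata", "mismatch_ratios.yaml", package = "poreCas9")`.
#'
#' @param path YAML file path.
#' @return `data.frame` as from [defaultMismatchRatios()].
#' @export
loadMismatchRatios <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed_boundary", "seed_mismatch", "seed_wobble",
             "distal_mismatch", "distal_wobble")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown mismatch-ratio key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaultMismatchRatios(
    seedBoundary = cfg$seed_boundary %||% 12,
    seedMismatch = cfg$seed_mismatch %||% 0.1,
    seedWobble = cfg$seed_wobble %||% 0.6,
    distalMismatch = cfg$distal_mismatch %||% 0.9,
    distalWobble = cfg$distal_wobble %||% 0.9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TDMS import hook (declared, not implemented)
#'
#' Native instrument recordings are TDMS files; this package analyses the
#' HDF5 trace container instead. The hook exists so callers converting
#' instrument data get a clear pointer rather than a missing-function
#' error.
#'
#' @param path TDMS file path.
#' @return Never returns; always raises a condition of class
#'   `"poreCas9_tdms_unimplemented"`.
#' @export
readTdmsTrace <- function(path) {
  cond <- simpleError(paste0(
    "TDMS import is declared but not implemented; convert the recording ",
    "to the HDF5 trace container (dataset 'current' in pA with a ",
    "'sampling_rate' attribute) and use readTrace()"))
  class(cond) <- c("poreCas9_tdms_unimplemented", class(cond))
  stop(cond)
}
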