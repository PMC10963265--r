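## Sequence-level model of dCas9 guide-target interaction: PAM finding,
## mismatch profiling, wobble classification and the multiplicative
## position-dependent binding-probability model used to parameterize
## simulations.

#' Find NGG PAM sites on one strand
#'
#' Scans a DNA sequence 5'->3' on the given strand for the `NGG` protospacer
#' adjacent motif required for dCas9 engagement. Overlapping matches are all
#' reported. Reverse-complement scanning is deliberately left to the caller:
#' overhang constructs are short, defined and oriented.
#'
#' @param dnaSequence DNA string over `{A,C,G,T}` (case-insensitive),
#'   length >= 3.
#' @return Sorted integer vector of 1-based offsets `i` such that the bases
#'   at `i + 1` and `i + 2` are both `G` (the `N` position of each NGG).
#' @examples
#' findPamSites("TTAGGTT")  # 3 (PAM "AGG")
#' findPamSites("AGGGG")    # 1 2 3, overlapping NGGs
#' @export
findPamSites <- function(dnaSequence) {
  stopifnot(is.character(dnaSequence), length(dnaSequence) == 1L)
  s <- toupper(dnaSequence)
  .checkAlphabet(s, .DNA_BASES, "dnaSequence")
  n <- nchar(s)
  if (n < 3L) stop("dnaSequence must be at least 3 nt", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  which(chars[2:(n - 1L)] == "G" & chars[3:n] == "G")
}

#' Classify an RNA-DNA wobble pair
#'
#' The tolerated non-Watson-Crick RNA-DNA mispairs are rG-dT, rU-dG, rA-dC
#' and rC-dA ("wobble" pairs), where the RNA base is the guide base opposite
#' the DNA base it would pair with. Watson-Crick matches and all other
#' mispairs are not wobble. Vectorized over pairs.
#'
#' @param rnaBase Guide base(s) over `{A,C,G,U}`.
#' @param dnaBase Target base(s) over `{A,C,G,T}`.
#' @return Logical vector.
#' @examples
#' isWobblePair("G", "T")  # TRUE
#' isWobblePair("A", "A")  # FALSE
#' @export
isWobblePair <- function(rnaBase, dnaBase) {
  rnaBase <- toupper(rnaBase)
  dnaBase <- toupper(dnaBase)
  if (!all(rnaBase %in% .RNA_BASES))
    stop("rnaBase must be over {A,C,G,U}", call. = FALSE)
  if (!all(dnaBase %in% .DNA_BASES))
    stop("dnaBase must be over {A,C,G,T}", call. = FALSE)
  paste(rnaBase, dnaBase) %in% c("G T", "U G", "A C", "C A")
}

#' Mismatch profile of a guide against a target site
#'
#' Compares a 20-nt spacer with a 20-bp protospacer position by position
#' (1 = PAM-proximal). Position `p` matches iff the RNA base is the
#' transcript equivalent of the DNA base (A-A, C-C, G-G, U-T); every other
#' position is recorded as a mismatch with its base pair and wobble flag.
#'
#' @param probe A [GuideProbe].
#' @param site A [TargetSite].
#' @param seedBoundary Last position counted as seed (default 12).
#' @return A [MismatchProfile]; empty entries for a perfect match.
#' @examples
#' site <- targetSite(strrep("ACGT", 5))
#' mismatchProfile(matchedProbe(site), site)  # perfect match
#' @export
mismatchProfile <- function(probe, site, seedBoundary = 12) {
  stopifnot(is(probe, "GuideProbe"), is(site, "TargetSite"))
  rna <- strsplit(spacer(probe), "")[[1]]
  dna <- strsplit(protospacer(site), "")[[1]]
  rnaAsDna <- chartr("U", "T", rna)
  mm <- which(rnaAsDna != dna)
  entries <- data.frame(position = as.integer(mm),
                        rna = rna[mm], dna = dna[mm],
                        wobble = if (length(mm)) isWobblePair(rna[mm], dna[mm])
                                 else logical(0),
                        stringsAsFactors = FALSE)
  new("MismatchProfile", entries = entries, seedBoundary = seedBoundary)
}

#' Perfect-match guide probe for a target site
#'
#' Convenience constructor: the spacer whose mismatch profile against `site`
#' is empty (the RNA transcript of the protospacer, position by position).
#'
#' @param site A [TargetSite].
#' @param name Probe label.
#' @return A [GuideProbe].
#' @export
matchedProbe <- function(site, name = "matched") {
  guideProbe(name, chartr("T", "U", protospacer(site)))
}

#' Default mismatch multiplier table
#'
#' A full `(position, wobble)` table of binding-probability multipliers.
#' Seed-region mismatches (positions `<= seedBoundary`) are strongly
#' penalized, wobble pairs less so, PAM-distal mismatches mildly. These
#' defaults are illustrative placeholders exposed as configuration
#' (`inst/extdata/mismatch_ratios.yaml` ships the same values), not
#' measured truths.
#'
#' @param seedBoundary Last seed position (default 12).
#' @param seedMismatch,seedWobble Multipliers for seed positions
#'   (defaults 0.1 and 0.6).
#' @param distalMismatch,distalWobble Multipliers for distal positions
#'   (defaults 0.9 and 0.9).
#' @return `data.frame` with columns `position`, `wobble`, `ratio` covering
#'   all 40 combinations.
#' @export
defaultMismatchRatios <- function(seedBoundary = 12,
                                  seedMismatch = 0.1, seedWobble = 0.6,
                                  distalMismatch = 0.9, distalWobble = 0.9) {
  tab <- expand.grid(position = 1:20, wobble = c(FALSE, TRUE),
                     KEEP.OUT.ATTRS = FALSE)
  seed <- tab$position <= seedBoundary
  tab$ratio <- ifelse(seed,
                      ifelse(tab$wobble, seedWobble, seedMismatch),
                      ifelse(tab$wobble, distalWobble, distalMismatch))
  tab
}

#' Binding probability of a guide at a target site
#'
#' Multiplicative position-dependent model: a target without a valid NGG PAM
#' binds with `noPamProbability`; a perfect match binds with the baseline
#' efficiency; otherwise the baseline is multiplied by the table ratio of
#' every mismatch and clamped to `[0, 1]`. Deterministic; a missing table
#' entry is a configuration error, never a silent default.
#'
#' @param profile A [MismatchProfile] (from [mismatchProfile()]).
#' @param site The [TargetSite] the profile was computed against.
#' @param params A [BindingModelParams].
#' @return A single probability in `[0, 1]`.
#' @examples
#' site <- targetSite(strrep("ACGT", 5))
#' bindingProbability(mismatchProfile(matchedProbe(site), site), site,
#'                    bindingModelParams())  # 0.337
#' @export
bindingProbability <- function(profile, site, params = bindingModelParams()) {
  stopifnot(is(profile, "MismatchProfile"), is(site, "TargetSite"),
            is(params, "BindingModelParams"))
  if (!hasValidPam(site)) return(params@noPamProbability)
  e <- profile@entries
  if (nrow(e) == 0L) return(params@baselineEfficiency)
  rt <- params@ratioTable
  idx <- match(paste(e$position, e$wobble),
               paste(rt$position, rt$wobble))
  if (anyNA(idx)) {
    miss <- e[is.na(idx), , drop = FALSE]
    stop(sprintf("no ratio-table entry for (position %s, wobble %s)",
                 paste(miss$position, collapse = ","),
                 paste(miss$wobble, collapse = ",")), call. = FALSE)
  }
  p <- params@baselineEfficiency * prod(rt$ratio[idx])
  min(max(p, 0), 1)
}

#' Binding probability directly from probe and site
#'
#' Wrapper around [mismatchProfile()] + [bindingProbability()].
#'
#' @inheritParams mismatchProfile
#' @inheritParams bindingProbability
#' @return A single probability in `[0, 1]`.
#' @export
siteBindingProbability <- function(probe, site,
                                   params = bindingModelParams(),
                                   seedBoundary = 12) {
  bindingProbability(mismatchProfile(probe, site, seedBoundary), site, params)
}
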