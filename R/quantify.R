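## Estimators for binding specificity, relative concentration, position-wise
## mismatch tolerance and binding efficiency, from decoded-event tallies.
## Count notation: for barcode b, n_bound is the number of classified events
## with that barcode and at least one dCas9 call; n_unbound the number with
## none.

#' Tally decoded events into per-barcode counts
#'
#' Counts, per barcode, the classified unfolded events with at least one
#' dCas9 binding call (`n_bound`) and without (`n_unbound`). Events decoded
#' as `"unclassified"` are excluded from all downstream statistics.
#'
#' @param decoded Decoded-event table from [decodeEvents()], or a counts
#'   table already holding columns `barcode`, `n_bound`, `n_unbound` (passed
#'   through after validation).
#' @return `data.frame` with columns `barcode`, `n_bound`, `n_unbound`.
#' @export
countEvents <- function(decoded) {
  if (all(c("barcode", "n_bound", "n_unbound") %in% names(decoded)) &&
      !"any_bound" %in% names(decoded)) {
    stopifnot(all(decoded$n_bound >= 0), all(decoded$n_unbound >= 0))
    return(decoded[c("barcode", "n_bound", "n_unbound")])
  }
  stopifnot(all(c("barcode", "any_bound") %in% names(decoded)))
  keep <- decoded$barcode != "unclassified" & !is.na(decoded$any_bound)
  d <- decoded[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(barcode = character(0), n_bound = integer(0),
                      n_unbound = integer(0)))
  agg <- stats::aggregate(cbind(n_bound = d$any_bound,
                                n_unbound = !d$any_bound),
                          by = list(barcode = d$barcode), FUN = sum)
  agg[order(agg$barcode), , drop = FALSE]
}

#' Tally per-position binding calls for a multi-overhang design
#'
#' For a design with several overhang sites, counts per site position the
#' events in which that site was called bound vs unbound (classified events
#' of that barcode only).
#'
#' @param decoded Decoded-event table from [decodeEvents()].
#' @param barcode The design's barcode.
#' @return `data.frame` with columns `position` (site index), `n_bound`,
#'   `n_unbound`.
#' @export
countPositions <- function(decoded, barcode) {
  d <- decoded[decoded$barcode == barcode & !is.na(decoded$bound), ,
               drop = FALSE]
  if (nrow(d) == 0L)
    stop("no classified events with barcode ", barcode, call. = FALSE)
  flags <- t(vapply(strsplit(d$bound, ","),
                    function(v) as.integer(v),
                    integer(length(strsplit(d$bound[1L], ",")[[1]]))))
  if (is.null(dim(flags))) flags <- matrix(flags, ncol = 1L)
  data.frame(position = seq_len(ncol(flags)),
             n_bound = colSums(flags),
             n_unbound = nrow(flags) - colSums(flags))
}

#' Percentage of dCas9-labelled events per barcode
#'
#' Specificity statistic: the share of all labelled (dCas9-bound) classified
#' events carried by each barcode,
#' `100 * n_bound[b] / sum(n_bound)`. For two barcodes this is the published
#' pair of specificity percentages; the generalization to k barcodes keeps
#' all labelled events in the denominator, so the values always sum to 100.
#'
#' @param counts Per-barcode counts from [countEvents()].
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' pctDcas9Events(data.frame(barcode = c("11111", "11001"),
#'                           n_bound = c(947, 53), n_unbound = c(0, 0)))
#' @export
pctDcas9Events <- function(counts) {
  counts <- countEvents(counts)
  tot <- sum(counts$n_bound)
  if (tot == 0)
    stop("no labelled events: percentage of dCas9 events is undefined",
         call. = FALSE)
  stats::setNames(100 * counts$n_bound / tot, counts$barcode)
}

#' Relative concentration of barcoded structures
#'
#' Estimates the mixture composition from labelled and unlabelled event
#' counts of two barcodes. Two estimators are provided:
#'
#' * `"printed"` follows the published relative-concentration formulas
#'   literally: each barcode's labelled-event fraction is multiplied by that
#'   barcode's total event count and the two products are normalized to
#'   sum 1. Note that under equal binding efficiencies this weights each
#'   barcode by the square of its mixture fraction (a 1:3 mixture yields
#'   10%/90%, not 25%/75%).
#' * `"efficiency_corrected"` (default) divides each barcode's labelled
#'   count by its own estimated binding efficiency
#'   `n_bound / (n_bound + n_unbound)`, which reduces to the barcode's total
#'   event count, then normalizes; under equal efficiencies this returns
#'   the input mixture fraction.
#'
#' @param counts Per-barcode counts for exactly two barcodes (the printed
#'   formulas are defined for two).
#' @param mode `"efficiency_corrected"` or `"printed"`.
#' @return Named numeric vector of two fractions summing to 1.
#' @examples
#' cts <- data.frame(barcode = c("10011", "11111"),
#'                   n_bound = c(250, 750), n_unbound = c(750, 2250))
#' relativeConcentration(cts)                    # 0.25, 0.75
#' relativeConcentration(cts, mode = "printed")  # 0.10, 0.90
#' @export
relativeConcentration <- function(counts,
                                  mode = c("efficiency_corrected",
                                           "printed")) {
  mode <- match.arg(mode)
  counts <- countEvents(counts)
  if (nrow(counts) != 2L)
    stop("relative concentration is defined for exactly two barcodes",
         call. = FALSE)
  nb <- counts$n_bound
  nu <- counts$n_unbound
  if (mode == "printed") {
    labFrac <- nb / sum(nb)
    x <- labFrac * (nb + nu)
  } else {
    pHat <- nb / (nb + nu)
    if (any(pHat == 0))
      stop("estimated binding efficiency is zero for barcode(s) ",
           paste(counts$barcode[pHat == 0], collapse = ", "),
           ": corrected mode undefined", call. = FALSE)
    x <- nb / pHat
  }
  stats::setNames(x / sum(x), counts$barcode)
}

#' Position-wise binding fraction
#'
#' `X_position = n_bound / (n_bound + n_unbound)` for one overhang position.
#' Vectorized.
#'
#' @param nBound,nUnbound Event counts at the position.
#' @return Fraction(s) in `[0, 1]`.
#' @export
positionBindingFraction <- function(nBound, nUnbound) {
  tot <- nBound + nUnbound
  if (any(tot == 0))
    stop("zero events at position: binding fraction undefined", call. = FALSE)
  nBound / tot
}

#' Control binding efficiency
#'
#' Arithmetic mean of the binding fractions of the three control positions:
#' the average binding efficiency of the probe at its perfectly matched
#' target, used as the normalization denominator.
#'
#' @param controlFractions Numeric vector of the control-position fractions
#'   (three in the reference design).
#' @return A single fraction.
#' @export
controlEfficiency <- function(controlFractions) {
  stopifnot(length(controlFractions) >= 1L)
  mean(controlFractions)
}

#' Normalized binding ratio to mismatched DNA
#'
#' `X_position / X_control`: a probe binding a mismatched target as well as
#' its matched control has ratio 1.0. May exceed 1.
#'
#' @param xPosition Binding fraction at the mismatched position.
#' @param xControl Control binding efficiency (> 0).
#' @return Ratio >= 0.
#' @examples
#' normalizedBindingRatio(0.337, 0.337)  # 1
#' @export
normalizedBindingRatio <- function(xPosition, xControl) {
  if (any(xControl == 0))
    stop("control efficiency is zero: normalized ratio undefined",
         call. = FALSE)
  xPosition / xControl
}

#' Binding efficiency to a target sequence
#'
#' `100 * n_bound / (n_bound + n_unbound)`, the percentage of a structure's
#' events whose overhang shows a dCas9 spike. Vectorized.
#'
#' @param nBound,nUnbound Event counts.
#' @return Percentage(s) in `[0, 100]`.
#' @examples
#' bindingEfficiency(337, 663)  # 33.7
#' @export
bindingEfficiency <- function(nBound, nUnbound) {
  100 * positionBindingFraction(nBound, nUnbound)
}

#' Population standard deviation
#'
#' `sqrt(sum((x - mean(x))^2) / N)`: the population (divisor `N`) standard
#' deviation used for repeat-to-repeat spread, not the sample (`N - 1`)
#' form.
#'
#' @param values Numeric vector.
#' @return A single non-negative number.
#' @examples
#' populationSd(c(2, 4, 4, 4, 5, 5, 7, 9))  # 2
#' @export
populationSd <- function(values) {
  stopifnot(length(values) >= 1L)
  sqrt(sum((values - mean(values))^2) / length(values))
}

#' Barcode library size
#'
#' `2^nBits` distinct codes: 32 for the 5-bit dumbbell barcode, and over
#' 1e16 for a 56-bit dense carrier. Powers of two are exactly representable
#' as doubles for any `nBits < 1024`, so the result is exact (use
#' `format(x, scientific = FALSE)` to print all digits).
#'
#' @param nBits Number of barcode bits (non-negative integer).
#' @return Exact count as a double.
#' @examples
#' barcodeLibrarySize(5)  # 32
#' format(barcodeLibrarySize(56), scientific = FALSE)
#' @export
barcodeLibrarySize <- function(nBits) {
  stopifnot(length(nBits) == 1L, nBits >= 0, nBits == round(nBits),
            nBits < 1024)
  2^nBits
}

#' Wilson score confidence interval for a binomial fraction
#'
#' 95% (by default) Wilson interval, computed with `stats::prop.test`
#' without continuity correction. Attached as supporting output to every
#' estimated fraction; repeat-to-repeat spread is reported separately as a
#' population SD.
#'
#' @param k Successes.
#' @param n Trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilsonCi <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  ## the chi-squared warning concerns prop.test's p-value, which is unused
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf, correct = FALSE))$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

#' Quantify a decoded run
#'
#' Aggregates the decoded-event table into the full set of binding
#' statistics: per-barcode labelled percentages, binding efficiencies with
#' Wilson intervals, and (for two-barcode runs) relative concentrations in
#' both modes.
#'
#' @param decoded Decoded-event table from [decodeEvents()] (or a counts
#'   table; see [countEvents()]).
#' @param mode Default relative-concentration mode.
#' @return A list of class `"QuantResult"` with elements `counts`,
#'   `pct_dcas9`, `binding_efficiency_pct`, `wilson_ci`, and for two
#'   barcodes `relative_concentration` plus
#'   `relative_concentration_printed`.
#' @export
quantifyBinding <- function(decoded,
                            mode = c("efficiency_corrected", "printed")) {
  mode <- match.arg(mode)
  counts <- countEvents(decoded)
  if (nrow(counts) == 0L) stop("no classified events to quantify",
                               call. = FALSE)
  eff <- bindingEfficiency(counts$n_bound, counts$n_unbound)
  ci <- t(mapply(wilsonCi, counts$n_bound,
                 counts$n_bound + counts$n_unbound))
  rownames(ci) <- counts$barcode
  out <- list(counts = counts,
              pct_dcas9 = pctDcas9Events(counts),
              binding_efficiency_pct = stats::setNames(eff, counts$barcode),
              wilson_ci = ci,
              mode = mode)
  if (nrow(counts) == 2L) {
    ## undefined estimators (a barcode with no labelled events in corrected
    ## mode) are reported as absent rather than aborting the run
    out$relative_concentration <-
      tryCatch(relativeConcentration(counts, mode), error = function(e) NULL)
    out$relative_concentration_printed <-
      tryCatch(relativeConcentration(counts, "printed"),
               error = function(e) NULL)
  }
  class(out) <- "QuantResult"
  out
}

#' @export
print.QuantResult <- function(x, ...) {
  cat("QuantResult over", nrow(x$counts), "barcode(s)\n")
  tab <- x$counts
  tab$pct_dcas9 <- round(x$pct_dcas9[tab$barcode], 2)
  tab$efficiency_pct <- round(x$binding_efficiency_pct[tab$barcode], 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$relative_concentration)) {
    cat(sprintf("relative concentration (%s): %s\n", x$mode,
                paste(sprintf("%s=%.3f", names(x$relative_concentration),
                              x$relative_concentration), collapse = ", ")))
  }
  invisible(x)
}
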