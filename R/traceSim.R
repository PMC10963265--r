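## Synthetic-data generator: seeded current traces with ground-truth logs,
## emulating the measurement at the phenomenological level. Blockades are
## negative deflections from a positive open-pore baseline (conductance
## drop, the usual convention for LiCl solid-state recordings); downstream
## analysis is magnitude-only so polarity is a convention.

## Shared fractional half-width of barcode-slot / overhang windows. Used by
## the simulator to place knot artifacts and by the decoder to bin spikes.
.WINDOW_HALFWIDTH <- 0.04

## Zero-phase first-order smoothing: forward then backward exponential
## moving average, so pulse edges acquire a symmetric finite rise time and
## time reversal commutes with the filter (up to boundary transients).
.zeroPhaseSmooth <- function(x, cutoffHz, samplingRate) {
  if (cutoffHz <= 0 || cutoffHz >= samplingRate / 2) return(x)
  alpha <- 1 - exp(-2 * pi * cutoffHz / samplingRate)
  ema <- function(v) {
    as.numeric(stats::filter(alpha * v, 1 - alpha, method = "recursive",
                             init = v[1L]))
  }
  rev(ema(rev(ema(x))))
}

.spikeWidthFraction <- function(config) {
  config@spikeWidth / (config@dwellMean * config@samplingRate)
}

## Add a spike of extra depth at forward-frame fraction q; for reverse
## events the centre index is mirrored exactly (c -> n + 1 - c) so that the
## reverse profile is the sample-reversed forward profile.
.addSpike <- function(depth, q, extra, halfw, reverse) {
  n <- length(depth)
  ctr <- max(1L, min(n, round(q * n)))
  if (reverse) ctr <- n + 1L - ctr
  lo <- max(1L, ctr - halfw)
  hi <- min(n, ctr + halfw)
  depth[lo:hi] <- depth[lo:hi] + extra
  depth
}

#' Simulate one translocation event
#'
#' Generates the current samples of a single carrier translocation: a square
#' pulse of depth `dsDnaBlockade` lasting a log-normally drawn dwell, with a
#' short extra-depth spike for every barcode bit set to 1 and every bound
#' overhang site. Unbound overhangs add no deflection (50 bp of dsDNA is
#' below the detection limit), except that with probability `knotRate` a
#' spurious knot spike is injected inside the unbound site's window. Reverse
#' translocations mirror all fractional positions; folded events double the
#' blockade over a random leading or trailing 30-70% of the event. Pulse
#' edges are smoothed with a zero-phase first-order filter at
#' `lowpassCutoff` and Gaussian noise of SD `noiseSd` is added.
#'
#' Draws come from the current RNG state, so the output is deterministic
#' given that state; [simulateTrace()] manages seeding.
#'
#' @param design A [NanostructureDesign].
#' @param boundFlags Logical vector, one flag per overhang site.
#' @param direction `"forward"` or `"reverse"`.
#' @param folded Logical.
#' @param config A [SimConfig].
#' @return A list with `samples` (numeric, pA, baseline included) and
#'   `truth` (list: `dwell_s`, `n_samples`, `direction`, `folded`,
#'   `fold_side`, `fold_frac`, `bound`, `knots` in carrier-frame fractions,
#'   `degenerate`). Events too short to resolve the spike spacing
#'   (< 100 samples) are flagged degenerate.
#' @export
simulateEvent <- function(design, boundFlags, direction = "forward",
                          folded = FALSE, config = simConfig()) {
  stopifnot(is(design, "NanostructureDesign"), is(config, "SimConfig"))
  direction <- match.arg(direction, c("forward", "reverse"))
  sites <- overhangSites(design)
  if (length(boundFlags) != length(sites))
    stop("boundFlags length must match the number of overhang sites",
         call. = FALSE)
  fs <- config@samplingRate
  dwell <- stats::rlnorm(1, meanlog = log(config@dwellMean) -
                           config@dwellSdLog^2 / 2,
                         sdlog = config@dwellSdLog)
  n <- max(2L, as.integer(round(dwell * fs)))
  degenerate <- n < 100L

  depth <- rep(config@dsDnaBlockade, n)
  foldSide <- NA_character_
  foldFrac <- NA_real_
  if (folded) {
    foldSide <- if (stats::runif(1) < 0.5) "leading" else "trailing"
    foldFrac <- stats::runif(1, 0.3, 0.7)
    k <- max(1L, round(foldFrac * n))
    idx <- if (foldSide == "leading") seq_len(k) else seq.int(n - k + 1L, n)
    depth[idx] <- depth[idx] + config@dsDnaBlockade
  }

  rev <- direction == "reverse"
  halfw <- max(1L, round(0.5 * .spikeWidthFraction(config) * n))
  bits <- as.integer(strsplit(barcode(design), "")[[1]])
  for (j in seq_along(bits)) {
    if (bits[j] == 1L)
      depth <- .addSpike(depth, slotPositions(design)[j],
                         config@spikeExtraBlockade, halfw, rev)
  }
  knots <- numeric(0)
  for (j in seq_along(sites)) {
    if (isTRUE(boundFlags[j])) {
      depth <- .addSpike(depth, sites[[j]]$position,
                         config@spikeExtraBlockade, halfw, rev)
    } else if (stats::runif(1) < config@knotRate) {
      hw <- .WINDOW_HALFWIDTH
      q <- stats::runif(1, max(1e-3, sites[[j]]$position - hw),
                        min(1 - 1e-3, sites[[j]]$position + hw))
      knots <- c(knots, q)
      depth <- .addSpike(depth, q, config@spikeExtraBlockade, halfw, rev)
    }
  }

  ## smooth with baseline context on both sides, then trim back to n
  pad <- 32L
  padded <- c(rep(0, pad), depth, rep(0, pad))
  smoothed <- .zeroPhaseSmooth(padded, config@lowpassCutoff, fs)
  profile <- config@baselineCurrent - smoothed[(pad + 1L):(pad + n)]
  samples <- profile + stats::rnorm(n, 0, config@noiseSd)

  list(samples = samples,
       truth = list(dwell_s = dwell, n_samples = n, direction = direction,
                    folded = folded, fold_side = foldSide,
                    fold_frac = foldFrac, bound = as.logical(boundFlags),
                    knots = knots, degenerate = degenerate))
}

.carrierList <- function(carriers) {
  if (is(carriers, "NanostructureDesign")) carriers <- list(carriers)
  ## a bare (design, probe) pair is promoted to a one-carrier list
  if (!is.null(carriers$design)) carriers <- list(carriers)
  lapply(carriers, function(ca) {
    if (is(ca, "NanostructureDesign")) list(design = ca, probe = NULL)
    else {
      stopifnot(is(ca$design, "NanostructureDesign"))
      if (!is.null(ca$probe)) stopifnot(is(ca$probe, "GuideProbe"))
      ca
    }
  })
}

#' Simulate a full recording of a carrier mixture
#'
#' Draws `nEvents` translocation events from a mixture of nanostructure
#' designs (multinomially by `concentrationWeight`), decides per-site dCas9
#' occupancy by a Bernoulli draw of the guide-model binding probability of
#' the paired probe (0 if no probe is paired), direction uniformly, and
#' folding with probability `foldedFraction`, then assembles the events into
#' one continuous trace separated by exponential baseline-only gaps. Fully
#' reproducible: identical configuration and seed give identical samples.
#'
#' @param carriers A [NanostructureDesign], a list of designs, or a list of
#'   `list(design = , probe = )` pairs pairing each design with the
#'   [GuideProbe] in solution that targets it (`probe = NULL` for none).
#' @param nEvents Number of events (>= 0).
#' @param config A [SimConfig]; `config@seed` seeds the run.
#' @param bindingParams A [BindingModelParams] for the occupancy draws.
#' @return A list with `trace` (a [CurrentTrace]) and `truth` (a
#'   `data.frame` with one row per event: design, barcode, direction,
#'   folded, per-site `bound` flags as a comma string, `n_bound`, knot
#'   positions, `start`/`end` sample indices, `dwell_s`, `degenerate`).
#' @examples
#' d <- nanostructureDesign("wt", "11111",
#'                          overhangSites = targetSite(strrep("ACGT", 5)))
#' sim <- simulateTrace(list(list(design = d, probe = NULL)), nEvents = 3,
#'                      config = simConfig(seed = 7, foldedFraction = 0))
#' sim$truth
#' @export
simulateTrace <- function(carriers, nEvents, config = simConfig(),
                          bindingParams = bindingModelParams()) {
  stopifnot(is(config, "SimConfig"))
  if (length(nEvents) != 1L || is.na(nEvents) || nEvents < 0)
    stop("nEvents must be a single non-negative integer", call. = FALSE)
  nEvents <- as.integer(nEvents)
  carriers <- .carrierList(carriers)
  k <- length(carriers)
  weights <- vapply(carriers, function(ca) concentrationWeight(ca$design),
                    numeric(1))
  if (k == 0L || all(weights == 0))
    stop("concentration weights must not all be zero", call. = FALSE)
  pSite <- lapply(carriers, function(ca) {
    sites <- overhangSites(ca$design)
    if (is.null(ca$probe)) rep(0, length(sites))
    else vapply(sites, function(s)
      siteBindingProbability(ca$probe, s$site, bindingParams), numeric(1))
  })

  ## seed locally, restore the caller's RNG state afterwards
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(config@seed))

  fs <- config@samplingRate
  gapLen <- function() {
    max(200L, as.integer(round(stats::rexp(1, config@eventRate) * fs)))
  }
  gapChunk <- function() {
    len <- gapLen()
    config@baselineCurrent + stats::rnorm(len, 0, config@noiseSd)
  }

  designIdx <- if (nEvents > 0L)
    sample.int(k, nEvents, replace = TRUE, prob = weights) else integer(0)

  chunks <- vector("list", 2L * nEvents + 1L)
  rows <- vector("list", nEvents)
  pos <- 0L
  ci <- 1L
  for (i in seq_len(nEvents)) {
    g <- gapChunk()
    chunks[[ci]] <- g; ci <- ci + 1L
    pos <- pos + length(g)
    ca <- carriers[[designIdx[i]]]
    nSites <- length(overhangSites(ca$design))
    bound <- if (nSites > 0L) stats::runif(nSites) < pSite[[designIdx[i]]]
             else logical(0)
    direction <- if (stats::runif(1) < 0.5) "forward" else "reverse"
    folded <- stats::runif(1) < config@foldedFraction
    ev <- simulateEvent(ca$design, bound, direction, folded, config)
    chunks[[ci]] <- ev$samples; ci <- ci + 1L
    tr <- ev$truth
    rows[[i]] <- data.frame(
      event = i, design = ca$design@name, barcode = barcode(ca$design),
      direction = tr$direction, folded = tr$folded,
      fold_side = tr$fold_side, fold_frac = tr$fold_frac,
      bound = paste(as.integer(tr$bound), collapse = ","),
      n_bound = sum(tr$bound),
      knots = paste(signif(tr$knots, 6), collapse = ","),
      start = pos + 1L, end = pos + tr$n_samples,
      dwell_s = tr$dwell_s, degenerate = tr$degenerate,
      stringsAsFactors = FALSE)
    pos <- pos + tr$n_samples
  }
  chunks[[ci]] <- gapChunk()

  trace <- currentTrace(unlist(chunks, use.names = FALSE), fs,
                        metadata = list(baseline = config@baselineCurrent,
                                        seed = config@seed,
                                        noise_sd = config@noiseSd,
                                        generator = "simulateTrace"))
  truth <- if (nEvents > 0L) do.call(rbind, rows)
           else data.frame(event = integer(0), design = character(0),
                           barcode = character(0), direction = character(0),
                           folded = logical(0), fold_side = character(0),
                           fold_frac = numeric(0), bound = character(0),
                           n_bound = integer(0), knots = character(0),
                           start = integer(0), end = integer(0),
                           dwell_s = numeric(0), degenerate = logical(0))
  list(trace = trace, truth = truth)
}
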