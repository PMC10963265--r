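# Shared fixture builders. All synthetic inputs are generated in code.

# A canonical protospacer/PAM and its perfectly matching probe
fixtureSite <- function(pam = "TGG") targetSite(strrep("ACGT", 5), pam)

# A carrier (design + optional matched probe); `pam = "TAA"` makes a
# PAM-less site, `probe = FALSE` an unpaired structure
fixtureCarrier <- function(name, code, weight = 1, pam = "TGG",
                           probe = TRUE, overhangPos = 0.1, nSites = 1) {
  sites <- lapply(seq_len(nSites), function(i)
    list(position = overhangPos + 0.07 * (i - 1), site = fixtureSite(pam)))
  d <- nanostructureDesign(name, code, overhangSites = sites,
                           concentrationWeight = weight)
  list(design = d,
       probe = if (probe) matchedProbe(fixtureSite(pam)) else NULL)
}

# Fast simulator settings for tests: shorter gaps, everything else default
testSimConfig <- function(...) {
  args <- utils::modifyList(list(eventRate = 250, seed = 1), list(...))
  do.call(simConfig, args)
}

# Wrap raw event samples in baseline so the public detection path can be
# used on constructed events
wrapEvent <- function(samples, baseline = 10000, fs = 250000, pad = 3000) {
  tr <- currentTrace(c(rep(baseline, pad), samples, rep(baseline, pad)), fs,
                     metadata = list(baseline = baseline))
  findEvents(tr)
}

# Construct a bare blockade profile (depth below a flat baseline) with
# rectangular spikes at given fractional positions
profileEvent <- function(n = 1000, baseline = 10000, dsDepth = 120,
                         spikeAt = numeric(0), spikeDepth = 120,
                         spikeHalfw = 5L) {
  depth <- rep(dsDepth, n)
  for (k in seq_along(spikeAt)) {
    ctr <- round(spikeAt[k] * n)
    lo <- max(1L, ctr - spikeHalfw)
    hi <- min(n, ctr + spikeHalfw)
    depth[lo:hi] <- depth[lo:hi] + spikeDepth[min(k, length(spikeDepth))]
  }
  baseline - depth
}

# Match detected events to ground-truth rows by maximal interval overlap;
# returns the truth row index per event (NA when no overlap)
matchTruth <- function(eventsTable, truth) {
  vapply(seq_len(nrow(eventsTable)), function(i) {
    ov <- pmin(eventsTable$end[i], truth$end) -
      pmax(eventsTable$start[i], truth$start) + 1L
    ov[ov < 0L] <- 0L
    if (all(ov == 0L)) NA_integer_ else which.max(ov)
  }, integer(1))
}

# Full pipeline on a simulated mixture, returning decoded events joined to
# their ground truth
runDecodePipeline <- function(carriers, nEvents, config,
                              bindingParams = bindingModelParams(),
                              peaks = peakParams()) {
  sim <- simulateTrace(carriers, nEvents, config, bindingParams)
  es <- findEvents(sim$trace)
  kept <- filterNoisyEvents(es)$kept
  cls <- classifyFoldStates(kept)
  dec <- decodeEvents(cls, lapply(carriers, `[[`, "design"), peaks)
  tab <- eventTable(cls)
  dec$truth_row <- matchTruth(tab[dec$event_id, , drop = FALSE], sim$truth)
  list(sim = sim, events = cls, decoded = dec)
}
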