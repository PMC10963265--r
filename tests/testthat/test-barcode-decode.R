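# Spike calling, barcode assignment with orientation handling, and
# per-overhang binding calls.

slots5 <- seq(0.3, 0.7, by = 0.1)

test_that("detectSpikes calls constructed spikes at their positions", {
  pos <- c(0.1, slots5)
  x <- profileEvent(n = 1000, spikeAt = pos)
  spikes <- detectSpikes(x, 10000, 120)
  expect_identical(nrow(spikes), 6L)
  expect_true(all(abs(sort(spikes$position) - sort(pos)) < 0.011))
  expect_true(all(spikes$depth > 60))
  expect_true(!is.unsorted(spikes$position))
})

test_that("spikes below the prominence or height thresholds are not called", {
  # a 40 pA bump fails both the 60 pA height and prominence criteria
  x <- profileEvent(spikeAt = c(0.3, 0.5), spikeDepth = c(120, 40))
  spikes <- detectSpikes(x, 10000, 120)
  expect_identical(nrow(spikes), 1L)
  expect_lt(abs(spikes$position - 0.3), 0.011)

  # high but non-prominent: a shoulder on a wide pedestal
  depth <- rep(120, 1000)
  depth[300:500] <- 240          # wide pedestal
  depth[390:410] <- 250          # small bump on top: prominence 10
  x2 <- 10000 - depth
  s2 <- detectSpikes(x2, 10000, 120)
  expect_true(all(abs(s2$position - 0.4) > 0.05 | s2$depth >= 120))
  expect_identical(nrow(s2), 1L)  # only the pedestal peak survives
})

test_that("minimum-distance suppression keeps the deeper spike, ties to the
           earlier", {
  # deeper of a violating pair wins
  x <- profileEvent(spikeAt = c(0.40, 0.43), spikeDepth = c(80, 100))
  spikes <- detectSpikes(x, 10000, 120, peakParams(minDistance = 0.05))
  expect_identical(nrow(spikes), 1L)
  expect_lt(abs(spikes$position - 0.43), 0.011)

  # exact tie: the earlier position wins
  xt <- profileEvent(spikeAt = c(0.40, 0.43), spikeDepth = c(90, 90))
  st <- detectSpikes(xt, 10000, 120, peakParams(minDistance = 0.05))
  expect_identical(nrow(st), 1L)
  expect_lt(abs(st$position - 0.40), 0.011)

  # spaced beyond minDistance both survive
  xs <- profileEvent(spikeAt = c(0.40, 0.48), spikeDepth = c(90, 90))
  expect_identical(
    nrow(detectSpikes(xs, 10000, 120, peakParams(minDistance = 0.05))), 2L)
})

test_that("assignBarcode resolves orientation against the library", {
  spikesAt <- function(pos) data.frame(position = pos,
                                       depth = rep(120, length(pos)),
                                       index = as.integer(round(pos * 1000)))
  lib <- c("11111", "11001")

  # palindromic occupancy: barcode assigned, orientation ambiguous
  a <- assignBarcode(spikesAt(slots5), slots5, lib)
  expect_identical(a$barcode, "11111")
  expect_identical(a$orientation, "ambiguous")

  # occupancy 10011 is the reversal of 11001
  b <- assignBarcode(spikesAt(c(0.3, 0.6, 0.7)), slots5, "11001")
  expect_identical(b$barcode, "11001")
  expect_identical(b$orientation, "reverse")

  # forward match of an asymmetric code
  f <- assignBarcode(spikesAt(c(0.3, 0.4, 0.7)), slots5, "11001")
  expect_identical(f$barcode, "11001")
  expect_identical(f$orientation, "forward")

  # occupancy matching no code in either orientation
  u <- assignBarcode(spikesAt(c(0.3, 0.5, 0.7)), slots5, lib)
  expect_identical(u$barcode, "unclassified")
  expect_identical(u$orientation, "ambiguous")

  # occupancy matching two different codes is not unique
  two <- assignBarcode(spikesAt(c(0.3, 0.4, 0.7)), slots5,
                       c("11001", "10011"))
  expect_identical(two$barcode, "unclassified")

  # spikes in slot windows are consumed, off-slot spikes are not
  c1 <- assignBarcode(spikesAt(c(0.1, 0.3)), slots5, lib)
  expect_identical(c1$consumed, c(FALSE, TRUE))

  expect_error(assignBarcode(spikesAt(0.3), slots5, lib,
                             slotTolerance = 0.5), "overlap")
  expect_error(assignBarcode(spikesAt(0.3), slots5, character(0)), "empty")
})

test_that("callDcas9 applies mirrored windows and counts artifacts", {
  spikesAt <- function(pos) data.frame(position = pos,
                                       depth = rep(120, length(pos)),
                                       index = as.integer(round(pos * 1000)))
  pos3 <- c(0.08, 0.15, 0.22)

  # spike at a window centre
  one <- callDcas9(spikesAt(0.08), pos3, "forward")
  expect_identical(one$bound, c(TRUE, FALSE, FALSE))
  expect_identical(one$offWindow, 0L)

  # no non-barcode spikes: all sites unbound
  none <- callDcas9(spikesAt(numeric(0)), pos3, "forward")
  expect_identical(none$bound, c(FALSE, FALSE, FALSE))

  # spikes in two of three windows
  two <- callDcas9(spikesAt(c(0.15, 0.22)), pos3, "forward")
  expect_identical(sum(two$bound), 2L)

  # reverse orientation mirrors the windows
  rev1 <- callDcas9(spikesAt(1 - 0.15), pos3, "reverse")
  expect_identical(rev1$bound, c(FALSE, TRUE, FALSE))
  expect_identical(callDcas9(spikesAt(0.15), pos3, "reverse")$bound,
                   c(FALSE, FALSE, FALSE))

  # ambiguous orientation accepts either window
  amb <- callDcas9(spikesAt(1 - 0.08), pos3, "ambiguous")
  expect_identical(amb$bound, c(TRUE, FALSE, FALSE))

  # a spike inside no window is an off-window artifact
  off <- callDcas9(spikesAt(0.5), pos3, "forward")
  expect_identical(off$offWindow, 1L)
  expect_identical(off$bound, c(FALSE, FALSE, FALSE))

  # consumed spikes are invisible to the binding call
  cons <- callDcas9(spikesAt(c(0.08, 0.3)), pos3, "forward",
                    consumed = c(TRUE, FALSE))
  expect_identical(cons$bound, c(FALSE, FALSE, FALSE))
})

test_that("decoding is invariant under time reversal of the samples", {
  ca <- fixtureCarrier("asym", "11001")
  cfg <- testSimConfig(knotRate = 0, noiseSd = 3)
  designs <- list(ca$design)
  set.seed(41)
  for (rep in 1:12) {
    dirn <- sample(c("forward", "reverse"), 1)
    bound <- runif(1) < 0.5
    ev <- simulateEvent(ca$design, bound, dirn, FALSE, cfg)
    d1 <- decodeEvents(wrapEvent(ev$samples), designs)
    d2 <- decodeEvents(wrapEvent(rev(ev$samples)), designs)
    expect_identical(d1$barcode, d2$barcode)
    expect_identical(d1$bound, d2$bound)
    expect_identical(d1$barcode, "11001")
    expect_identical(d1$any_bound, bound)
  }
})

test_that("per-site binding calls reproduce the simulator's ground truth", {
  carriers <- list(fixtureCarrier("a", "11111"),
                   fixtureCarrier("b", "11001", pam = "TAA", probe = FALSE))
  out <- runDecodePipeline(carriers, 1000,
                           testSimConfig(knotRate = 0, seed = 42),
                           bindingModelParams(baselineEfficiency = 0.5))
  dec <- out$decoded
  expect_gt(nrow(dec), 200)
  expect_lt(mean(dec$barcode == "unclassified"), 0.01)
  ok <- dec$barcode != "unclassified" & !is.na(dec$truth_row)
  agree <- dec$any_bound[ok] ==
    (out$sim$truth$n_bound[dec$truth_row[ok]] > 0)
  expect_gte(mean(agree), 0.99)
  # barcode calls agree with the simulated design
  expect_gte(mean(dec$barcode[ok] ==
                    out$sim$truth$barcode[dec$truth_row[ok]]), 0.99)
})

test_that("with zero true binding the measured bound fraction equals the
           knot rate", {
  k <- 0.045
  carriers <- list(fixtureCarrier("a", "11111", probe = FALSE))
  out <- runDecodePipeline(
    carriers, 2000,
    testSimConfig(knotRate = k, foldedFraction = 0, seed = 43))
  dec <- out$decoded[out$decoded$barcode != "unclassified", ]
  n <- nrow(dec)
  frac <- mean(dec$any_bound)
  expect_lt(abs(frac - k), 3 * sqrt(k * (1 - k) / n))
})

test_that("the barcode confusion matrix is diagonal-dominant", {
  carriers <- list(fixtureCarrier("a", "11111"),
                   fixtureCarrier("b", "11001"),
                   fixtureCarrier("c", "10110"),
                   fixtureCarrier("d", "00100"))
  out <- runDecodePipeline(carriers, 800, testSimConfig(seed = 44))
  dec <- out$decoded
  ok <- dec$barcode != "unclassified" & !is.na(dec$truth_row)
  truthCode <- out$sim$truth$barcode[dec$truth_row[ok]]
  expect_gte(mean(dec$barcode[ok] == truthCode), 0.99)
  # off-diagonal rate per true barcode at most 1%
  for (code in unique(truthCode)) {
    sel <- truthCode == code
    expect_lte(mean(dec$barcode[ok][sel] != code), 0.01)
  }
})

test_that("decodeEvents rejects inconsistent design sets", {
  a <- nanostructureDesign("a", "11111")
  b <- nanostructureDesign("b", "11111")
  es <- wrapEvent(profileEvent())
  expect_error(decodeEvents(es, list(a, b)), "distinct barcodes")
  c1 <- nanostructureDesign("c", "111", slotPositions = c(0.3, 0.4, 0.5))
  expect_error(decodeEvents(es, list(a, c1)), "same slot layout")
  # an overhang window overlapping a slot window is a configuration error
  bad <- nanostructureDesign("bad", "11111",
                             overhangSites = list(list(position = 0.31,
                                                       site = fixtureSite())))
  expect_error(decodeEvents(es, list(bad)), "overlapping decode windows")
})
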