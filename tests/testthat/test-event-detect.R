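# Event segmentation and quality filters.

test_that("baseline estimation recovers level and noise scale", {
  # constant trace: exact level, zero noise
  bl <- estimateBaseline(currentTrace(rep(10000, 5000), 250000))
  expect_identical(unname(bl), c(10000, 0))

  # seeded simulation oracle: known level and sigma
  set.seed(21)
  tr <- currentTrace(10000 + rnorm(200000, 0, 6), 250000)
  bl <- estimateBaseline(tr)
  expect_lt(abs(bl[["level"]] - 10000), 1)
  expect_lt(abs(bl[["sigma"]] - 6) / 6, 0.2)

  # still robust with a sizeable event fraction present
  set.seed(22)
  x <- 10000 + rnorm(50000, 0, 6)
  x[10000:20000] <- x[10000:20000] - 120
  bl <- estimateBaseline(currentTrace(x, 250000))
  expect_lt(abs(bl[["level"]] - 10000), 1)
})

test_that("degenerate traces are rejected", {
  expect_error(estimateBaseline(currentTrace(rep(10000, 10), 250000)),
               "at least 1000")
  # a trace that is 100% event: nominal baseline metadata exposes it
  allEvent <- currentTrace(rep(9880, 5000), 250000,
                           metadata = list(baseline = 10000))
  expect_error(estimateBaseline(allEvent), "no open-pore baseline")
})

test_that("findEvents segments injected pulses at their true boundaries", {
  set.seed(31)
  noise <- function(n) rnorm(n, 0, 6)
  pulse <- function(n) rep(-120, n)
  x <- c(10000 + noise(5000),
         10000 + pulse(600) + noise(600),
         10000 + noise(5000))
  es <- findEvents(currentTrace(x, 250000))
  expect_identical(nEvents(es), 1L)
  tab <- eventTable(es)
  expect_lt(abs(tab$start - 5001), 10)
  expect_lt(abs(tab$end - 5600), 10)

  # two pulses separated by a clear gap come back in order
  x2 <- c(10000 + noise(4000), 10000 + pulse(500) + noise(500),
          10000 + noise(4000), 10000 + pulse(700) + noise(700),
          10000 + noise(4000))
  es2 <- findEvents(currentTrace(x2, 250000))
  expect_identical(nEvents(es2), 2L)
  t2 <- eventTable(es2)
  expect_true(all(diff(t2$start) > 0))
  expect_true(all(t2$start[-1] > t2$end[-nrow(t2)]))

  # baseline-only trace: the empty list is a valid result
  es0 <- findEvents(currentTrace(10000 + noise(20000), 250000))
  expect_identical(nEvents(es0), 0L)

  # sub-minimum-duration blips are not events
  x3 <- c(10000 + noise(5000), 10000 + pulse(20) + noise(20),
          10000 + noise(5000))
  expect_identical(nEvents(findEvents(currentTrace(x3, 250000))), 0L)
})

test_that("event intervals are always disjoint and sorted", {
  carriers <- list(fixtureCarrier("a", "11111"),
                   fixtureCarrier("b", "11001"))
  s <- simulateTrace(carriers, 200, testSimConfig(seed = 32))
  tab <- eventTable(findEvents(s$trace))
  expect_true(all(tab$end > tab$start))
  if (nrow(tab) > 1L)
    expect_true(all(tab$start[-1] > tab$end[-nrow(tab)]))
})

test_that("the noise filter partitions events exhaustively at 15 pA", {
  set.seed(33)
  mkPulse <- function(extraNoise) {
    c(10000 + rnorm(4000, 0, 6),
      9880 + rnorm(800, 0, sqrt(6^2 + extraNoise^2)),
      10000 + rnorm(4000, 0, 6))
  }
  x <- c(mkPulse(0), mkPulse(25))  # second event is noisy
  es <- findEvents(currentTrace(x, 250000))
  expect_identical(nEvents(es), 2L)
  parts <- filterNoisyEvents(es, maxNoisePA = 15)
  expect_identical(nEvents(parts$kept), 1L)
  expect_identical(nEvents(parts$discarded), 1L)
  expect_identical(nEvents(parts$kept) + nEvents(parts$discarded),
                   nEvents(es))
  expect_true(all(eventTable(parts$kept)$noise_pA <= 15))
  expect_true(all(eventTable(parts$discarded)$noise_pA > 15))

  # boundary semantics: noise of exactly 16 pA is discarded, 5 pA is kept
  expect_identical(nEvents(filterNoisyEvents(es, maxNoisePA = 5)$kept), 0L)

  # empty set in, empty partition out
  es0 <- findEvents(currentTrace(10000 + rnorm(20000, 0, 6), 250000))
  p0 <- filterNoisyEvents(es0)
  expect_identical(nEvents(p0$kept), 0L)
  expect_identical(nEvents(p0$discarded), 0L)
})

test_that("fold classification follows the depth-fraction rule", {
  n <- 1000
  # uniform single blockade: unfolded
  expect_identical(
    classifyFoldState(rep(10000 - 120, n), 10000, 120), "unfolded")
  # leading 40% at twice the blockade: folded
  ev <- c(rep(10000 - 240, 0.4 * n), rep(10000 - 120, 0.6 * n))
  expect_identical(classifyFoldState(ev, 10000, 120), "folded")
  # a 5% spike at twice the blockade is not a fold
  sp <- rep(10000 - 120, n)
  sp[500:549] <- 10000 - 240
  expect_identical(classifyFoldState(sp, 10000, 120), "unfolded")
  # rule boundary: exactly minFraction does not trigger
  ev20 <- c(rep(10000 - 240, 200), rep(10000 - 120, 800))
  expect_identical(classifyFoldState(ev20, 10000, 120), "unfolded")
  expect_identical(classifyFoldState(ev20, 10000, 120, minFraction = 0.19),
                   "folded")
})

test_that("detection achieves near-perfect precision and recall, and every
           true folded event is excluded", {
  carriers <- list(fixtureCarrier("a", "11111"),
                   fixtureCarrier("b", "11001"))
  s <- simulateTrace(carriers, 500, testSimConfig(knotRate = 0, seed = 34))
  es <- classifyFoldStates(filterNoisyEvents(findEvents(s$trace))$kept)
  tab <- eventTable(es)
  m <- matchTruth(tab, s$truth)

  recall <- length(unique(stats::na.omit(m))) / nrow(s$truth)
  precision <- mean(!is.na(m))
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)

  # fold classification agrees with the simulator's ground truth
  truthFolded <- s$truth$folded[m]
  expect_true(all(tab$fold_state[truthFolded] == "folded"))
  expect_true(all(tab$fold_state[!truthFolded] == "unfolded"))
})
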