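# Binding statistics: labelled-event percentages, relative concentration
# in both estimators, position-wise ratios, efficiencies, population SD
# and library combinatorics.

cts <- function(codes, nb, nu) {
  data.frame(barcode = codes, n_bound = nb, n_unbound = nu)
}

test_that("labelled-event percentages mirror the published pair and sum
           to 100", {
  p <- pctDcas9Events(cts(c("11111", "11001"), c(947, 53), c(0, 0)))
  expect_equal(unname(p), c(94.7, 5.3))
  expect_equal(sum(p), 100)

  expect_equal(unname(pctDcas9Events(cts(c("a", "b"), c(0, 10), c(0, 0)))),
               c(0, 100))
  # symmetry over k barcodes
  k <- 5
  pk <- pctDcas9Events(cts(letters[1:k], rep(1, k), rep(2, k)))
  expect_equal(unname(pk), rep(100 / k, k))
  expect_equal(sum(pk), 100)

  expect_error(pctDcas9Events(cts(c("a", "b"), c(0, 0), c(5, 5))),
               "undefined")
})

test_that("relative concentration: corrected mode returns the mixture,
           printed mode the literal formula", {
  # equal counts, equal efficiency: both modes give 50/50
  eq <- cts(c("a", "b"), c(100, 100), c(200, 200))
  expect_equal(unname(relativeConcentration(eq)), c(0.5, 0.5))
  expect_equal(unname(relativeConcentration(eq, "printed")), c(0.5, 0.5))

  # 1:3 mixture at equal efficiency p = 0.25, exact expected counts
  mix <- cts(c("10011", "11111"), c(250, 750), c(750, 2250))
  expect_equal(unname(relativeConcentration(mix)), c(0.25, 0.75))
  # the literal equations weight by the squared mixture fraction
  expect_equal(unname(relativeConcentration(mix, "printed")), c(0.10, 0.90))

  # both modes normalize to 1
  odd <- cts(c("a", "b"), c(37, 411), c(150, 90))
  expect_equal(sum(relativeConcentration(odd)), 1)
  expect_equal(sum(relativeConcentration(odd, "printed")), 1)

  expect_error(relativeConcentration(cts("a", 10, 5)), "exactly two")
  expect_error(relativeConcentration(cts(c("a", "b"), c(0, 10), c(5, 5))),
               "zero")
})

test_that("position fractions, control efficiency and normalized ratio", {
  expect_equal(positionBindingFraction(10, 10), 0.5)
  expect_equal(positionBindingFraction(0, 50), 0)
  expect_equal(positionBindingFraction(337, 663), 0.337)
  expect_error(positionBindingFraction(0, 0), "undefined")

  expect_equal(controlEfficiency(c(0.337, 0.337, 0.337)), 0.337)
  expect_equal(controlEfficiency(c(0, 0, 0)), 0)
  expect_equal(controlEfficiency(c(0.3, 0.33, 0.38)), mean(c(0.3, 0.33, 0.38)))

  # a probe binding its control as well as the control binds has ratio 1
  expect_identical(normalizedBindingRatio(0.337, 0.337), 1)
  expect_identical(normalizedBindingRatio(0, 0.337), 0)
  expect_equal(normalizedBindingRatio(0.1685, 0.337), 0.5)
  expect_error(normalizedBindingRatio(0.3, 0), "undefined")
})

test_that("binding efficiency and its scale invariance", {
  expect_equal(bindingEfficiency(10, 0), 100)
  expect_equal(bindingEfficiency(0, 10), 0)
  expect_equal(bindingEfficiency(337, 663), 33.7)
  # multiplying all counts by a constant changes nothing
  for (s in c(2, 10, 137)) {
    expect_equal(bindingEfficiency(337 * s, 663 * s), 33.7)
    base <- cts(c("a", "b"), c(40, 160), c(60, 140))
    scaled <- cts(c("a", "b"), c(40, 160) * s, c(60, 140) * s)
    expect_equal(pctDcas9Events(base), pctDcas9Events(scaled))
    expect_equal(relativeConcentration(base), relativeConcentration(scaled))
  }
})

test_that("population SD uses the N divisor", {
  expect_identical(populationSd(c(1, 1, 1)), 0)
  expect_identical(populationSd(c(0, 2)), 1)
  # direct-evaluation oracle
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_identical(populationSd(x), sqrt(sum((x - mean(x))^2) / length(x)))
  expect_identical(populationSd(x), 2)
  # strictly smaller than the sample SD for non-constant data
  expect_lt(populationSd(x), sd(x))
})

test_that("barcode library size is exact integer arithmetic", {
  expect_identical(barcodeLibrarySize(5), 32)
  expect_identical(barcodeLibrarySize(1), 2)
  n56 <- barcodeLibrarySize(56)
  expect_identical(format(n56, scientific = FALSE), "72057594037927936")
  expect_gt(n56, 1e16)
  expect_error(barcodeLibrarySize(5.5))
})

test_that("wilsonCi matches the score interval and brackets the estimate", {
  ci <- wilsonCi(337, 1000)
  expect_lt(ci[["lower"]], 0.337)
  expect_gt(ci[["upper"]], 0.337)
  # agreement with the closed-form Wilson formula
  z <- qnorm(0.975)
  p <- 0.337; n <- 1000
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(unname(ci), c(centre - half, centre + half), tolerance = 1e-8)
})

test_that("countEvents aggregates decoded rows and drops unclassified", {
  dec <- data.frame(
    event_id = 1:6,
    barcode = c("11111", "11111", "11001", "unclassified", "11001", "11111"),
    orientation = "forward",
    n_spikes = 5L,
    bound = c("1", "0", "0", NA, "1", "1"),
    n_bound = c(1L, 0L, 0L, NA, 1L, 1L),
    any_bound = c(TRUE, FALSE, FALSE, NA, TRUE, TRUE),
    off_window_count = 0L, stringsAsFactors = FALSE)
  counts <- countEvents(dec)
  expect_identical(counts$barcode, c("11001", "11111"))
  expect_identical(counts$n_bound, c(1L, 2L))
  expect_identical(counts$n_unbound, c(1L, 1L))
  # a counts table passes through unchanged
  expect_identical(countEvents(counts)$n_bound, c(1L, 2L))
})

test_that("quantifyBinding assembles a coherent result", {
  counts <- cts(c("10011", "11111"), c(250, 750), c(750, 2250))
  q <- quantifyBinding(counts)
  expect_s3_class(q, "QuantResult")
  expect_equal(sum(q$pct_dcas9), 100)
  expect_equal(unname(q$relative_concentration), c(0.25, 0.75))
  expect_equal(unname(q$relative_concentration_printed), c(0.10, 0.90))
  expect_equal(unname(q$binding_efficiency_pct), c(25, 25))
  expect_identical(rownames(q$wilson_ci), c("10011", "11111"))
  expect_output(print(q), "QuantResult")
})
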