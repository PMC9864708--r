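test_that("published interval boundaries score exactly as printed", {
  thC <- pvi_thresholds("C")
  expect_equal(score_pvi(c(0.15, 0.20, 0.22, 0.26, 0.30, 0.36, 0.37), thC),
               c(4L, 4L, 3L, 3L, 2L, 2L, 1L))
  expect_warning(s <- score_pvi(2.5, thC), "sanity bound")
  expect_equal(s, 1L)
  expect_error(score_pvi(0, thC), "non-positive")
  thMaxS <- pvi_thresholds("MaxS")
  expect_equal(score_pvi(c(50, 80, 90, 101, 105, 110, 111), thMaxS),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  thMeanS <- pvi_thresholds("MeanS")
  expect_equal(score_pvi(c(70, 88, 93, 94), thMeanS), c(1L, 2L, 3L, 4L))
  thMaxSn <- pvi_thresholds("MaxSn")
  expect_equal(score_pvi(c(0.17, 0.18, 0.2, 0.21), thMaxSn),
               c(1L, 2L, 3L, 4L))
  thMeanSn <- pvi_thresholds("MeanSn")
  expect_equal(score_pvi(c(0.18, 0.2, 0.21, 0.22), thMeanSn),
               c(1L, 2L, 3L, 4L))
})

test_that("scoring is monotone in the measurement", {
  thC <- pvi_thresholds("C")
  v <- sort(runif(200, 0.05, 1.9))
  expect_true(all(diff(score_pvi(v, thC)) <= 0))
  thS <- pvi_thresholds("MeanS")
  v <- sort(runif(200, 10, 150))
  expect_true(all(diff(score_pvi(v, thS)) >= 0))
})

test_that("delta and binary outcome follow the change definition", {
  db <- delta_binary(c(2L, 3L, 4L), c(3L, 3L, 1L))
  expect_equal(db$delta, c(1L, 0L, -3L))
  expect_equal(db$binary, c(1L, -1L, -1L))
  expect_error(delta_binary(0L, 2L))
})

test_that("calibration separates rank-aligned labels perfectly", {
  set.seed(12)
  lab <- sample(1:4, 80, replace = TRUE)
  val <- lab * 10 + runif(80, -4, 4)
  th <- calibrate_thresholds(val, lab, "MeanS")
  expect_equal(attr(th, "match_rate"), 1)
  expect_equal(score_pvi(val, th), lab)
  # round trip: re-scoring reproduces the reported match rate
  expect_equal(mean(score_pvi(val, th) == lab), attr(th, "match_rate"))
})

test_that("calibration on shuffled labels approaches the mode frequency", {
  set.seed(13)
  lab <- sample(1:4, 120, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  val <- runif(120)
  rates <- vapply(1:5, function(i) {
    attr(calibrate_thresholds(val, sample(lab), "MaxS"), "match_rate")
  }, 0)
  mode_freq <- max(table(lab)) / length(lab)
  # optimised cuts track the mode frequency; midpoint cuts cannot force
  # every slice into one category, so allow a few inevitable misses
  expect_true(all(rates >= mode_freq - 0.05))
  expect_lt(mean(rates), mode_freq + 0.15)
})

test_that("calibration equals a dense-grid brute-force oracle (n <= 50)", {
  # independent enumeration: every ordered triple of candidate cuts drawn
  # from the observed values (plus one below the minimum), scored directly
  brute_force_rate <- function(values, labels) {
    cand <- c(min(values) - 0.05, sort(unique(values)))
    nc <- length(cand)
    best <- 0
    for (a in 1:(nc - 2)) {
      for (b in (a + 1):(nc - 1)) {
        for (cc in (b + 1):nc) {
          pred <- 1L + findInterval(values, cand[c(a, b, cc)],
                                    left.open = TRUE)
          best <- max(best, mean(pred == labels))
        }
      }
    }
    best
  }
  set.seed(14)
  for (rep_i in 1:3) {
    n <- sample(20:50, 1)
    lab <- sample(1:4, n, replace = TRUE)
    val <- lab * 2 + rnorm(n, 0, 1.5)
    th <- calibrate_thresholds(val, lab, "MaxSn")
    expect_equal(attr(th, "match_rate"), brute_force_rate(val, lab),
                 tolerance = 1e-12)
  }
})

test_that("calibrated cuts beat the fixed published cuts on the same data", {
  set.seed(15)
  lab <- sample(1:4, 100, replace = TRUE)
  val <- 60 + lab * 12 + rnorm(100, 0, 6)   # kPa-like scale
  th_cal <- calibrate_thresholds(val, lab, "MaxS")
  rate_cal <- mean(score_pvi(val, th_cal) == lab)
  rate_fixed <- mean(score_pvi(val, pvi_thresholds("MaxS")) == lab)
  expect_gte(rate_cal, rate_fixed)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibrate_thresholds(rep(1, 10), rep(2L, 10), "MaxS"),
               "2 C-PVI categories")
  expect_error(calibrate_thresholds(rep(1, 10), rep(1:2, 5), "MaxS"),
               "identical")
})
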