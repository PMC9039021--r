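# Independent enumeration oracle for P(X >= m), X ~ Binomial(k, f),
# built from the binomial mass written out with choose().
enum_tail <- function(k, f, m) {
  if (m > k) return(0)
  x <- m:k
  sum(choose(k, x) * f^x * (1 - f)^(k - x))
}

test_that("capture probability has the right closed forms and edges", {
  expect_equal(capture_probability(10, 0), 0)
  expect_equal(capture_probability(5, 1), 1)
  expect_equal(capture_probability(0, 0.5), 0)
  expect_equal(capture_probability(10, 0.1), 1 - 0.9^10)
  expect_equal(capture_probability(10, 0.1, min_mutant = 0), 1)
  expect_error(capture_probability(10, 0.1, min_mutant = -1), "min_mutant")
})

test_that("exact mode matches exhaustive enumeration over small k", {
  for (k in c(1, 3, 7, 15, 30))
    for (f in seq(0.05, 0.95, by = 0.15))
      for (m in c(1, 2, min(k, 5)))
        expect_equal(capture_probability(k, f, m, method = "exact"),
                     enum_tail(k, f, m), tolerance = 1e-12)
})

test_that("capture probability is monotone in copies and in mutant fraction", {
  ks <- c(1, 2, 5, 10, 20, 50, 150, 400)
  p_k <- vapply(ks, capture_probability, numeric(1), vaf_f = 0.1)
  expect_true(all(diff(p_k) >= 0))
  fs <- seq(0, 1, by = 0.1)
  p_f <- vapply(fs, function(f) capture_probability(30, f), numeric(1))
  expect_true(all(diff(p_f) >= 0))
})

test_that("Gaussian tail with continuity correction tracks the exact binomial", {
  # at 100 copies the normal regime applies; with the expected mutant
  # count at 10 or more (f >= 0.1 for one captured copy) the absolute
  # error is far below 0.01, and stays below 0.015 even at the skewed
  # f = 0.05 edge; away from the tails it is bounded by the Berry-Esseen
  # style worst case of a few percent
  for (f in seq(0.1, 0.95, by = 0.05)) {
    d <- abs(capture_probability(100, f, 1, method = "normal") -
               capture_probability(100, f, 1, method = "exact"))
    expect_lt(d, 0.01)
  }
  d_edge <- abs(capture_probability(100, 0.05, 1, method = "normal") -
                  capture_probability(100, 0.05, 1, method = "exact"))
  expect_lt(d_edge, 0.015)
  # across all thresholds m the worst-case error stays below 3%
  worst <- max(vapply(seq(0.05, 0.95, by = 0.05), function(f) {
    max(vapply(1:100, function(m)
      abs(capture_probability(100, f, m, method = "normal") -
            capture_probability(100, f, m, method = "exact")),
      numeric(1)))
  }, numeric(1)))
  expect_lt(worst, 0.03)
  # auto switches to the approximation from 100 copies on
  expect_equal(capture_probability(99, 0.3),
               capture_probability(99, 0.3, method = "exact"))
  expect_equal(capture_probability(100, 0.3),
               capture_probability(100, 0.3, method = "normal"))
})

test_that("minimum input for detection inverts the capture probability", {
  expect_equal(min_input_for_detection(1, 0.99), 1L)
  # brute-force oracle: smallest k with 1 - 0.9^k >= 0.95
  oracle <- which(1 - 0.9^(1:200) >= 0.95)[1]
  expect_equal(min_input_for_detection(0.1, 0.95), as.integer(oracle))
  expect_equal(oracle, 29L)
  # non-increasing in the mutant fraction
  fs <- c(0.05, 0.1, 0.2, 0.5, 1)
  k_needed <- vapply(fs, min_input_for_detection, integer(1),
                     target_prob = 0.95)
  expect_true(all(diff(k_needed) <= 0))
  expect_error(min_input_for_detection(0, 0.95), "zero mutant fraction")
})

test_that("droplet-count distribution propagates sampling through the model", {
  m <- preamp_model(1574 / 65)
  # no mutant fraction: point mass at zero
  none <- expected_positive_droplets_after_preamp(65, 0, m)
  expect_equal(none$mean, 0)
  expect_equal(none$p_positive_call, 0)
  # pure mutant template: point mass at the calibration output
  all_mut <- expected_positive_droplets_after_preamp(65, 1, m)
  expect_equal(all_mut$mean, 1574)
  expect_equal(all_mut$p_positive_call, 1)
  # low-VAF regime: cross-check mean and call probability against the
  # enumeration oracle
  res <- expected_positive_droplets_after_preamp(65, 0.14, m)
  x <- 0:65
  px <- choose(65, x) * 0.14^x * 0.86^(65 - x)
  droplets <- ifelse(x >= 0, round(1574 / 65 * x), 0)
  expect_equal(res$mean, sum(px * droplets), tolerance = 1e-12)
  expect_equal(res$p_positive_call, sum(px[droplets >= 50]),
               tolerance = 1e-12)
  # with ~9 expected mutant copies each worth ~24 droplets, a positive
  # call is near-certain but not guaranteed
  expect_gt(res$p_positive_call, 0.99)
  expect_lt(res$p_positive_call, 1)
})
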