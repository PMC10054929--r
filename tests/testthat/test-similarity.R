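test_that("signal correlation bins, concatenates and matches direct Pearson", {
  set.seed(1)
  a <- matrix(stats::rnorm(2 * 100), 2, 100)   # 2 trials x 100 samples
  expect_equal(signal_correlation(a, a, sampling_rate_hz = 10), 1)
  expect_equal(signal_correlation(a, -a, sampling_rate_hz = 10), -1)
  b <- matrix(stats::rnorm(2 * 100), 2, 100)
  got <- signal_correlation(a, b, sampling_rate_hz = 10, bin_ms = 500)
  # independent recomputation: 5 samples per bin, trials concatenated
  bin5 <- function(m) as.numeric(apply(m, 1, function(r)
    colMeans(matrix(r, 5))))
  expect_equal(got, stats::cor(bin5(a), bin5(b)))
  expect_true(is.na(signal_correlation(matrix(1, 1, 100), a[1, , drop = FALSE],
                                       sampling_rate_hz = 10)))
})

test_that("CCmax is one for identical trials and tracks the analytic ceiling", {
  sig <- sin(seq(0, 6 * pi, length.out = 120))
  trials <- matrix(rep(sig, 5), 5, byrow = TRUE)
  expect_equal(cc_max(trials), 1)
  # planted variance components: the estimator's expectation carries the
  # finite-N factor N/(N-1) on top of sqrt(s2 / (s2 + n2 / N))
  set.seed(2)
  N <- 10; Tn <- 300
  est <- replicate(150, {
    s <- stats::rnorm(Tn)
    cc_max(matrix(rep(s, N), N, byrow = TRUE) +
             matrix(stats::rnorm(N * Tn), N))
  })
  pred <- sqrt(min(1, (N / (N - 1)) / (1 + 1 / N)))
  expect_equal(mean(est), pred, tolerance = 0.03)
  # pure noise with many trials: near zero on average
  noise_est <- replicate(150, cc_max(matrix(stats::rnorm(40 * 100), 40)))
  expect_lt(mean(noise_est), 0.2)
  expect_error(cc_max(matrix(1, 1, 10)), "2 trials")
})

test_that("CCabs is the prediction-response Pearson with guarded edge cases", {
  set.seed(3)
  x <- stats::rnorm(50); y <- stats::rnorm(50)
  expect_equal(cc_abs(x, x), 1)
  expect_equal(cc_abs(x, y), stats::cor(x, y))
  expect_true(is.na(cc_abs(rep(1, 50), y)))
  trials <- rbind(y + stats::rnorm(50), y + stats::rnorm(50))
  expect_equal(cc_abs(x, trials), stats::cor(x, colMeans(trials)))
})

test_that("feature similarity is the cosine with scale invariance", {
  w <- c(1, 2, 3)
  expect_equal(feature_similarity(w, w), 1)
  expect_equal(feature_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(feature_similarity(w, -w), -1)
  set.seed(4)
  a <- stats::rnorm(16); b <- stats::rnorm(16)
  expect_equal(feature_similarity(a, b), feature_similarity(3.7 * a, b))
  expect_error(feature_similarity(a, rep(0, 16)), "zero")
  expect_error(feature_similarity(a, stats::rnorm(8)), "dimension")
})

test_that("RF center distance is the eye-ray angle and a metric", {
  expect_equal(rf_center_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(rf_center_distance(c(0, 0), c(15, 0)), 45)  # arctan(15/15)
  set.seed(5)
  pts <- matrix(stats::runif(30, -20, 20), ncol = 2)
  ang <- function(p, q) {   # vector-algebra oracle
    u <- c(p, 15); v <- c(q, 15)
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  for (i in 1:5) {
    p <- pts[3 * i - 2, ]; q <- pts[3 * i - 1, ]; r <- pts[3 * i, ]
    expect_equal(rf_center_distance(p, q), ang(p, q), tolerance = 1e-10)
    expect_equal(rf_center_distance(p, q), rf_center_distance(q, p))
    expect_lte(rf_center_distance(p, r),
               rf_center_distance(p, q) + rf_center_distance(q, r) + 1e-9)
  }
})

test_that("orientation difference wraps on the 180-degree circle", {
  expect_equal(delta_orientation(10, 10), 0)
  expect_equal(delta_orientation(5, 175), 10)
  expect_equal(delta_orientation(0, 90), 90)
  expect_equal(delta_orientation(179, 1), 2)
})
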