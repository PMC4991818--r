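test_that("self- and anti-correlation give +1 and -1 at zero lag", {
  set.seed(1)
  x <- abs(rnorm(600)) + 0.5
  p <- stwc_params(200, 100)
  m_self <- stwc_single_trial(x, x, 400, p)
  zero <- which(m_self$lag_ms == 0)
  expect_true(all(abs(m_self$values[, zero] - 1) < 1e-12))
  m_anti <- stwc_single_trial(x, -x, 400, p)
  expect_true(all(abs(m_anti$values[, zero] + 1) < 1e-12))
  expect_true(all(m_self$values >= -1 & m_self$values <= 1))
})

test_that("a delayed copy peaks at its delay for every time row", {
  set.seed(2)
  n <- 800
  x <- abs(rnorm(n)) + 0.5
  k <- 16L
  y <- c(rep(0.5, k), x[1:(n - k)])
  m <- stwc_single_trial(x, y, 400, stwc_params(200, 100))
  best_lag <- m$lag_ms[apply(m$values, 1, which.max)]
  expect_true(all(best_lag == k / 400 * 1000))
})

test_that("kernel matches a naive double-loop correlation oracle", {
  set.seed(3)
  rate <- 400
  x <- abs(rnorm(rate)) * 2 + 1    # 1 s envelopes
  y <- abs(rnorm(rate)) * 2 + 1
  p <- stwc_params(200, 100)
  m <- stwc_single_trial(x, y, rate, p)
  half <- 40L; maxlag <- 40L
  worst <- 0
  for (it in seq_along(m$time_s)) {
    t <- round(m$time_s[it] * rate) + 1L
    for (ld in seq_along(m$lag_ms)) {
      d <- as.integer(round(m$lag_ms[ld] / 1000 * rate))
      r <- stats::cor(x[(t - half):(t + half)], y[(t + d - half):(t + d + half)])
      worst <- max(worst, abs(m$values[it, ld] - r))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("zero-variance windows are missing, never infinite", {
  x <- c(rep(1, 300), abs(rnorm(300)) + 1)
  y <- abs(rnorm(600)) + 1
  m <- stwc_single_trial(x, y, 400, stwc_params(200, 100))
  expect_true(anyNA(m$values))
  expect_false(any(is.infinite(m$values)))
})

test_that("map averaging is an entrywise mean that ignores missing entries", {
  set.seed(4)
  x <- abs(rnorm(600)) + 0.5; y <- abs(rnorm(600)) + 0.5
  p <- stwc_params(200, 100)
  m <- stwc_single_trial(x, y, 400, p)
  same <- average_stwc(list(m, m, m))
  expect_equal(same$values, m$values)
  expect_equal(same$n_trials, 3L)

  neg <- m; neg$values <- -m$values
  zero <- average_stwc(list(m, neg))
  expect_true(all(abs(zero$values) < 1e-12))

  holes <- m; holes$values[1, 1] <- NA
  avg <- average_stwc(list(m, holes))
  expect_equal(avg$values[1, 1], m$values[1, 1])   # NA ignored, not zeroed

  expect_error(average_stwc(list()), class = "ecog_config_error")
})

test_that("averaging independent noise maps shrinks the peak like 1/sqrt(N)", {
  set.seed(5)
  p <- stwc_params(200, 100)
  singles <- replicate(50, {
    stwc_single_trial(abs(rnorm(500)) + 0.5, abs(rnorm(500)) + 0.5, 400, p)
  }, simplify = FALSE)
  avg <- average_stwc(singles)
  ratio <- max(abs(avg$values)) /
    mean(vapply(singles, function(m) max(abs(m$values)), numeric(1)))
  expect_lt(ratio, 3 / sqrt(50))
  expect_gt(ratio, 0.3 / sqrt(50))
})

test_that("peak extraction honors the analysis window and tie-breaks", {
  vals <- matrix(0, 5, 5)
  vals[1, 3] <- 0.9       # outside the window below
  vals[4, 5] <- 0.6       # inside
  m <- make_stwc_map(vals, time_s = seq(0, 0.4, 0.1),
                     lag_ms = c(-100, -50, 0, 50, 100))
  pk <- extract_peak(m, c(0.25, 0.45))
  expect_equal(pk$coef, 0.6)
  expect_equal(pk$lag_ms, 100)
  expect_equal(pk$t_s, 0.3)

  # ties: smallest |lag| wins, then the negative lag
  tie <- matrix(0, 1, 5)
  tie[1, c(1, 2, 4, 5)] <- 0.7
  mt <- make_stwc_map(tie, 0, c(-100, -50, 50, 100))
  expect_equal(extract_peak(mt, c(-1, 1))$lag_ms, -50)

  expect_error(extract_peak(m, c(10, 11)), class = "ecog_config_error")
  allna <- make_stwc_map(matrix(NA_real_, 2, 3), c(0, 0.1), c(-50, 0, 50))
  expect_error(extract_peak(allna, c(-1, 1)), class = "ecog_config_error")
})

test_that("pair-map averaging agrees with the list-of-maps route", {
  set.seed(6)
  xs <- matrix(abs(rnorm(500 * 4)) + 0.5, 500)
  ys <- matrix(abs(rnorm(500 * 4)) + 0.5, 500)
  p <- stwc_params(200, 100)
  a <- stwc_pair_map(xs, ys, 400, p, zero_s = -0.6)
  b <- average_stwc(lapply(1:4, function(j) {
    stwc_single_trial(xs[, j], ys[, j], 400, p, zero_s = -0.6)
  }))
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_equal(a$time_s, b$time_s)
})

test_that("tidy and glance expose the map contents", {
  set.seed(7)
  m <- stwc_single_trial(abs(rnorm(500)) + 0.5, abs(rnorm(500)) + 0.5,
                         400, stwc_params(200, 100))
  td <- tidy(m)
  expect_tibble_cols(td, c("time_s", "lag_ms", "coef"))
  expect_equal(nrow(td), length(m$time_s) * length(m$lag_ms))
  gl <- glance(m)
  expect_equal(gl$peak_coef, max(m$values, na.rm = TRUE))
  expect_s3_class(autoplot(m), "ggplot")
})
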