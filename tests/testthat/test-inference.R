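test_that("phase randomization preserves the spectrum and autocorrelation", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = 0.8), 512))
  spec_in <- Mod(stats::fft(x))
  set.seed(2)
  y <- phase_randomize(x)
  expect_lt(max(abs(Mod(stats::fft(y)) - spec_in)) / max(spec_in), 1e-10)
  expect_true(all(abs(Im(stats::fft(stats::fft(y), inverse = TRUE) / 512)
                      ) < 1e-9))

  # circular autocorrelation is preserved exactly (Wiener-Khinchin);
  # the linear sample acf agrees closely
  circ <- function(v) Re(stats::fft(Mod(stats::fft(v))^2, inverse = TRUE))
  expect_lt(max(abs(circ(x) - circ(y))) / max(abs(circ(x))), 1e-10)
  acf_in <- stats::acf(x, lag.max = 20, plot = FALSE, demean = FALSE)$acf
  acf_out <- stats::acf(y, lag.max = 20, plot = FALSE, demean = FALSE)$acf
  expect_lt(max(abs(acf_in - acf_out)), 0.05)

  set.seed(3)
  rs <- vapply(1:200, function(i) stats::cor(x, phase_randomize(x)),
               numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("STWC significance uses the +1 convention and a strict threshold", {
  null <- structure(list(samples = seq(0.01, 1, length.out = 100),
                         n_resamples = 100L, scope = "max",
                         statistic = "stwc_peak"),
                    class = "null_distribution")
  peaks <- tibble::tibble(coef = c(0.001, 1.5,
                                   stats::quantile(null$samples, 0.95,
                                                   names = FALSE)))
  out <- stwc_significance(peaks, null)
  expect_gt(out$p[1], 0.99)
  expect_equal(out$p[2], 1 / 101)
  expect_true(out$significant[2])
  expect_false(out$significant[3])   # at the percentile, not above it
  expect_true(all(out$p > 0 & out$p <= 1))
})

test_that("surrogate null flags injected coupling and warns on tiny n_iter", {
  set.seed(4)
  ntr <- 8
  n <- 500
  xs <- matrix(abs(rnorm(n * ntr)) + 0.5, n)
  ys_noise <- matrix(abs(rnorm(n * ntr)) + 0.5, n)
  ys_copy <- xs + 0.01 * matrix(rnorm(n * ntr), n)
  p <- stwc_params(200, 100)
  win <- c(0.35, 0.9)
  null <- stwc_null(xs, list(a = ys_copy, b = ys_noise), 400, p, win,
                    n_iter = 60, seed = 5)
  obs <- extract_peak(stwc_pair_map(xs, ys_copy, 400, p), win)
  res <- stwc_significance(obs, null)
  expect_equal(res$p, 1 / (1 + null$n_resamples))
  expect_true(res$significant)

  expect_warning(stwc_null(xs, list(a = ys_noise), 400, p, win, n_iter = 5,
                           seed = 6),
                 "unstable")
})

test_that("the null tail is stable in the number of iterations", {
  set.seed(7)
  ntr <- 8; n <- 500
  xs <- matrix(abs(rnorm(n * ntr)) + 0.5, n)
  ys <- matrix(abs(rnorm(n * ntr)) + 0.5, n)
  p <- stwc_params(200, 100)
  win <- c(0.35, 0.9)
  q1 <- stats::quantile(stwc_null(xs, list(a = ys), 400, p, win,
                                  n_iter = 100, scope = "pooled",
                                  seed = 8)$samples, 0.95)
  q2 <- stats::quantile(stwc_null(xs, list(a = ys), 400, p, win,
                                  n_iter = 200, scope = "pooled",
                                  seed = 9)$samples, 0.95)
  expect_lt(abs(q2 - q1) / q1, 0.05)
})

test_that("bPLV trial shuffling excludes the identity and flags coupling", {
  nt <- 40; ntr <- 12
  src <- uniform_phase_tensor(7:125, nt, ntr, seed = 10)
  tgt <- uniform_phase_tensor(77:125, nt, ntr, seed = 11)
  i1 <- match(10, src$freqs); i2 <- match(80, src$freqs)
  i3 <- match(90, tgt$freqs)
  tgt$phases[i3, , ] <- -(src$phases[i1, , ] + src$phases[i2, , ])
  out <- bplv_null(src, tgt, t0 = 0, t1 = 0.1, n_resamples = 500,
                   n_pairs = 3, seed = 12)
  # identity offset excluded: no null sample reaches the coherent maximum
  expect_lt(max(out$null$samples), max(out$observed$values))
  expect_equal(out$p, 1 / 501)
  expect_lt(out$p_corrected, 0.05)
  expect_true(out$significant)
  expect_equal(dim(out$p_grid), c(19, 31))

  expect_error(bplv_null(uniform_phase_tensor(7:125, 5, 3, 1),
                         uniform_phase_tensor(77:125, 5, 3, 2),
                         n_resamples = 10),
               class = "ecog_inference_error")
})

test_that("chance performance bounds match exact binomial quantiles", {
  ci <- chance_performance_ci(100, seed = 13)
  expect_equal(ci$point, 0.5)
  expect_lte(abs(ci$lo - stats::qbinom(0.025, 100, 0.5) / 100), 0.02)
  expect_lte(abs(ci$hi - stats::qbinom(0.975, 100, 0.5) / 100), 0.02)

  wide <- chance_performance_ci(10000, seed = 14)
  expect_lt(wide$hi - wide$lo, 0.02)
})

test_that("early/late comparison handles ties, power and degenerate input", {
  same <- tibble::tibble(subject = rep(paste0("S", 1:4), each = 4),
                         half = rep(c("early", "late"), 8),
                         value = rep(c(0.5, 0.5), 8))
  out <- early_late_comparison(same)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)

  single <- tibble::tibble(subject = "S1", half = c("early", "late"),
                           value = c(1, 0.5))
  expect_error(early_late_comparison(single), class = "ecog_inference_error")

  # simulated decay across 9 subjects: one-sided p < 0.05 in >= 80% of runs
  set.seed(15)
  hits <- vapply(1:25, function(run) {
    res <- purrr::map_dfr(1:9, function(s) {
      tibble::tibble(subject = paste0("S", s),
                     half = rep(c("early", "late"), each = 4),
                     value = c(1.0 + rnorm(4, 0, 0.15),
                               0.5 + rnorm(4, 0, 0.15)))
    })
    early_late_comparison(res, alternative = "greater")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("SNR control flags electrodes whose activation collapses", {
  rate <- 100
  d <- c(rest = 1, targeting = 1, feedback = 2, reward = 1)
  ntr <- 16
  trial_s <- sum(d)
  start <- (seq_len(ntr) - 1) * trial_s
  trials <- tibble::tibble(
    trial = seq_len(ntr), target = "up", outcome = "hit",
    rest_on = start, targeting_on = start + 1, feedback_on = start + 2,
    reward_on = start + 4, end_s = start + 5, cue_time = start + 2)
  n <- ntr * trial_s * rate
  set.seed(16)
  flat <- abs(rnorm(n)) + 1
  early_only <- flat
  steady <- flat
  for (j in seq_len(ntr)) {
    idx <- (start[j] + 2) * rate + seq_len(2 * rate)
    steady[idx] <- steady[idx] + 3
    if (j <= ntr / 2) early_only[idx] <- early_only[idx] + 3
  }
  env <- ecog_envelope(rbind(flat, steady, early_only), c(70, 150), rate,
                       labels = c("none", "steady", "fading"))
  out <- snr_control(env, trials)
  expect_lt(abs(out$snr_early[out$electrode == "none"]), 1)
  expect_gt(out$snr_early[out$electrode == "steady"],
            out$snr_early[out$electrode == "none"])
  expect_false(out$flagged[out$electrode == "steady"])
  expect_true(out$flagged[out$electrode == "fading"])
})

test_that("distance comparison reduces to per-subject medians", {
  montage <- tibble::tibble(
    name = c("ctl", "near", "far"),
    x_mm = c(0, 3, 30), y_mm = c(0, 4, 40), z_mm = 0,
    region = "M1", good = TRUE, is_ctl = c(TRUE, FALSE, FALSE))
  expect_equal(electrode_distance(montage, "ctl", "near"), 5)

  mk <- function(remote) {
    tibble::tibble(subject = paste0("S", 1:4), ctl = "ctl", remote = remote)
  }
  same <- distance_comparison(mk("near"), mk("near"), montage)
  expect_equal(same$p, 1)

  ordered <- distance_comparison(mk("near"), mk("far"), montage)
  expect_lt(ordered$mean_stwc_mm, ordered$mean_bplv_mm)
})
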