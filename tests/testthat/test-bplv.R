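test_that("wavelet phase advances at the oscillation frequency", {
  rate <- 400
  tt <- seq(0, 6 - 1 / rate, by = 1 / rate)
  x <- cos(2 * pi * 80 * tt)
  ph <- wavelet_phase(matrix(x, ncol = 1), rate, 80)
  mid <- 400:2000
  dphi <- diff(ph$phases[1, mid, 1])
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap increments
  expect_lt(abs(mean(dphi) - 2 * pi * 80 / rate) / (2 * pi * 80 / rate), 0.01)

  # a fixed pi/2 offset between two sinusoids is recovered
  y <- cos(2 * pi * 80 * tt - pi / 2)
  phy <- wavelet_phase(matrix(y, ncol = 1), rate, 80)
  dd <- ph$phases[1, mid, 1] - phy$phases[1, mid, 1]
  dd <- (dd + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dd - pi / 2)), 0.05)

  expect_error(wavelet_phase(matrix(x, ncol = 1), rate, 200),
               class = "ecog_config_error")
})

test_that("wavelet amplitude ridge tracks a chirp within 2 Hz", {
  rate <- 400
  tt <- seq(0, 5 - 1 / rate, by = 1 / rate)
  f_inst <- 70 + (100 - 70) * tt / max(tt)
  x <- cos(2 * pi * cumsum(f_inst) / rate)
  wt <- wavelet_phase(matrix(x, ncol = 1), rate, 60:110,
                      return_amplitude = TRUE)
  probe <- seq(400, 1600, by = 200)
  ridge <- vapply(probe, function(i) {
    wt$freqs[which.max(wt$amplitude[, i, 1])]
  }, numeric(1))
  expect_true(all(abs(ridge - f_inst[probe]) <= 2))
})

test_that("bPLV is the unit-vector magnitude of the triple phase sum", {
  # N = 1: B is identically 1
  t1 <- uniform_phase_tensor(7:125, 20, 1, seed = 1)
  m1 <- bplv_map(t1, t1)
  expect_true(all(abs(m1$values - 1) < 1e-12))
  expect_equal(dim(m1$values), c(19, 31, 20))

  # constant triple sum across trials: B = 1 at the matching grid point
  nt <- 10; ntr <- 30
  src <- uniform_phase_tensor(7:125, nt, ntr, seed = 2)
  tgt <- uniform_phase_tensor(77:125, nt, ntr, seed = 3)
  i1 <- match(10, src$freqs); i2 <- match(80, src$freqs)
  i3 <- match(90, tgt$freqs)
  tgt$phases[i3, , ] <- -(src$phases[i1, , ] + src$phases[i2, , ]) + 1.3
  m <- bplv_map(src, tgt)
  expect_true(all(abs(m$values[match(10, m$f1), match(80, m$f2), ] - 1) < 1e-9))
  # B is invariant under adding a common constant to the triple sums
  tgt2 <- tgt; tgt2$phases[i3, , ] <- tgt$phases[i3, , ] + 0.7
  m2 <- bplv_map(src, tgt2)
  expect_equal(m2$values[match(10, m$f1), match(80, m$f2), ],
               m$values[match(10, m$f1), match(80, m$f2), ])
  expect_true(all(m$values >= 0 & m$values <= 1 + 1e-12))
})

test_that("uncoupled bPLV sits at the Rayleigh resultant level", {
  n_mc <- 200
  src <- uniform_phase_tensor(7:125, 25, n_mc, seed = 4)
  tgt <- uniform_phase_tensor(77:125, 25, n_mc, seed = 5)
  m <- bplv_map(src, tgt)
  expected <- sqrt(pi) / (2 * sqrt(n_mc))
  expect_lt(abs(mean(m$values) - expected) / expected, 0.2)
})

test_that("time integration is a mean over the half-open interval", {
  vals <- array(0, c(2, 3, 10))
  vals[, , 1:5] <- 1
  m <- structure(list(values = vals, f1 = 7:8, f2 = 70:72,
                      time_s = seq(0, 0.9, 0.1), n_trials = 5L),
                 class = "bplv_map")
  g <- integrate_bplv(m, 0, 1)
  expect_true(all(g$values == 0.5))
  g2 <- integrate_bplv(m, 0, 0.5)
  expect_true(all(g2$values == 1))
  expect_error(integrate_bplv(m, 5, 6), class = "ecog_config_error")
  expect_tibble_cols(tidy(g), c("f1", "f2", "value"))
  expect_equal(nrow(tidy(g)), 6)
})

test_that("injected quadratic coupling is the argmax of the integrated grid", {
  fx <- phase_fixture()
  g <- integrate_bplv(bplv_map(fx$src, fx$tgt), 0, 1)
  am <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_equal(g$f1[am[1]], 10)
  expect_equal(g$f2[am[2]], 80)
})

test_that("pseudo-z normalization standardizes the baseline", {
  set.seed(6)
  vals <- array(abs(rnorm(2 * 2 * 100, 0.3, 0.05)), c(2, 2, 100))
  tax <- seq(-3, 2 - 0.05, by = 0.05)
  m <- structure(list(values = vals, f1 = 7:8, f2 = 70:71,
                      time_s = tax, n_trials = 10L),
                 class = "bplv_map")
  z <- normalize_pseudo_z(m)
  base <- tax >= -3 & tax < 0
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(mean(z$values[i, j, base])), 1e-12)
    expect_equal(sd(z$values[i, j, base]), 1)
  }
  # location invariance
  m_shift <- m; m_shift$values <- m$values + 5
  z2 <- normalize_pseudo_z(m_shift)
  expect_equal(z2$values, z$values)
  # the output is not confined to [0, 1]
  expect_gt(max(z$values), 1)

  flat <- m; flat$values[] <- 0.5
  expect_error(normalize_pseudo_z(flat), class = "ecog_inference_error")
})

test_that("grand averaging returns mean and 1-SEM band", {
  tax <- seq(0, 1, 0.1)
  a <- sin(tax)
  g_same <- grand_average(list(a, a, a), tax)
  expect_equal(g_same$mean, a)
  expect_true(all(g_same$hi - g_same$lo < 1e-12))

  g_opp <- grand_average(list(a, -a), tax)
  expect_true(all(abs(g_opp$mean) < 1e-12))

  expect_error(grand_average(list(a), tax), class = "ecog_config_error")
  expect_error(grand_average(list(a, a[-1]), tax), class = "ecog_config_error")

  # an injected group effect exceeds the baseline band
  set.seed(7)
  tax2 <- seq(-1, 1.5, 0.05)
  subj <- lapply(1:8, function(i) {
    rnorm(length(tax2), 0, 0.3) + ifelse(tax2 >= 0.5 & tax2 < 1, 2, 0)
  })
  g <- grand_average(subj, tax2)
  eff <- tax2 >= 0.5 & tax2 < 1
  expect_gt(min(g$lo[eff]), max(g$hi[tax2 < 0]))
})

test_that("linear PLV detects within-frequency locking only where present", {
  t1 <- uniform_phase_tensor(1:50, 30, 40, seed = 8)
  same <- linear_plv(t1, t1)
  expect_true(all(abs(same$values - 1) < 1e-12))

  t2 <- uniform_phase_tensor(1:50, 30, 40, seed = 9)
  # lock frequency 25 with a fixed offset; leave the rest independent
  t2$phases[25, , ] <- t1$phases[25, , ] + 0.9
  plv <- linear_plv(t1, t2)
  sp <- tidy(plv)
  expect_gt(sp$plv[sp$freq_hz == 25], 0.99)
  expect_lt(max(sp$plv[sp$freq_hz != 25]), 0.5)

  # independent channels: time-averaged PLV near the Rayleigh level
  big1 <- uniform_phase_tensor(1:10, 40, 200, seed = 10)
  big2 <- uniform_phase_tensor(1:10, 40, 200, seed = 11)
  lev <- mean(linear_plv(big1, big2)$values)
  expect_lt(abs(lev - sqrt(pi) / (2 * sqrt(200))) / (sqrt(pi) / (2 * sqrt(200))),
            0.2)
})
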