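fit_loglog_slope <- function(x, rate, fmin = 1, fmax = 150) {
  ps <- stats::spec.pgram(x, taper = 0, plot = FALSE, fast = FALSE)
  f <- ps$freq * rate
  keep <- f >= fmin & f <= fmax
  unname(stats::coef(stats::lm(log(ps$spec[keep]) ~ log(f[keep])))[2])
}

test_that("background spectral slope tracks the configured exponent", {
  white <- generate_background(sim_config(n_channels = 1, n_trials = 6,
                                          noise_exponent = 0,
                                          line_amplitude = 0, seed = 5))
  expect_lt(abs(fit_loglog_slope(white$data[1, ], white$rate)), 0.1)

  pink <- generate_background(sim_config(n_channels = 1, n_trials = 6,
                                         noise_exponent = 1,
                                         line_amplitude = 0, seed = 5))
  expect_lt(abs(fit_loglog_slope(pink$data[1, ], pink$rate) - (-1)), 0.2)
})

test_that("generation is deterministic under the seed and covers the trials", {
  cfg <- sim_config(n_channels = 3, n_trials = 10, seed = 9)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$data, b$data)
  # 10 trials x (1 + 2 + 3 + 1) s = 70 s
  expect_equal(ncol(a$data) / a$rate, 70)

  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$trials, s2$trials)
})

test_that("line contamination dominates the 60 Hz periodogram bin", {
  rec <- generate_background(sim_config(n_channels = 1, n_trials = 4,
                                        line_amplitude = 0.5, seed = 2))
  ps <- stats::spec.pgram(rec$data[1, ], taper = 0, plot = FALSE, fast = FALSE)
  f <- ps$freq * rec$rate
  i60 <- which.min(abs(f - 60))
  neighbors <- ps$spec[c(i60 - 5, i60 - 4, i60 + 4, i60 + 5)]
  expect_gt(ps$spec[i60], 10 * max(neighbors))
})

test_that("trial outcomes follow the hit probability", {
  all_hit <- ecogcoupling:::build_trial_table(
    sim_config(n_trials = 50, hit_probability = 1, seed = 1))
  expect_true(all(all_hit$outcome == "hit"))

  tt <- ecogcoupling:::build_trial_table(
    sim_config(n_trials = 1000, hit_probability = 0.5, seed = 4))
  expect_gte(mean(tt$outcome == "hit"), 0.45)
  expect_lte(mean(tt$outcome == "hit"), 0.55)
  # phases are contiguous and ordered
  expect_true(all(diff(t(as.matrix(tt[, c("rest_on", "targeting_on",
                                          "feedback_on", "reward_on",
                                          "end_s")]))) > 0))
})

test_that("zero-strength amplitude coupling leaves the recording unchanged", {
  cfg <- sim_config(n_channels = 4, n_trials = 4, seed = 13)
  base <- simulate_session(cfg)
  injected <- inject_hg_amplitude_coupling(
    base, amp_coupling_spec("ch1", "ch2", lag_ms = 100, strength = 0))
  expect_identical(base$recording$data, injected$recording$data)
})

test_that("amplitude injection is confined to up-target feedback windows", {
  cfg <- sim_config(n_channels = 4, n_trials = 8, seed = 17,
                    up_probability = 0.5)
  base <- simulate_session(cfg)
  ses <- inject_hg_amplitude_coupling(
    base, amp_coupling_spec("ch1", "ch2", lag_ms = 50, strength = 1))
  rate <- ses$recording$rate
  changed <- which(ses$recording$data[1, ] != base$recording$data[1, ])
  fb <- unlist(lapply(which(ses$trials$target == "up"), function(j) {
    ecogcoupling:::sample_window(ses$trials$feedback_on[j],
                                 ses$trials$reward_on[j], rate)
  }))
  expect_true(all(changed %in% fb))
  # down-target trials and non-feedback phases are bit-identical
  down <- which(ses$trials$target == "down")
  expect_true(length(down) > 0)
  for (j in down) {
    idx <- ecogcoupling:::sample_window(ses$trials$rest_on[j],
                                        ses$trials$end_s[j], rate)
    expect_identical(base$recording$data[, idx], ses$recording$data[, idx])
  }
})

test_that("unknown channels in coupling specs raise lookup errors", {
  ses <- simulate_session(sim_config(n_channels = 2, n_trials = 2, seed = 1))
  expect_error(inject_hg_amplitude_coupling(
    ses, amp_coupling_spec("ch1", "ch99")), class = "ecog_lookup_error")
  expect_error(inject_biphase_coupling(
    ses, phase_coupling_spec("ch99", "ch2")), class = "ecog_lookup_error")
})

test_that("injected envelopes co-modulate at the configured delay", {
  fx <- amp_fixture()
  env <- fx$env
  trials <- fx$session$trials
  rate <- env$rate
  # cross-correlation oracle on the extracted high-gamma envelopes
  xc <- vapply(seq(-40, 40), function(d) {
    mean(vapply(seq_len(nrow(trials)), function(j) {
      idx <- ecogcoupling:::sample_window(trials$feedback_on[j],
                                          trials$reward_on[j], rate)
      x <- env$data[1, idx]; y <- env$data[2, idx]
      nn <- length(x)
      if (d >= 0) stats::cor(x[1:(nn - d)], y[(1 + d):nn])
      else stats::cor(x[(1 - d):nn], y[1:(nn + d)])
    }, numeric(1)))
  }, numeric(1))
  peak_ms <- (which.max(xc) - 41) / rate * 1000
  expect_lte(abs(peak_ms - 50), 2.5)   # one sample at 400 Hz
  expect_gt(max(xc), 0.5)
})

test_that("no envelope coupling during rest phases", {
  # pooled correlation over 100 one-second rest windows; a realistically
  # sized montage keeps the common-average-reference leakage small
  cfg <- sim_config(n_channels = 12, n_trials = 100, sampling_rate = 400,
                    seed = 23, up_probability = 1)
  ses <- simulate_session(
    cfg, amp_specs = amp_coupling_spec("ch1", "ch2", lag_ms = 50,
                                       strength = 1))
  env <- preprocess_envelope(ses$recording)
  idx <- unlist(lapply(seq_len(nrow(ses$trials)), function(j) {
    ecogcoupling:::sample_window(ses$trials$rest_on[j],
                                 ses$trials$targeting_on[j], env$rate)
  }))
  expect_lt(abs(stats::cor(env$data[1, idx], env$data[2, idx])), 0.1)
})

test_that("noiseless phase coupling locks the triple phase sum across trials", {
  fx <- phase_fixture()
  it <- which.min(abs(fx$time_s - 0.5))   # window center
  s <- fx$src$phases[match(10, fx$src$freqs), it, ] +
    fx$src$phases[match(80, fx$src$freqs), it, ] +
    fx$tgt$phases[match(90, fx$tgt$freqs), it, ]
  resultant <- Mod(mean(exp(1i * s)))
  circ_sd <- sqrt(-2 * log(resultant))
  expect_lt(circ_sd, 0.1)
})

test_that("injected source phases are uniform across trials", {
  cfg <- sim_config(n_channels = 3, n_trials = 100, sampling_rate = 400,
                    seed = 29, up_probability = 1)
  ses <- simulate_session(
    cfg, phase_specs = phase_coupling_spec("ch1", "ch2"),
    phase_targets = "all")
  for (col in c("psi1", "psi2")) {
    psi <- ses$truth$psi[[col]]
    rbar <- Mod(mean(exp(1i * psi)))
    p_rayleigh <- exp(-length(psi) * rbar^2)
    expect_gt(p_rayleigh, 0.01)
  }
})

test_that("infinite phase jitter destroys the coupling", {
  cfg <- sim_config(n_channels = 3, n_trials = 10, sampling_rate = 1000,
                    seed = 31, up_probability = 1)
  mk <- function(jit) {
    ses <- simulate_session(
      cfg, phase_specs = phase_coupling_spec("ch1", "ch2", f1 = 10, f2 = 80,
                                             phase_jitter_sd = jit),
      phase_targets = "all")
    broad <- preprocess_broadband(ses$recording)
    tax <- -3 + (seq_len(2200) - 1) / 400
    ex <- epoch_channel(broad, "ch1", ses$trials$feedback_on, c(-3, 2.5))
    ey <- epoch_channel(broad, "ch2", ses$trials$feedback_on, c(-3, 2.5))
    src <- wavelet_phase(ex, 400, c(10, 80), time_s = tax)
    tgt <- wavelet_phase(ey, 400, 90, time_s = tax)
    keep <- tax >= 0 & tax < 1
    mean(Mod(colMeans(exp(1i * (
      t(src$phases[1, keep, ]) + t(src$phases[2, keep, ]) +
        t(tgt$phases[1, keep, ]))))))
  }
  coupled <- mk(0)
  destroyed <- mk(50)
  expect_gt(coupled, 0.8)
  # at the Rayleigh noise floor for N = 10 (sqrt(pi)/(2 sqrt(10)) ~ 0.28)
  expect_lt(destroyed, 0.5)
  expect_lt(destroyed, coupled / 2)
})

test_that("screening block generator marks cues and injects activation", {
  blk <- simulate_screening_block(n_channels = 4, n_reps = 12, rate = 500,
                                  effect_channels = "ch2", effect_size = 1.5,
                                  seed = 7)
  expect_equal(nrow(blk$cues), 12)
  env <- band_envelope(blk$recording)
  act <- ecogcoupling:::sample_window(blk$cues$onset_s[1],
                                      blk$cues$onset_s[1] + 3, 500)
  rest <- ecogcoupling:::sample_window(blk$cues$onset_s[1] + 3,
                                       blk$cues$onset_s[1] + 6, 500)
  expect_gt(mean(env$data[2, act]), mean(env$data[2, rest]) * 1.2)
})
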