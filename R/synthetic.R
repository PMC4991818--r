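#' Configuration for a synthetic BCI session
#'
#' Describes one synthetic ECoG BCI session: montage size, sampling rate,
#' trial count, the four task-phase durations (rest, targeting, feedback,
#' reward), the 1/f^alpha background slope, power-line contamination level,
#' the controlling electrode, the per-trial hit probability, and the seed.
#' With the defaults a trial lasts 1 + 2 + 3 + 1 = 7 s.
#'
#' @param n_channels Number of electrodes.
#' @param sampling_rate Acquisition rate in Hz (>= 400).
#' @param n_trials Number of trials.
#' @param phase_durations Named numeric: seconds for `rest`, `targeting`,
#'   `feedback`, `reward`; all > 0.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param line_amplitude Amplitude of the 60 and 120 Hz line components,
#'   relative to the unit background SD.
#' @param ctl_channel Label of the controlling electrode.
#' @param hit_probability Probability that a trial is a hit, in \[0, 1\].
#' @param up_probability Probability that a trial is an up-target.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   sessions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_channels = 8, sampling_rate = 1000, n_trials = 20,
                       phase_durations = c(rest = 1, targeting = 2,
                                           feedback = 3, reward = 1),
                       noise_exponent = 1, line_amplitude = 0.5,
                       ctl_channel = "ch1", hit_probability = 0.7,
                       up_probability = 0.5, seed = 1) {
  stopifnot_scalar_number(n_channels, "n_channels", lower = 1)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", lower = 400)
  stopifnot_scalar_number(n_trials, "n_trials", lower = 1)
  stopifnot_scalar_number(noise_exponent, "noise_exponent", lower = 0)
  stopifnot_scalar_number(line_amplitude, "line_amplitude", lower = 0)
  stopifnot_scalar_number(hit_probability, "hit_probability", 0, 1)
  stopifnot_scalar_number(up_probability, "up_probability", 0, 1)
  phase_durations <- phase_durations[c("rest", "targeting", "feedback", "reward")]
  if (anyNA(phase_durations) || any(phase_durations <= 0)) {
    abort("`phase_durations` must name positive rest/targeting/feedback/reward",
          class = "ecog_config_error")
  }
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 n_trials = as.integer(n_trials),
                 phase_durations = phase_durations,
                 noise_exponent = noise_exponent,
                 line_amplitude = line_amplitude,
                 ctl_channel = ctl_channel,
                 hit_probability = hit_probability,
                 up_probability = up_probability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth amplitude coupling specification
#'
#' Describes an injected amplitude-amplitude interaction: during the
#' feedback phase of up-target trials, `source` and `target` receive
#' band-limited carriers whose envelopes share a slow stochastic modulator;
#' the target's copy is delayed by `lag_ms` and mixed with an independent
#' modulator at fraction `1 - strength`.
#'
#' @param source,target Channel labels (must differ).
#' @param lag_ms Signed delay of the target envelope in ms, |lag| <= 300.
#'   Positive means the target's activity follows (lags) the source's.
#' @param strength Shared-modulation fraction in \[0, 1\]; 0 disables the
#'   injection entirely.
#' @param band Carrier band in Hz (default high gamma, 70-150).
#' @param amplitude Carrier scale in units of the channel SD.
#' @return An `amp_coupling_spec` list.
#' @export
amp_coupling_spec <- function(source, target, lag_ms = 0, strength = 1,
                              band = c(70, 150), amplitude = 2.5) {
  if (identical(source, target)) {
    abort("`source` and `target` must differ", class = "ecog_config_error")
  }
  stopifnot_scalar_number(lag_ms, "lag_ms", -300, 300)
  stopifnot_scalar_number(strength, "strength", 0, 1)
  stopifnot_scalar_number(amplitude, "amplitude", lower = 0)
  structure(list(source = source, target = target, lag_ms = lag_ms,
                 strength = strength, band = band, amplitude = amplitude),
            class = "amp_coupling_spec")
}

#' Ground-truth quadratic phase coupling specification
#'
#' Describes an injected cross-frequency phase-phase interaction: per trial,
#' independent uniform phases psi1, psi2 are drawn; the source receives
#' cos(2 pi f1 t + psi1) + cos(2 pi f2 t + psi2) and the target receives
#' cos(2 pi (f1+f2) t - (psi1 + psi2) + eps), eps ~ N(0, phase_jitter_sd^2),
#' confined to `window` (seconds relative to feedback onset).  The phase
#' triple sum phi(f1) + phi(f2) + phi(f1+f2) is then constant across trials
#' up to the jitter.
#'
#' @param source,target Channel labels.
#' @param f1 Low source frequency, in \[7, 25\] Hz.
#' @param f2 High source frequency, in \[70, 100\] Hz.
#' @param phase_jitter_sd Jitter SD of the target phase, radians (>= 0).
#' @param window Length-2 numeric, seconds relative to feedback onset.
#' @param amplitude Sinusoid scale in units of the channel SD.
#' @return A `phase_coupling_spec` list.
#' @export
phase_coupling_spec <- function(source, target, f1 = 10, f2 = 80,
                                phase_jitter_sd = 0, window = c(0, 1),
                                amplitude = 4) {
  stopifnot_scalar_number(f1, "f1", 7, 25)
  stopifnot_scalar_number(f2, "f2", 70, 100)
  stopifnot_scalar_number(phase_jitter_sd, "phase_jitter_sd", lower = 0)
  stopifnot_scalar_number(amplitude, "amplitude", lower = 0)
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(start, end) with start < end",
          class = "ecog_config_error")
  }
  structure(list(source = source, target = target, f1 = f1, f2 = f2,
                 phase_jitter_sd = phase_jitter_sd, window = window,
                 amplitude = amplitude),
            class = "phase_coupling_spec")
}

# One channel of 1/f^alpha noise synthesized in the frequency domain with
# Hermitian-symmetric random phases (exact real output, controlled slope),
# scaled to unit SD.
one_over_f_channel <- function(n, rate, alpha) {
  stopifnot(n %% 2 == 0)
  nf <- n / 2
  f <- (1:(nf - 1)) * rate / n
  amp <- f^(-alpha / 2)
  z <- complex(real = rnorm(nf - 1), imaginary = rnorm(nf - 1)) * amp
  nyq <- rnorm(1) * (rate / 2)^(-alpha / 2)
  spec <- c(0, z, nyq, Conj(rev(z)))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate session background activity
#'
#' Each channel is independent 1/f^alpha noise (unit SD) plus sinusoidal
#' 60 and 120 Hz line components at `line_amplitude`, with a random phase
#' per channel.  The recording covers all trials of the configured session.
#'
#' @param config A [sim_config()].
#' @return An [ecog_recording()].
#' @export
generate_background <- function(config) {
  trial_s <- sum(config$phase_durations)
  n <- config$n_trials * trial_s * config$sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    abort("trial duration times sampling rate must be an integer sample count",
          class = "ecog_config_error")
  }
  n <- as.integer(round(n))
  if (n %% 2 == 1) n <- n + 1L
  with_seed(config$seed, {
    tt <- (seq_len(n) - 1) / config$sampling_rate
    data <- matrix(0, config$n_channels, n)
    for (i in seq_len(config$n_channels)) {
      x <- one_over_f_channel(n, config$sampling_rate, config$noise_exponent)
      if (config$line_amplitude > 0) {
        x <- x +
          config$line_amplitude * sin(2 * pi * 60 * tt + runif(1, 0, 2 * pi)) +
          config$line_amplitude * sin(2 * pi * 120 * tt + runif(1, 0, 2 * pi))
      }
      data[i, ] <- x
    }
    ecog_recording(data, config$sampling_rate,
                   labels = paste0("ch", seq_len(config$n_channels)))
  })
}

# Trial table for a session: phase onset times, targets, outcomes.
build_trial_table <- function(config) {
  d <- config$phase_durations
  trial_s <- sum(d)
  start <- (seq_len(config$n_trials) - 1) * trial_s
  with_seed(derive_seed(config$seed, "trials"), {
    target <- ifelse(stats::rbinom(config$n_trials, 1, config$up_probability) == 1,
                     "up", "down")
    outcome <- ifelse(stats::rbinom(config$n_trials, 1, config$hit_probability) == 1,
                      "hit", "miss")
    tibble::tibble(
      trial = seq_len(config$n_trials),
      target = target,
      outcome = outcome,
      rest_on = start,
      targeting_on = start + d[["rest"]],
      feedback_on = start + d[["rest"]] + d[["targeting"]],
      reward_on = start + d[["rest"]] + d[["targeting"]] + d[["feedback"]],
      end_s = start + trial_s,
      cue_time = start + d[["rest"]] + d[["targeting"]],
      onset_time = NA_real_
    )
  })
}

# Electrode montage on a rectangular grid with 10 mm pitch, with coarse
# region labels by grid column (frontal regions nearer the CTL corner).
build_montage <- function(config) {
  n <- config$n_channels
  ncol_grid <- min(8L, n)
  col <- (seq_len(n) - 1L) %% ncol_grid
  row <- (seq_len(n) - 1L) %/% ncol_grid
  regions <- c("M1", "PMv", "PMd", "S1", "PFC", "unknown")
  tibble::tibble(
    name = paste0("ch", seq_len(n)),
    x_mm = col * 10,
    y_mm = row * 10,
    z_mm = 0,
    region = regions[(col %% length(regions)) + 1L],
    good = TRUE,
    is_ctl = paste0("ch", seq_len(n)) == config$ctl_channel
  )
}

# Slow positive stochastic modulator profile on the feedback grid: a
# smooth onset ramp at latency `latency_s` multiplied by low-pass
# (< 8 Hz) positive noise, so the injected co-modulation is slow relative
# to the 500 ms STWC analysis window.
modulator_profile <- function(n, rate, latency_s, noise) {
  tt <- (seq_len(n) - 1) / rate
  ramp <- stats::pnorm(tt, mean = latency_s, sd = 0.06)
  # full-weight slow noise so the shared modulation carries enough
  # sub-second structure for the lag to be identifiable within one sample
  ramp * pmax(0, 1 + noise)
}

slow_noise <- function(n, rate, cutoff = 8) {
  flt <- signal::butter(2, cutoff / (rate / 2), type = "low")
  x <- signal::filtfilt(flt, rnorm(n + 2 * rate))[rate + seq_len(n)]
  x / sd(x)
}

bandlimited_carrier <- function(n, rate, band) {
  flt <- butter_sos(4, band, rate, "pass")
  pad <- as.integer(rate %/% 2)
  x <- signal::filtfilt(flt, rnorm(n + 2 * pad))[pad + seq_len(n)]
  x / sd(x)
}

#' Inject ground-truth amplitude-amplitude coupling
#'
#' During the feedback phase of up-target trials, adds band-limited carriers
#' at the source and target channels whose envelopes share a common slow
#' stochastic modulator; the target's copy is delayed by `lag_ms` and mixed
#' at fraction `strength` with an independent modulator.  Onset latency
#' varies across trials; the modulator's half-maximum crossing is recorded
#' per trial as the true high-gamma onset.  Samples outside the injected
#' windows are untouched, and `strength = 0` leaves the session unchanged.
#'
#' @param session An `ecog_session` from [simulate_session()].
#' @param spec An [amp_coupling_spec()].
#' @param seed Optional seed (defaults to one derived from the session seed).
#' @return The modified `ecog_session`, with truth records updated.
#' @export
inject_hg_amplitude_coupling <- function(session, spec, seed = NULL) {
  rec <- session$recording
  for (ch in c(spec$source, spec$target)) {
    if (!ch %in% rec$labels) {
      abort(sprintf("unknown channel '%s'", ch), class = "ecog_lookup_error")
    }
  }
  if (spec$strength == 0) {
    session$truth$amp <- c(session$truth$amp, list(spec))
    return(session)
  }
  rate <- rec$rate
  lag_samp <- as.integer(round(spec$lag_ms / 1000 * rate))
  isrc <- match(spec$source, rec$labels)
  itgt <- match(spec$target, rec$labels)
  sd_src <- sd(rec$data[isrc, ])
  sd_tgt <- sd(rec$data[itgt, ])
  if (is.null(seed)) seed <- derive_seed(session$config$seed, "amp_coupling")
  trials <- session$trials
  onsets <- rep(NA_real_, nrow(trials))
  with_seed(seed, {
    for (j in which(trials$target == "up")) {
      fb0 <- trials$feedback_on[j]
      fb1 <- trials$reward_on[j]
      idx <- sample_window(fb0, fb1, rate)
      n_w <- length(idx)
      # extended grid so the delayed copy is defined at both window ends
      margin <- abs(lag_samp)
      n_ext <- n_w + 2L * margin
      latency <- runif(1, 0.3, 1.0)
      shared <- modulator_profile(n_ext, rate,
                                  latency + margin / rate,
                                  slow_noise(n_ext, rate))
      indep <- modulator_profile(n_ext, rate,
                                 latency + margin / rate,
                                 slow_noise(n_ext, rate))
      m_src <- shared[margin + seq_len(n_w)]
      m_tgt_shared <- shared[margin - lag_samp + seq_len(n_w)]
      m_tgt <- spec$strength * m_tgt_shared +
        (1 - spec$strength) * indep[margin - lag_samp + seq_len(n_w)]
      c_src <- bandlimited_carrier(n_w, rate, spec$band)
      c_tgt <- bandlimited_carrier(n_w, rate, spec$band)
      rec$data[isrc, idx] <- rec$data[isrc, idx] +
        spec$amplitude * sd_src * m_src * c_src
      rec$data[itgt, idx] <- rec$data[itgt, idx] +
        spec$amplitude * sd_tgt * m_tgt * c_tgt
      # true onset mirrors the detection rule, applied to the clean
      # modulator (same 470 ms smoothing, baseline/max search bounds and
      # half-maximum crossing), so recovery is well-posed by construction
      true_rel <- detect_hg_onset(m_src, rate)
      onsets[j] <- if (is.na(true_rel)) NA_real_ else fb0 + true_rel
    }
  })
  session$recording <- rec
  session$truth$amp <- c(session$truth$amp, list(spec))
  # onsets describe CTL activity; keep the CTL-sourced record if present
  if (spec$source == session$config$ctl_channel ||
      is.null(session$truth$onsets)) {
    session$truth$onsets <- tibble::tibble(trial = trials$trial,
                                           true_onset_s = onsets)
  }
  session
}

#' Inject ground-truth quadratic phase coupling
#'
#' Per selected trial, draws independent uniform phases psi1 and psi2, adds
#' `cos(2 pi f1 t + psi1) + cos(2 pi f2 t + psi2)` at the source channel and
#' `cos(2 pi (f1 + f2) t - (psi1 + psi2) + eps)` at the target channel
#' within `spec$window` (relative to feedback onset), with
#' `eps ~ N(0, phase_jitter_sd^2)`.  Window edges are tapered with a 25 ms
#' cosine ramp.  Samples outside the windows are untouched.
#'
#' @param session An `ecog_session`.
#' @param spec A [phase_coupling_spec()].
#' @param targets Which trials receive the injection: `"up"` (default,
#'   mirroring the task's up-target modulation), `"down"`, or `"all"`.
#' @param seed Optional seed.
#' @return The modified `ecog_session`, with truth records updated.
#' @export
inject_biphase_coupling <- function(session, spec, targets = "up", seed = NULL) {
  rec <- session$recording
  for (ch in c(spec$source, spec$target)) {
    if (!ch %in% rec$labels) {
      abort(sprintf("unknown channel '%s'", ch), class = "ecog_lookup_error")
    }
  }
  rate <- rec$rate
  if (spec$f1 + spec$f2 >= 400 / 2) {
    abort("f1 + f2 must be below the 400 Hz pipeline Nyquist",
          class = "ecog_config_error")
  }
  isrc <- match(spec$source, rec$labels)
  itgt <- match(spec$target, rec$labels)
  sd_src <- sd(rec$data[isrc, ])
  sd_tgt <- sd(rec$data[itgt, ])
  if (is.null(seed)) seed <- derive_seed(session$config$seed, "phase_coupling")
  trials <- session$trials
  rows <- switch(targets,
                 all = seq_len(nrow(trials)),
                 up = which(trials$target == "up"),
                 down = which(trials$target == "down"),
                 abort("`targets` must be 'all', 'up' or 'down'",
                       class = "ecog_config_error"))
  psis <- matrix(NA_real_, nrow(trials), 2)
  with_seed(seed, {
    for (j in rows) {
      w0 <- trials$feedback_on[j] + spec$window[1]
      w1 <- trials$feedback_on[j] + spec$window[2]
      if (w0 < trials$rest_on[j] || w1 > trials$end_s[j]) {
        abort("phase-coupling window falls outside the trial",
              class = "ecog_config_error")
      }
      idx <- sample_window(w0, w1, rate)
      tt <- (idx - 1) / rate
      psi1 <- runif(1, 0, 2 * pi)
      psi2 <- runif(1, 0, 2 * pi)
      eps <- if (spec$phase_jitter_sd > 0) rnorm(1, 0, spec$phase_jitter_sd) else 0
      taper <- cosine_taper(length(idx), as.integer(round(0.025 * rate)))
      rec$data[isrc, idx] <- rec$data[isrc, idx] +
        spec$amplitude * sd_src * taper *
        (cos(2 * pi * spec$f1 * tt + psi1) + cos(2 * pi * spec$f2 * tt + psi2))
      rec$data[itgt, idx] <- rec$data[itgt, idx] +
        spec$amplitude * sd_tgt * taper *
        cos(2 * pi * (spec$f1 + spec$f2) * tt - (psi1 + psi2) + eps)
      psis[j, ] <- c(psi1, psi2)
    }
  })
  session$recording <- rec
  session$truth$phase <- c(session$truth$phase, list(spec))
  session$truth$psi <- tibble::tibble(trial = trials$trial,
                                      psi1 = psis[, 1], psi2 = psis[, 2])
  session
}

cosine_taper <- function(n, ramp) {
  if (ramp < 1 || 2 * ramp >= n) return(rep(1, n))
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  c(up, rep(1, n - 2 * ramp), rev(up))
}

#' Simulate a complete synthetic BCI session
#'
#' Generates background activity, a four-phase trial table with Bernoulli
#' outcomes, a grid montage, and applies any amplitude and phase coupling
#' injections.  Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param amp_specs List of [amp_coupling_spec()] objects.
#' @param phase_specs List of [phase_coupling_spec()] objects.
#' @param phase_targets Trial subset for phase injections (see
#'   [inject_biphase_coupling()]).
#' @return An `ecog_session`: list with `recording`, `trials`, `montage`,
#'   `truth`, and the `config`.
#' @export
simulate_session <- function(config, amp_specs = list(), phase_specs = list(),
                             phase_targets = "up") {
  if (inherits(amp_specs, "amp_coupling_spec")) amp_specs <- list(amp_specs)
  if (inherits(phase_specs, "phase_coupling_spec")) phase_specs <- list(phase_specs)
  rec <- generate_background(config)
  trials <- build_trial_table(config)
  montage <- build_montage(config)
  session <- structure(list(recording = rec, trials = trials,
                            montage = montage, config = config,
                            truth = list(amp = list(), phase = list(),
                                         onsets = NULL)),
                       class = "ecog_session")
  for (k in seq_along(amp_specs)) {
    session <- inject_hg_amplitude_coupling(
      session, amp_specs[[k]],
      seed = derive_seed(config$seed, paste0("amp", k)))
  }
  for (k in seq_along(phase_specs)) {
    session <- inject_biphase_coupling(
      session, phase_specs[[k]], targets = phase_targets,
      seed = derive_seed(config$seed, paste0("phase", k)))
  }
  session
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("<ecog_session> %d channels, %d trials (%d up, %d hit), CTL = %s\n",
              x$config$n_channels, nrow(x$trials),
              sum(x$trials$target == "up"), sum(x$trials$outcome == "hit"),
              x$config$ctl_channel))
  cat(sprintf("  injected: %d amplitude, %d phase coupling spec(s)\n",
              length(x$truth$amp), length(x$truth$phase)))
  invisible(x)
}

#' Simulate a motor screening block
#'
#' Cued movement/imagery screening: visual cues of `activity_s` seconds
#' followed by `rest_s` seconds of inter-trial rest, repeated `n_reps`
#' times.  Channels listed in `effect_channels` receive a high-gamma-band
#' carrier at `effect_size` times the channel SD during the cue windows.
#'
#' @param n_channels Number of electrodes.
#' @param n_reps Number of cue repetitions (the screening analysis requires
#'   at least 10).
#' @param rate Sampling rate in Hz.
#' @param effect_channels Channels with injected activation.
#' @param effect_size Injected carrier scale in channel-SD units.
#' @param activity_s,rest_s Cue and inter-trial durations, seconds.
#' @param noise_exponent Background spectral slope.
#' @param movement Movement type label.
#' @param seed Integer seed.
#' @return A `screening_block`: list with `recording`, `cues`, `movement`.
#' @export
simulate_screening_block <- function(n_channels = 8, n_reps = 12, rate = 1000,
                                     effect_channels = "ch1", effect_size = 1,
                                     activity_s = 3, rest_s = 3,
                                     noise_exponent = 1, movement = "hand",
                                     seed = 1) {
  n <- as.integer(n_reps * (activity_s + rest_s) * rate)
  if (n %% 2L == 1L) n <- n + 1L
  with_seed(seed, {
    data <- matrix(0, n_channels, n)
    for (i in seq_len(n_channels)) {
      data[i, ] <- one_over_f_channel(n, rate, noise_exponent)
    }
    labels <- paste0("ch", seq_len(n_channels))
    rownames(data) <- labels
    cues <- tibble::tibble(
      onset_s = (seq_len(n_reps) - 1) * (activity_s + rest_s),
      duration_s = activity_s
    )
    for (ch in effect_channels) {
      i <- match(ch, labels)
      if (is.na(i)) abort(sprintf("unknown channel '%s'", ch),
                          class = "ecog_lookup_error")
      for (k in seq_len(n_reps)) {
        idx <- sample_window(cues$onset_s[k], cues$onset_s[k] + activity_s, rate)
        data[i, idx] <- data[i, idx] +
          effect_size * bandlimited_carrier(length(idx), rate, c(70, 150))
      }
    }
    structure(list(recording = ecog_recording(data, rate, labels),
                   cues = cues, movement = movement),
              class = "screening_block")
  })
}
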