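# Shared fixtures, built once per test run.  Everything is generated in
# code from seeded configs; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Session with one injected amplitude coupling (ch1 -> ch2, +50 ms),
# plus its preprocessed envelope and detected onsets.
amp_fixture <- function() {
  fixture("amp_session", function() {
    cfg <- sim_config(n_channels = 12, n_trials = 12, seed = 3,
                      up_probability = 1)
    ses <- simulate_session(
      cfg, amp_specs = amp_coupling_spec("ch1", "ch2", lag_ms = 50,
                                         strength = 1))
    env <- preprocess_envelope(ses$recording)
    trials <- detect_session_onsets(env, ses$trials, "ch1")
    list(session = ses, env = env, trials = trials,
         realigned = realign_trials(trials))
  })
}

# Session with one injected quadratic phase coupling (ch1 -> ch5,
# f1 = 10 Hz, f2 = 80 Hz, window 0-1 s), plus broadband path and phase
# tensors on the analysis epoch.
phase_fixture <- function() {
  fixture("phase_session", function() {
    cfg <- sim_config(n_channels = 8, n_trials = 12, seed = 11,
                      up_probability = 1)
    ses <- simulate_session(
      cfg, phase_specs = phase_coupling_spec("ch1", "ch5", f1 = 10, f2 = 80,
                                             window = c(0, 1)),
      phase_targets = "all")
    broad <- preprocess_broadband(ses$recording)
    epoch <- c(-3, 2.5)
    tax <- epoch[1] + (seq_len(2200) - 1) / 400
    ex <- epoch_channel(broad, "ch1", ses$trials$feedback_on, epoch)
    ey <- epoch_channel(broad, "ch5", ses$trials$feedback_on, epoch)
    src <- wavelet_phase(ex, 400, sort(unique(c(7:25, 70:100))), time_s = tax)
    tgt <- wavelet_phase(ey, 400, 77:125, time_s = tax)
    list(session = ses, broad = broad, src = src, tgt = tgt, time_s = tax)
  })
}

# Phase tensor with i.i.d. uniform phases (no structure), for null checks.
uniform_phase_tensor <- function(freqs, nt, ntr, seed) {
  set.seed(seed)
  structure(list(
    phases = array(runif(length(freqs) * nt * ntr, -pi, pi),
                   c(length(freqs), nt, ntr)),
    freqs = freqs, rate = 400,
    time_s = (seq_len(nt) - 1) / 400, n_trials = ntr),
    class = "phase_tensor")
}

# Build an stwc_map directly (for peak-extraction contract tests).
make_stwc_map <- function(values, time_s, lag_ms) {
  structure(list(values = values, time_s = time_s, lag_ms = lag_ms,
                 n_trials = 1L, pair = NULL),
            class = "stwc_map")
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
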