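#' Detect the high-gamma onset within one trial
#'
#' Implements the response-onset rule used for trial realignment, on the
#' controlling electrode's high-gamma envelope for a single trial:
#'
#' 1. smooth the trial envelope with a 470 ms FWHM (1 s wide) Gaussian
#'    window;
#' 2. the pre-onset baseline is the lowest smoothed value in the first
#'    second of the feedback period; note its time;
#' 3. the maximum is the largest smoothed value after the baseline time and
#'    before 2 s into feedback (exclusive);
#' 4. the onset is the first point after the baseline time at which the
#'    smoothed envelope reaches baseline + (max - baseline) / 2.
#'
#' If the level is crossed between samples the earlier sample is reported
#' ("first point when crossed").  A flat trial (max equal to baseline)
#' yields `NA` with a reason attribute.
#'
#' @param env_segment Numeric vector: the envelope for one trial, starting
#'   at feedback onset (or earlier, see `feedback_start_s`) and covering the
#'   full feedback period.
#' @param rate Sampling rate of the segment in Hz.
#' @param feedback_start_s Time of feedback onset relative to the start of
#'   `env_segment`, seconds.
#' @param smooth Logical; set `FALSE` if the segment is already smoothed at
#'   the 470 ms scale.
#' @return Onset time in seconds relative to feedback onset, or `NA_real_`
#'   (with attribute `reason`) when no onset is defined.
#' @export
detect_hg_onset <- function(env_segment, rate, feedback_start_s = 0,
                            smooth = TRUE) {
  x <- as.numeric(env_segment)
  if (smooth) {
    k <- gaussian_kernel(470, 1000, rate)
    x <- as.numeric(smooth_rows(matrix(x, 1), k))
  }
  fb0 <- as.integer(floor(feedback_start_s * rate)) + 1L
  if (fb0 < 1L || fb0 + as.integer(rate) - 1L > length(x)) {
    abort("segment must cover at least the first second of feedback",
          class = "ecog_config_error")
  }
  first_sec <- fb0:(fb0 + as.integer(rate) - 1L)
  b_idx <- first_sec[which.min(x[first_sec])]
  baseline <- x[b_idx]
  two_sec_excl <- fb0 + as.integer(2 * rate) - 1L   # last sample < 2 s
  hi <- min(two_sec_excl, length(x))
  if (b_idx + 1L > hi) {
    return(structure(NA_real_, reason = "baseline at end of search window"))
  }
  search <- (b_idx + 1L):hi
  peak <- max(x[search])
  if (peak <= baseline) {
    return(structure(NA_real_, reason = "flat trial: max equals baseline"))
  }
  level <- baseline + (peak - baseline) / 2
  cross <- search[which(x[search] >= level)[1]]
  # "first point when crossed": if the level is passed between samples,
  # report the earlier sample
  if (cross > b_idx + 1L && x[cross - 1L] < level && x[cross] > level) {
    cross <- cross - 1L
  }
  (cross - fb0) / rate
}

#' Detect onsets for every trial of a session envelope
#'
#' Runs [detect_hg_onset()] on the controlling channel for each trial of a
#' trial table, using the (smoothed, resampled) high-gamma envelope.
#'
#' @param env An [ecog_envelope()] at the pipeline rate.
#' @param trials Trial table tibble (from a session or [read_events_tsv()]).
#' @param ctl Controlling channel label.
#' @return The trial table with `onset_time` filled in (absolute seconds;
#'   `NA` where undetected).
#' @export
detect_session_onsets <- function(env, trials, ctl) {
  i <- match(ctl, env$labels)
  if (is.na(i)) abort(sprintf("unknown channel '%s'", ctl),
                      class = "ecog_lookup_error")
  onsets <- vapply(seq_len(nrow(trials)), function(j) {
    idx <- sample_window(trials$feedback_on[j], trials$reward_on[j], env$rate)
    o <- detect_hg_onset(env$data[i, idx], env$rate)
    as.numeric(o)
  }, numeric(1))
  trials$onset_time <- trials$feedback_on + onsets
  trials
}

#' Response-locked trial realignment
#'
#' Sets the response-locked zero to the detected high-gamma onset for
#' up-target trials with a detected onset.  Down-target trials and trials
#' with failed detection are excluded from response-locked analyses, since
#' subjects only modulate high gamma above baseline for up-targets.
#'
#' @param trials Trial table with an `onset_time` column (see
#'   [detect_session_onsets()]).
#' @return A tibble of response-locked trials with a `response_zero` column
#'   (absolute seconds).
#' @export
realign_trials <- function(trials) {
  if (!"onset_time" %in% names(trials)) {
    abort("`trials` must carry an `onset_time` column",
          class = "ecog_config_error")
  }
  trials |>
    dplyr::filter(.data$target == "up", !is.na(.data$onset_time)) |>
    dplyr::mutate(response_zero = .data$onset_time)
}
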