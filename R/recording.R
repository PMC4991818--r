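#' ECoG recording container
#'
#' A multichannel continuous field-potential recording: a channels x samples
#' numeric matrix (microvolts) with a sampling rate, unique channel labels,
#' and a good-channel mask.  Bad channels (artifact, inter-ictal activity)
#' stay in the matrix but are excluded from the common average reference and
#' from analyses.
#'
#' @param data Numeric matrix, channels x samples, all values finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel names, one per row.
#' @param good Logical vector flagging good channels; at least one `TRUE`.
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, rate, labels = rownames(data),
                           good = rep(TRUE, nrow(data))) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    abort("`data` must be a finite numeric matrix", class = "ecog_config_error")
  }
  stopifnot_scalar_number(rate, "rate", lower = 1e-9)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data) || anyDuplicated(labels)) {
    abort("`labels` must be unique, one per channel", class = "ecog_config_error")
  }
  good <- as.logical(good)
  if (length(good) != nrow(data) || !any(good)) {
    abort("`good` must flag at least one good channel",
          class = "ecog_config_error")
  }
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels, good = good),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), %d good\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              sum(x$good)))
  invisible(x)
}

#' @export
dim.ecog_recording <- function(x) dim(x$data)

#' Band-limited amplitude envelope container
#'
#' Nonnegative per-channel envelope time series for a named frequency band,
#' produced by [band_envelope()].  Carries the band edges, the sampling rate
#' and a description of any temporal smoothing applied.
#'
#' @param data Nonnegative numeric matrix, channels x samples.
#' @param band Length-2 numeric, band edges in Hz (low < high).
#' @param rate Sampling rate in Hz.
#' @param labels Channel names.
#' @param good Logical good-channel mask.
#' @param smoothing Character description of smoothing, or `"none"`.
#'
#' @return An object of class `ecog_envelope`.
#' @export
ecog_envelope <- function(data, band, rate, labels = rownames(data),
                          good = rep(TRUE, nrow(data)), smoothing = "none") {
  data <- as.matrix(data)
  if (any(data < 0)) {
    abort("envelope values must be nonnegative", class = "ecog_config_error")
  }
  if (length(band) != 2L || band[1] >= band[2]) {
    abort("`band` must be c(low, high) with low < high",
          class = "ecog_config_error")
  }
  rec <- ecog_recording(data, rate, labels, good)
  structure(c(unclass(rec), list(band = band, smoothing = smoothing)),
            class = c("ecog_envelope", "ecog_recording"))
}

#' @export
print.ecog_envelope <- function(x, ...) {
  cat(sprintf("<ecog_envelope> %g-%g Hz, %d channels x %d samples @ %g Hz, smoothing: %s\n",
              x$band[1], x$band[2], nrow(x$data), ncol(x$data), x$rate,
              x$smoothing))
  invisible(x)
}

# Extract one channel's samples over a half-open time interval [t0, t1)
# in seconds.  Sample index 0 corresponds to t = 0.
channel_segment <- function(rec, channel, t0, t1) {
  i <- match(channel, rec$labels)
  if (is.na(i)) {
    abort(sprintf("unknown channel '%s'", channel), class = "ecog_lookup_error")
  }
  j0 <- floor(t0 * rec$rate) + 1
  j1 <- floor(t1 * rec$rate)
  if (j0 < 1 || j1 > ncol(rec$data) || j0 > j1) {
    abort("requested segment falls outside the recording",
          class = "ecog_config_error")
  }
  rec$data[i, j0:j1]
}

# Sample indices (1-based) of the half-open interval [t0, t1).
sample_window <- function(t0, t1, rate) {
  j0 <- floor(t0 * rate) + 1
  j1 <- floor(t1 * rate)
  if (j0 > j1) integer(0) else j0:j1
}

#' Tidy a recording or envelope into a long tibble
#'
#' @param x An `ecog_recording` or `ecog_envelope`.
#' @param channels Optional subset of channel labels.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time_s`, `value`.
#' @method tidy ecog_recording
#' @export
tidy.ecog_recording <- function(x, channels = NULL, ...) {
  keep <- if (is.null(channels)) x$labels else channels
  i <- match(keep, x$labels)
  if (anyNA(i)) abort("unknown channel in `channels`", class = "ecog_lookup_error")
  tt <- (seq_len(ncol(x$data)) - 1) / x$rate
  tibble::tibble(
    channel = rep(keep, each = ncol(x$data)),
    time_s = rep(tt, times = length(keep)),
    value = as.numeric(t(x$data[i, , drop = FALSE]))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
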