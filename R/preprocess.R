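#' Common average re-referencing
#'
#' Subtracts, at every sample, the mean over all *good* channels from every
#' channel (bad channels are re-referenced too but never contribute to the
#' average).  After re-referencing, the per-sample mean of the good channels
#' is zero to machine precision.
#'
#' @param rec An [ecog_recording()].
#' @return A re-referenced `ecog_recording`.
#' @export
common_average_rereference <- function(rec) {
  if (sum(rec$good) < 2L) {
    abort("common average reference needs at least 2 good channels",
          class = "ecog_preprocess_error")
  }
  avg <- colMeans(rec$data[rec$good, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, avg)
  rec
}

butter_sos <- function(order, edges, rate, type) {
  nyq <- rate / 2
  if (any(edges <= 0) || any(edges >= nyq)) {
    abort("filter edges must lie strictly inside (0, Nyquist)",
          class = "ecog_config_error")
  }
  # signal::butter() follows the MATLAB convention: for band filters an
  # argument of n yields a filter of order 2n.
  signal::butter(order / 2, edges / nyq, type = type)
}

filtfilt_rows <- function(m, flt) {
  out <- t(apply(m, 1L, function(x) signal::filtfilt(flt, x)))
  dimnames(out) <- dimnames(m)
  out
}

#' Notch filtering of power-line contamination
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-stop
#' filter around each line frequency.  The -3 dB stop bandwidth defaults to
#' 4 Hz around each center.
#'
#' @param rec An [ecog_recording()].
#' @param centers Line frequencies in Hz to remove.
#' @param bandwidth Full stop-band width in Hz around each center.
#' @return The notch-filtered `ecog_recording`.
#' @export
notch_line_noise <- function(rec, centers = c(60, 120), bandwidth = 4) {
  nyq <- rec$rate / 2
  if (any(centers >= nyq)) {
    abort("notch centers must be below the Nyquist frequency",
          class = "ecog_config_error")
  }
  for (f0 in centers) {
    flt <- butter_sos(4, c(f0 - bandwidth / 2, f0 + bandwidth / 2),
                      rec$rate, "stop")
    rec$data <- filtfilt_rows(rec$data, flt)
  }
  rec
}

#' Band-limited amplitude envelope
#'
#' Zero-phase 4th-order Butterworth band-pass followed by the magnitude of
#' the analytic signal (Hilbert transform), per channel.  The default band
#' is the canonical high-gamma range, 70-150 Hz.
#'
#' @param rec An [ecog_recording()].
#' @param band Length-2 numeric band edges in Hz.
#' @return An [ecog_envelope()].
#' @export
band_envelope <- function(rec, band = c(70, 150)) {
  if (length(band) != 2L || band[1] <= 0 || band[2] >= rec$rate / 2 ||
      band[1] >= band[2]) {
    abort("`band` must lie strictly inside (0, Nyquist)",
          class = "ecog_config_error")
  }
  flt <- butter_sos(4, band, rec$rate, "pass")
  filt <- filtfilt_rows(rec$data, flt)
  env <- t(apply(filt, 1L, function(x) Mod(analytic_signal(x))))
  dimnames(env) <- dimnames(rec$data)
  ecog_envelope(env, band = band, rate = rec$rate, labels = rec$labels,
                good = rec$good, smoothing = "none")
}

#' Temporal smoothing of an envelope
#'
#' Convolves each channel with a truncated Gaussian window (unit sum) of the
#' given full width at half maximum and total width, with reflective edge
#' handling.  Defaults: 47 ms FWHM in a 100 ms window, the setting used to
#' suppress high-frequency noise in the high-gamma envelope.
#'
#' @param env An [ecog_envelope()].
#' @param fwhm_ms Kernel full width at half maximum, ms.
#' @param width_ms Total kernel width, ms.
#' @return The smoothed `ecog_envelope`.
#' @export
smooth_envelope <- function(env, fwhm_ms = 47, width_ms = 100) {
  k <- gaussian_kernel(fwhm_ms, width_ms, env$rate)
  env$data <- smooth_rows(env$data, k)
  env$smoothing <- sprintf("gaussian fwhm %g ms, width %g ms", fwhm_ms, width_ms)
  env
}

#' Anti-aliased resampling
#'
#' Polyphase (upfirdn) resampling with a Kaiser-windowed sinc low-pass,
#' flat in the passband and with zero group delay, so event latencies are
#' preserved.  Only downsampling (or rate-preserving) requests are allowed.
#' Envelopes are clipped at zero afterwards: the anti-aliasing filter can
#' ring slightly negative around sharp transients, and envelope
#' nonnegativity is part of the envelope contract.
#'
#' @param x An [ecog_recording()] or [ecog_envelope()].
#' @param rate Target sampling rate in Hz (default 400, the pipeline rate).
#' @return The same type as `x`, at the new rate.
#' @export
resample_to <- function(x, rate = 400) {
  if (rate > x$rate) {
    abort("upsampling is not supported; target rate must be <= native rate",
          class = "ecog_config_error")
  }
  if (rate == x$rate) return(x)
  frac <- rate / x$rate
  pq <- find_ratio(frac)
  out <- t(apply(x$data, 1L, resample_poly, p = pq[1], q = pq[2]))
  rownames(out) <- x$labels
  if (inherits(x, "ecog_envelope")) out[out < 0] <- 0
  x$data <- out
  x$rate <- rate
  x
}

# Small-denominator rational approximation of a resampling ratio.
find_ratio <- function(frac, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- frac * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  abort("target rate is not a simple rational fraction of the native rate",
        class = "ecog_config_error")
}

#' Standard ECoG conditioning chain
#'
#' Convenience wrapper running the canonical order: common average
#' reference, 60/120 Hz notch, high-gamma envelope, 47 ms Gaussian
#' smoothing, resampling to 400 Hz.
#'
#' @param rec An [ecog_recording()].
#' @param band Envelope band in Hz.
#' @param target_rate Output rate in Hz.
#' @param fwhm_ms,width_ms Smoothing kernel parameters, ms.
#' @return A smoothed, resampled [ecog_envelope()].
#' @export
preprocess_envelope <- function(rec, band = c(70, 150), target_rate = 400,
                                fwhm_ms = 47, width_ms = 100) {
  rec |>
    common_average_rereference() |>
    notch_line_noise() |>
    band_envelope(band = band) |>
    smooth_envelope(fwhm_ms = fwhm_ms, width_ms = width_ms) |>
    resample_to(target_rate)
}

#' Broadband conditioning chain for phase analyses
#'
#' Common average reference, notch, and resampling to the 400 Hz pipeline
#' rate, *without* envelope extraction: wavelet phases are computed on the
#' broadband signal.
#'
#' @param rec An [ecog_recording()].
#' @param target_rate Output rate in Hz.
#' @return A resampled `ecog_recording`.
#' @export
preprocess_broadband <- function(rec, target_rate = 400) {
  rec |>
    common_average_rereference() |>
    notch_line_noise() |>
    resample_to(target_rate)
}
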