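#' Extract aligned epochs from one channel
#'
#' Cuts equal-length epochs around a set of alignment zeros (e.g. feedback
#' onsets, or detected response onsets).  Epochs are half-open
#' `[zero + w0, zero + w1)`; at the 400 Hz pipeline rate the default
#' -3 s to +2.5 s window yields 2200 samples per epoch.
#'
#' @param rec An [ecog_recording()] or [ecog_envelope()].
#' @param channel Channel label.
#' @param zeros Numeric vector of alignment times (absolute seconds).
#' @param window Length-2 numeric, epoch window in seconds relative to the
#'   zeros.
#' @return A samples x epochs numeric matrix.
#' @export
epoch_channel <- function(rec, channel, zeros, window = c(-3, 2.5)) {
  i <- match(channel, rec$labels)
  if (is.na(i)) {
    abort(sprintf("unknown channel '%s'", channel), class = "ecog_lookup_error")
  }
  # fixed epoch length regardless of sub-sample alignment of the zeros
  n_samp <- as.integer(round((window[2] - window[1]) * rec$rate))
  vapply(zeros, function(z) {
    j0 <- as.integer(floor((z + window[1]) * rec$rate)) + 1L
    if (j0 < 1L || j0 + n_samp - 1L > ncol(rec$data)) {
      abort("epoch falls outside the recording", class = "ecog_config_error")
    }
    rec$data[i, j0:(j0 + n_samp - 1L)]
  }, numeric(n_samp))
}

#' Morlet wavelet phase estimation
#'
#' Convolves each epoch with continuous complex Morlet wavelets (analytic,
#' Gaussian in frequency, `n_cycles` cycles at every frequency) and takes
#' the argument, giving a time-varying phase per frequency at 1 Hz
#' resolution.
#'
#' @param epochs Samples x trials numeric matrix (see [epoch_channel()]).
#' @param rate Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz; all must lie in (0, rate/2).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param time_s Optional time axis for the epoch samples (seconds,
#'   relative to the alignment zero).
#' @param return_amplitude Also keep the wavelet magnitude (doubles the
#'   memory footprint; off by default).
#' @return A `phase_tensor`: phases array \[frequency, time, trial\]
#'   wrapped to (-pi, pi\], plus `freqs`, `rate`, `time_s` (and
#'   `amplitude` when requested).
#' @export
wavelet_phase <- function(epochs, rate, freqs, n_cycles = 7, time_s = NULL,
                          return_amplitude = FALSE) {
  epochs <- as.matrix(epochs)
  if (any(freqs <= 0) || any(freqs >= rate / 2)) {
    abort("all frequencies must lie strictly inside (0, Nyquist)",
          class = "ecog_config_error")
  }
  nt <- nrow(epochs)
  ntr <- ncol(epochs)
  sigma_t_max <- n_cycles / (2 * pi * min(freqs))
  pad <- ceiling(6 * sigma_t_max * rate)
  nfft <- stats::nextn(nt + 2 * pad, 2)
  fgrid <- (seq_len(nfft) - 1) * rate / nfft
  spec <- stats::mvfft(rbind(epochs, matrix(0, nfft - nt, ntr)))
  phases <- array(NA_real_, c(length(freqs), nt, ntr))
  amps <- if (return_amplitude) array(NA_real_, c(length(freqs), nt, ntr))
  half_idx <- fgrid <= rate / 2
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles
    h <- numeric(nfft)
    h[half_idx] <- exp(-(fgrid[half_idx] - f0)^2 / (2 * sigma_f^2))
    conv <- stats::mvfft(spec * h, inverse = TRUE)[seq_len(nt), , drop = FALSE]
    phases[k, , ] <- Arg(conv)
    if (return_amplitude) amps[k, , ] <- Mod(conv) / nfft
  }
  if (is.null(time_s)) time_s <- (seq_len(nt) - 1) / rate
  structure(list(phases = phases, freqs = freqs, rate = rate,
                 time_s = time_s, n_trials = ntr, amplitude = amps),
            class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  cat(sprintf("<phase_tensor> %d freqs (%g-%g Hz) x %d samples x %d trials @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              dim(x$phases)[2], x$n_trials, x$rate))
  invisible(x)
}

unit_phasors <- function(tensor, freqs) {
  idx <- match(freqs, tensor$freqs)
  if (anyNA(idx)) {
    abort("phase tensor does not contain all requested frequencies",
          class = "ecog_config_error")
  }
  exp(1i * tensor$phases[idx, , , drop = FALSE])
}

check_unit_step <- function(f, name) {
  if (length(f) > 1 && any(abs(diff(f) - 1) > 1e-9)) {
    abort(sprintf("`%s` must be a contiguous 1 Hz grid", name),
          class = "ecog_config_error")
  }
}

#' Bi-phase locking value map
#'
#' Computes, for every frequency pair (f1, f2) and time point, the bi-phase
#' locking value
#' \deqn{B_{XYZ}(t, f_1, f_2) = \left| \frac{1}{N} \sum_{j=1}^{N}
#'   e^{i(\phi_X^j(t, f_1) + \phi_Y^j(t, f_2) + \phi_Z^j(t, f_1 + f_2))}
#'   \right|}
#' with X = Y = the controlling electrode (the source) and Z = the remote
#' electrode (the target), detecting quadratic coupling where the source
#' phases at f1 and f2 predict the target phase at f1 + f2.  The default
#' grid, f1 = 7..25 Hz by f2 = 70..100 Hz at 1 Hz steps, yields 19 x 31 =
#' 589 frequency-pair series.
#'
#' @param source A `phase_tensor` at the controlling electrode containing
#'   all `f1` and `f2` rows.
#' @param target A `phase_tensor` at the remote electrode containing all
#'   `f1 + f2` rows, with the same trial count and time axis.
#' @param f1,f2 Contiguous 1 Hz frequency grids (Hz).
#' @return A `bplv_map`: values array \[f1, f2, time\] in \[0, 1\], plus
#'   axes and `n_trials`.
#' @export
bplv_map <- function(source, target, f1 = 7:25, f2 = 70:100) {
  if (source$n_trials != target$n_trials || source$n_trials < 1) {
    abort("source and target must have the same (positive) trial count",
          class = "ecog_config_error")
  }
  if (!isTRUE(all.equal(source$time_s, target$time_s))) {
    abort("source and target must share a time axis", class = "ecog_config_error")
  }
  check_unit_step(f1, "f1"); check_unit_step(f2, "f2")
  fsum <- seq(min(f1) + min(f2), max(f1) + max(f2))
  e1 <- unit_phasors(source, f1)
  e2 <- unit_phasors(source, f2)
  e3 <- unit_phasors(target, fsum)
  nt <- dim(e1)[2]
  vals <- bplv_map_kernel(as.complex(e1), as.complex(e2), as.complex(e3),
                          length(f1), length(f2), length(fsum),
                          nt, source$n_trials)
  structure(list(values = vals, f1 = f1, f2 = f2, time_s = source$time_s,
                 n_trials = source$n_trials),
            class = "bplv_map")
}

#' @export
print.bplv_map <- function(x, ...) {
  cat(sprintf("<bplv_map> %d x %d frequency pairs (%d series) x %d samples, N = %d trials\n",
              length(x$f1), length(x$f2), length(x$f1) * length(x$f2),
              dim(x$values)[3], x$n_trials))
  invisible(x)
}

#' Time-integrated bPLV grid
#'
#' Time-mean of the bPLV over `[t0, t1)` for every frequency pair.  The
#' mean (rather than a raw sum) keeps values in \[0, 1\]; it is affine to
#' the integral, so rankings and max-statistic inference are identical.
#'
#' @param map A `bplv_map`.
#' @param t0,t1 Integration bounds in seconds on the map's time axis
#'   (default 0 to 1 s: control onset to 1 s post onset).
#' @return A `bplv_grid`: f1 x f2 matrix of integrated values, plus axes.
#' @export
integrate_bplv <- function(map, t0 = 0, t1 = 1) {
  keep <- map$time_s >= t0 & map$time_s < t1
  if (!any(keep)) {
    abort("empty integration interval", class = "ecog_config_error")
  }
  vals <- apply(map$values[, , keep, drop = FALSE], c(1, 2), mean)
  dimnames(vals) <- list(f1 = map$f1, f2 = map$f2)
  structure(list(values = vals, f1 = map$f1, f2 = map$f2,
                 t0 = t0, t1 = t1, duration_s = t1 - t0,
                 n_trials = map$n_trials),
            class = "bplv_grid")
}

#' Tidy an integrated bPLV grid
#' @param x A `bplv_grid`.
#' @param ... Unused.
#' @return A tibble with `f1`, `f2`, `value`.
#' @method tidy bplv_grid
#' @export
tidy.bplv_grid <- function(x, ...) {
  tibble::tibble(
    f1 = rep(x$f1, times = length(x$f2)),
    f2 = rep(x$f2, each = length(x$f1)),
    value = as.numeric(x$values)
  )
}

#' Plot an integrated bPLV grid
#' @param object A `bplv_grid`.
#' @param ... Unused.
#' @return A ggplot raster of integrated bPLV by (f1, f2).
#' @method autoplot bplv_grid
#' @export
autoplot.bplv_grid <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$f1, y = .data$f2,
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "f1 (Hz)", y = "f2 (Hz)", fill = "bPLV")
}

#' Pseudo-zscore normalization of bPLV time series
#'
#' bPLV magnitudes depend on the trial count, so subject-level series are
#' scaled to pseudo-zscores before group averaging: per frequency pair,
#' subtract the mean and divide by the SD of the pre-control baseline
#' interval.  The output is not necessarily bounded on \[0, 1\].
#'
#' @param x A `bplv_map`, or a numeric vector with `time_s` supplied.
#' @param baseline Length-2 numeric, baseline interval in seconds (default
#'   -3 to 0, the pre-control period).
#' @param time_s Time axis when `x` is a plain vector.
#' @return Same shape as `x`, normalized.
#' @export
normalize_pseudo_z <- function(x, baseline = c(-3, 0), time_s = NULL) {
  if (inherits(x, "bplv_map")) {
    keep <- x$time_s >= baseline[1] & x$time_s < baseline[2]
    if (sum(keep) < 2) {
      abort("baseline interval is empty", class = "ecog_config_error")
    }
    base <- x$values[, , keep, drop = FALSE]
    mu <- apply(base, c(1, 2), mean)
    sg <- apply(base, c(1, 2), sd)
    if (any(sg == 0)) {
      abort("zero baseline SD", class = "ecog_inference_error")
    }
    x$values <- sweep(sweep(x$values, c(1, 2), mu), c(1, 2), sg, "/")
    x$normalized <- TRUE
    return(x)
  }
  if (is.null(time_s)) {
    abort("`time_s` is required for vector input", class = "ecog_config_error")
  }
  keep <- time_s >= baseline[1] & time_s < baseline[2]
  if (sum(keep) < 2) abort("baseline interval is empty",
                           class = "ecog_config_error")
  mu <- mean(x[keep]); sg <- sd(x[keep])
  if (sg == 0) abort("zero baseline SD", class = "ecog_inference_error")
  (x - mu) / sg
}

#' Grand average of normalized series across subjects
#'
#' Pointwise mean across subjects with a +/- 1 standard-error band (the 84%
#' confidence interval of the group average).
#'
#' @param series List of numeric vectors (one per subject) on a common time
#'   axis, or a subjects-in-columns matrix.
#' @param time_s Common time axis, seconds.
#' @return A tibble with `time_s`, `mean`, `lo`, `hi`, `n_subjects`.
#' @export
grand_average <- function(series, time_s) {
  if (is.list(series)) {
    len <- lengths(series)
    if (length(series) < 2) {
      abort("grand average needs at least 2 series", class = "ecog_config_error")
    }
    if (length(unique(len)) != 1) {
      abort("series lie on mismatched axes", class = "ecog_config_error")
    }
    series <- do.call(cbind, series)
  }
  if (ncol(series) < 2 || nrow(series) != length(time_s)) {
    abort("series must match the time axis and include >= 2 subjects",
          class = "ecog_config_error")
  }
  mu <- rowMeans(series)
  sem <- apply(series, 1, sd) / sqrt(ncol(series))
  tibble::tibble(time_s = time_s, mean = mu, lo = mu - sem, hi = mu + sem,
                 n_subjects = ncol(series))
}

#' Linear (within-frequency) phase locking value
#'
#' The classical control for the cross-frequency analysis: per frequency,
#' \eqn{|\,\mathrm{mean}_j\, e^{i(\phi_x^j(t,f) - \phi_y^j(t,f))}|}.
#'
#' @param phase_x,phase_y `phase_tensor`s on identical frequency and time
#'   axes with equal trial counts.
#' @return A `plv_map`: values matrix \[frequency, time\] in \[0, 1\].
#' @export
linear_plv <- function(phase_x, phase_y) {
  if (!isTRUE(all.equal(phase_x$freqs, phase_y$freqs)) ||
      !isTRUE(all.equal(phase_x$time_s, phase_y$time_s)) ||
      phase_x$n_trials != phase_y$n_trials) {
    abort("phase tensors must share frequency/time axes and trial count",
          class = "ecog_config_error")
  }
  if (phase_x$n_trials < 1) abort("no trials", class = "ecog_config_error")
  d <- dim(phase_x$phases)
  z <- exp(1i * (phase_x$phases - phase_y$phases))
  vals <- Mod(rowMeans(matrix(z, d[1] * d[2], d[3])))
  vals <- matrix(vals, d[1], d[2])
  structure(list(values = vals, freqs = phase_x$freqs,
                 time_s = phase_x$time_s, n_trials = phase_x$n_trials),
            class = "plv_map")
}

#' Time-averaged PLV spectrum
#' @param x A `plv_map`.
#' @param ... Unused.
#' @return A tibble with `freq_hz` and time-averaged `plv`.
#' @method tidy plv_map
#' @export
tidy.plv_map <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs, plv = rowMeans(x$values))
}
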