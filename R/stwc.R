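#' STWC parameters
#'
#' Window and lag settings for short-time windowed covariance maps.
#' Defaults follow the standard analysis: 500 ms correlation window,
#' maximum lag 300 ms.  At the 400 Hz pipeline rate these convert to a
#' 201-sample window and 120-sample maximum lag.
#'
#' @param window_ms Correlation window width tau, ms (> 0).
#' @param max_lag_ms Maximum lag Delta, ms (>= 0).
#' @return An `stwc_params` list.
#' @export
stwc_params <- function(window_ms = 500, max_lag_ms = 300) {
  stopifnot_scalar_number(window_ms, "window_ms", lower = 1e-9)
  stopifnot_scalar_number(max_lag_ms, "max_lag_ms", lower = 0)
  structure(list(window_ms = window_ms, max_lag_ms = max_lag_ms),
            class = "stwc_params")
}

new_stwc_map <- function(values, time_s, lag_ms, n_trials, pair = NULL) {
  structure(list(values = values, time_s = time_s, lag_ms = lag_ms,
                 n_trials = n_trials, pair = pair),
            class = "stwc_map")
}

#' Single-trial short-time windowed covariance map
#'
#' For two equal-length envelope segments x (the controlling electrode) and
#' y (a remote electrode), computes the normalized STWC
#' \deqn{C(x, y, t, \tau, \delta) = \frac{1}{\sigma_{x,t,\tau}\,
#'   \sigma_{y,t+\delta,\tau}} \sum_{i = t - \tau/2}^{t + \tau/2}
#'   \frac{(x_i - \bar x)(y_{\delta + i} - \bar y_\delta)}{\tau + 1}}
#' i.e. the Pearson correlation of the (tau + 1)-sample window of x
#' centered at t with the window of y centered at t + delta, for every
#' retained time t and every lag delta in \[-Delta, Delta\].  Time centers
#' are retained only where both windows fit inside the segments at all
#' lags.  A positive-lag peak means the remote channel's matching activity
#' occurs later than at the controlling electrode (remote lags CTL);
#' negative lags mean the remote leads.  Zero-variance windows give `NA`,
#' never infinities.
#'
#' @param x,y Numeric envelope segments, equal length, same rate.
#' @param rate Sampling rate in Hz.
#' @param params An [stwc_params()].
#' @param zero_s Time (s) of segment sample 1 relative to the alignment
#'   zero, so the map's time axis is alignment-relative.
#' @return An `stwc_map` with a time x lag matrix of coefficients in
#'   \[-1, 1\].
#' @export
stwc_single_trial <- function(x, y, rate, params = stwc_params(),
                              zero_s = 0) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "ecog_config_error")
  }
  half <- as.integer(round(params$window_ms / 1000 * rate / 2))
  max_lag <- as.integer(round(params$max_lag_ms / 1000 * rate))
  n <- length(x)
  lo <- half + max_lag + 1L
  hi <- n - half - max_lag
  if (lo > hi) {
    abort("segment too short for the requested window and lag",
          class = "ecog_config_error")
  }
  centers <- lo:hi
  vals <- stwc_kernel(x, y, half, max_lag, centers - 1L)
  new_stwc_map(vals,
               time_s = zero_s + (centers - 1L) / rate,
               lag_ms = seq(-max_lag, max_lag) / rate * 1000,
               n_trials = 1L)
}

#' Average STWC map across trials
#'
#' Entrywise mean over per-trial maps, ignoring missing (zero-variance)
#' entries; all maps must share time and lag axes.
#'
#' @param maps List of `stwc_map` objects.
#' @return An `stwc_map` with `n_trials` set to the number averaged.
#' @export
average_stwc <- function(maps) {
  if (length(maps) == 0L) {
    abort("cannot average an empty list of maps", class = "ecog_config_error")
  }
  ax <- maps[[1]]
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(m$time_s, ax$time_s)) ||
        !isTRUE(all.equal(m$lag_ms, ax$lag_ms))) {
      abort("all maps must share time and lag axes", class = "ecog_config_error")
    }
  }
  arr <- vapply(maps, function(m) m$values,
                matrix(0, nrow(ax$values), ncol(ax$values)))
  sums <- rowSums(array(ifelse(is.na(arr), 0, arr), dim = dim(arr)), dims = 2)
  cnts <- rowSums(array(!is.na(arr), dim = dim(arr)), dims = 2)
  avg <- ifelse(cnts > 0, sums / cnts, NA_real_)
  new_stwc_map(avg, ax$time_s, ax$lag_ms, n_trials = length(maps),
               pair = ax$pair)
}

#' Extract the peak STWC coefficient and its lag
#'
#' Returns the maximum coefficient within a restricted time range (e.g. the
#' first second of the feedback period for cue-locked maps, or +/- 500 ms
#' around the high-gamma onset for response-locked maps) across all lags,
#' with its time and lag.  Exact ties are broken toward the smallest |lag|,
#' then toward the negative lag.
#'
#' @param map An `stwc_map`.
#' @param analysis_window Length-2 numeric, time range (s, half-open
#'   `[t0, t1)`) on the map's alignment-relative time axis.
#' @return A one-row tibble: `coef`, `t_s`, `lag_ms`.
#' @export
extract_peak <- function(map, analysis_window) {
  keep <- map$time_s >= analysis_window[1] & map$time_s < analysis_window[2]
  if (!any(keep)) {
    abort("analysis window does not intersect the map's time axis",
          class = "ecog_config_error")
  }
  sub <- map$values[keep, , drop = FALSE]
  if (all(is.na(sub))) {
    abort("all entries missing in the analysis window",
          class = "ecog_config_error")
  }
  best <- max(sub, na.rm = TRUE)
  hits <- which(sub == best, arr.ind = TRUE)
  lags <- map$lag_ms[hits[, 2]]
  ord <- order(abs(lags), lags)   # smallest |lag| first, negative before positive
  pick <- hits[ord[1], , drop = FALSE]
  tibble::tibble(coef = best,
                 t_s = map$time_s[keep][pick[1, 1]],
                 lag_ms = map$lag_ms[pick[1, 2]])
}

#' Tidy an STWC map into a long tibble
#' @param x An `stwc_map`.
#' @param ... Unused.
#' @return A tibble with `time_s`, `lag_ms`, `coef`.
#' @method tidy stwc_map
#' @export
tidy.stwc_map <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$time_s, times = length(x$lag_ms)),
    lag_ms = rep(x$lag_ms, each = length(x$time_s)),
    coef = as.numeric(x$values)
  )
}

#' One-row summary of an STWC map
#' @param x An `stwc_map`.
#' @param ... Unused.
#' @return A tibble with peak value/time/lag and trial count.
#' @method glance stwc_map
#' @export
glance.stwc_map <- function(x, ...) {
  pk <- extract_peak(x, range(x$time_s) + c(0, 1e-9))
  tibble::tibble(peak_coef = pk$coef, peak_t_s = pk$t_s,
                 peak_lag_ms = pk$lag_ms, n_trials = x$n_trials)
}

#' Plot an STWC map
#' @param object An `stwc_map`.
#' @param ... Unused.
#' @return A ggplot raster of coefficient by time and lag.
#' @method autoplot stwc_map
#' @export
autoplot.stwc_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s, y = .data$lag_ms,
                                 fill = .data$coef)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "lag (ms)", fill = "STWC")
}

#' @export
print.stwc_map <- function(x, ...) {
  cat(sprintf("<stwc_map> %d times x %d lags, %d trial(s)\n",
              nrow(x$values), ncol(x$values), x$n_trials))
  invisible(x)
}

#' Average STWC map for one channel pair over aligned epochs
#'
#' Computes a per-trial map for every epoch column and averages them.
#'
#' @param epochs_x,epochs_y Samples x trials envelope epoch matrices for
#'   the controlling and remote channel (see [epoch_channel()]), sample 1
#'   at `zero_s` relative to the alignment zero.
#' @param rate Sampling rate, Hz.
#' @param params An [stwc_params()].
#' @param zero_s Alignment-relative time of epoch sample 1, seconds.
#' @return The trial-averaged `stwc_map`.
#' @export
stwc_pair_map <- function(epochs_x, epochs_y, rate, params = stwc_params(),
                          zero_s = 0) {
  epochs_x <- as.matrix(epochs_x); epochs_y <- as.matrix(epochs_y)
  if (!all(dim(epochs_x) == dim(epochs_y))) {
    abort("epoch matrices must have identical dimensions",
          class = "ecog_config_error")
  }
  half <- as.integer(round(params$window_ms / 1000 * rate / 2))
  max_lag <- as.integer(round(params$max_lag_ms / 1000 * rate))
  n <- nrow(epochs_x)
  lo <- half + max_lag + 1L
  hi <- n - half - max_lag
  if (lo > hi) {
    abort("epochs too short for the requested window and lag",
          class = "ecog_config_error")
  }
  centers <- lo:hi
  vals <- stwc_avg_kernel(epochs_x, epochs_y, half, max_lag, centers - 1L)
  new_stwc_map(vals,
               time_s = zero_s + (centers - 1L) / rate,
               lag_ms = seq(-max_lag, max_lag) / rate * 1000,
               n_trials = ncol(epochs_x))
}
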