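#' Phase-randomized surrogate of a signal
#'
#' Discrete-spectrum amplitudes are preserved exactly; the phases of the
#' positive frequencies are drawn i.i.d. uniform and Hermitian-symmetrized;
#' DC and Nyquist bins are untouched, so the output is exactly real with
#' the same power spectrum (hence the same autocorrelation) as the input.
#'
#' @param x Real numeric vector.
#' @return A surrogate vector of the same length.
#' @export
phase_randomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  if (n < 3) return(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- runif(half, 0, 2 * pi)
  rot <- exp(1i * ph)
  X[2:(half + 1)] <- X[2:(half + 1)] * rot
  X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

new_null_distribution <- function(samples, n_resamples, scope, statistic) {
  stopifnot(length(samples) == n_resamples, all(is.finite(samples)))
  structure(list(samples = samples, n_resamples = n_resamples,
                 scope = scope, statistic = statistic),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s, %d resamples (%s), 95th pctile %.4f\n",
              x$statistic, x$n_resamples, x$scope,
              stats::quantile(x$samples, 0.95)))
  invisible(x)
}

#' Surrogate null distribution for STWC peaks
#'
#' Builds the max-statistic null for average STWC maps: per iteration,
#' each remote channel's trial pairing is shuffled and every trial segment
#' of both channels is phase-randomized (the statistic is computed on
#' envelopes, so randomizing the envelope segments preserves each
#' channel's envelope power spectrum - and with it the stereotyped
#' event-locked autocorrelation - while destroying cross-channel
#' alignment).  Average maps are recomputed for every controlling-remote
#' pair and the in-window peak retained.  With `scope = "max"` (default,
#' the maximum-statistic convention) the maximum across pairs is kept per
#' iteration, giving exact family-wise control; `scope = "pooled"` pools
#' every pair's peak into one distribution.
#'
#' @param epochs_x Samples x trials envelope epochs at the controlling
#'   electrode.
#' @param epochs_y Named list of samples x trials epoch matrices, one per
#'   remote channel.
#' @param rate Sampling rate in Hz.
#' @param params An [stwc_params()].
#' @param analysis_window Length-2 numeric, peak search window (s) on the
#'   epoch's alignment-relative time axis.
#' @param zero_s Time of epoch sample 1 relative to the alignment zero.
#' @param n_iter Number of surrogate iterations (default 100; fewer than
#'   20 warns of an unstable tail).
#' @param scope `"max"` or `"pooled"` (see above).
#' @param seed Optional seed for reproducibility.
#' @return A `null_distribution`.
#' @export
stwc_null <- function(epochs_x, epochs_y, rate, params = stwc_params(),
                      analysis_window, zero_s = 0, n_iter = 100,
                      scope = c("max", "pooled"), seed = NULL) {
  scope <- match.arg(scope)
  if (!is.list(epochs_y)) epochs_y <- list(remote = epochs_y)
  if (n_iter < 20) {
    warn("fewer than 20 surrogate iterations gives an unstable null tail")
  }
  ntr <- ncol(epochs_x)
  with_seed(seed, {
    per_iter <- lapply(seq_len(n_iter), function(it) {
      xs <- apply(epochs_x, 2, phase_randomize)
      peaks <- vapply(epochs_y, function(ey) {
        perm <- sample.int(ntr)
        ys <- apply(ey[, perm, drop = FALSE], 2, phase_randomize)
        m <- stwc_pair_map(xs, ys, rate, params, zero_s)
        keep <- m$time_s >= analysis_window[1] & m$time_s < analysis_window[2]
        max(m$values[keep, ], na.rm = TRUE)
      }, numeric(1))
      if (scope == "max") max(peaks) else peaks
    })
    samples <- unlist(per_iter, use.names = FALSE)
    new_null_distribution(samples, length(samples), scope, "stwc_peak")
  })
}

#' Significance of observed STWC peaks against a surrogate null
#'
#' Randomization p-values use the +1 convention,
#' `p = (1 + #(null >= observed)) / (1 + n)`, so p is never 0; an
#' observed peak is significant only if it exceeds the empirical 95th
#' percentile strictly.
#'
#' @param peaks Tibble of observed peaks with a `coef` column (one row per
#'   channel pair; see [extract_peak()]).
#' @param null A `null_distribution` from [stwc_null()].
#' @return `peaks` with `p` and `significant` columns added.
#' @export
stwc_significance <- function(peaks, null) {
  if (null$n_resamples < 1) {
    abort("empty null distribution", class = "ecog_inference_error")
  }
  thr <- stats::quantile(null$samples, 0.95, names = FALSE)
  peaks |>
    dplyr::mutate(
      p = vapply(.data$coef,
                 function(v) (1 + sum(null$samples >= v)) /
                   (1 + null$n_resamples), numeric(1)),
      significant = .data$coef > thr
    )
}

#' Trial-shuffled null and p-values for integrated bPLV
#'
#' Surrogates are built by circularly shifting the target channel's trial
#' order relative to the source by a random nonzero offset (the identity
#' offset is excluded by construction), recomputing the time-integrated
#' (f1, f2) grid, and retaining its maximum over all frequency pairs.
#' Since only `N - 1` distinct nonzero shifts exist, each distinct offset
#' is computed once and the resamples draw among them.  The observed grid
#' is compared against the histogram of maxima (so no correction across
#' the frequency grid is needed), and the pair-level p-value is Bonferroni
#' corrected by the number of channel pairs examined.
#'
#' @param source `phase_tensor` at the controlling electrode (must contain
#'   the `f1` and `f2` rows).
#' @param target `phase_tensor` at the remote electrode (must contain the
#'   `f1 + f2` rows).
#' @param f1,f2 Frequency grids (1 Hz steps).
#' @param t0,t1 Integration interval, seconds.
#' @param n_resamples Number of resamples (default 10000).
#' @param n_pairs Number of channel pairs examined, for the Bonferroni
#'   correction.
#' @param seed Optional seed.
#' @return A list: `observed` (`bplv_grid`), `p_grid` (matrix of per-pair
#'   frequency p-values), `p` (pair-level p from the grid maximum),
#'   `p_corrected`, `significant`, and the `null` distribution of maxima.
#' @export
bplv_null <- function(source, target, f1 = 7:25, f2 = 70:100,
                      t0 = 0, t1 = 1, n_resamples = 10000, n_pairs = 1,
                      seed = NULL) {
  ntr <- source$n_trials
  if (ntr < 5) {
    abort("bPLV trial shuffling needs at least 5 trials",
          class = "ecog_inference_error")
  }
  check_unit_step(f1, "f1"); check_unit_step(f2, "f2")
  keep <- source$time_s >= t0 & source$time_s < t1
  if (!any(keep)) abort("empty integration interval",
                        class = "ecog_config_error")
  fsum <- seq(min(f1) + min(f2), max(f1) + max(f2))
  e1 <- unit_phasors(source, f1)[, keep, , drop = FALSE]
  e2 <- unit_phasors(source, f2)[, keep, , drop = FALSE]
  e3 <- unit_phasors(target, fsum)[, keep, , drop = FALSE]
  nt <- sum(keep)
  kern <- bplv_offsets_kernel(as.complex(e1), as.complex(e2), as.complex(e3),
                              length(f1), length(f2), length(fsum),
                              nt, ntr)
  obs <- kern$observed
  offset_max <- kern$offset_max
  samples <- with_seed(seed,
    offset_max[sample.int(ntr - 1L, n_resamples, replace = TRUE)])
  p_grid <- matrix(
    (1 + vapply(as.numeric(obs), function(v) sum(samples >= v), numeric(1))) /
      (1 + n_resamples),
    nrow(obs), ncol(obs))
  p_pair <- (1 + sum(samples >= max(obs))) / (1 + n_resamples)
  observed <- structure(list(values = obs, f1 = f1, f2 = f2, t0 = t0, t1 = t1,
                             duration_s = t1 - t0, n_trials = ntr),
                        class = "bplv_grid")
  list(observed = observed,
       p_grid = p_grid,
       p = p_pair,
       p_corrected = min(1, p_pair * n_pairs),
       significant = min(1, p_pair * n_pairs) < 0.05,
       null = new_null_distribution(samples, n_resamples, "per-pair",
                                    "bplv_integrated_max"))
}

#' Bootstrap confidence bounds for chance behavioral performance
#'
#' Under the null of equally likely success and failure, one bootstrap
#' sample of chance performance is the mean of N Bernoulli(0.5) draws; the
#' CI is the empirical 2.5/97.5 percentile over `n_boot` repetitions.  The
#' theoretical chance point estimate on this task is 0.5.
#'
#' @param n_trials Number of trials performed by the subject (>= 1).
#' @param n_boot Bootstrap repetitions (default 1000).
#' @param seed Optional seed.
#' @return A one-row tibble: `point`, `lo`, `hi`, `n_trials`, `n_boot`.
#' @export
chance_performance_ci <- function(n_trials, n_boot = 1000, seed = NULL) {
  stopifnot_scalar_number(n_trials, "n_trials", lower = 1)
  sims <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(stats::rbinom(n_trials, 1, 0.5))
  }, numeric(1)))
  ci <- stats::quantile(sims, c(0.025, 0.975), names = FALSE)
  tibble::tibble(point = 0.5, lo = ci[1], hi = ci[2],
                 n_trials = as.integer(n_trials), n_boot = as.integer(n_boot))
}

# t-test that tolerates the degenerate all-equal case (t = 0, p = 1).
safe_t_test <- function(a, b, paired = FALSE, alternative = "two.sided") {
  if (paired) {
    d <- a - b
    if (all(d == d[1]) && d[1] == 0) {
      return(list(statistic = 0, p.value = 1,
                  parameter = length(d) - 1, estimate = 0))
    }
    if (sd(d) == 0) {
      return(list(statistic = sign(d[1]) * Inf, p.value = 0,
                  parameter = length(d) - 1, estimate = d[1]))
    }
    tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                  p.value = if (same) 1 else 0,
                  parameter = length(a) + length(b) - 2,
                  estimate = mean(a) - mean(b)))
    }
    tt <- stats::t.test(a, b, alternative = alternative)
  }
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       parameter = unname(tt$parameter),
       estimate = if (paired) unname(tt$estimate)
                  else unname(diff(rev(tt$estimate))))
}

#' Early-versus-late comparison of interaction strength
#'
#' For each subject, takes the median interaction strength over its
#' significant interactions separately for early trials (first half) and
#' late trials (second half), then runs a paired t-test across subjects.
#' Subjects lacking either half are excluded (and reported).
#'
#' @param results Tibble with columns `subject`, `half` (`"early"` /
#'   `"late"`), and `value` (peak STWC coefficient or normalized bPLV),
#'   one row per significant interaction.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   for the early-minus-late difference.
#' @return A one-row tibble: per-subject median means for both halves,
#'   `t`, `df`, `p`, `n_subjects`, `n_excluded`.
#' @export
early_late_comparison <- function(results, alternative = "two.sided") {
  med <- results |>
    dplyr::group_by(.data$subject, .data$half) |>
    dplyr::summarise(m = stats::median(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "m")
  if (!all(c("early", "late") %in% names(med))) {
    abort("results must contain both 'early' and 'late' halves",
          class = "ecog_inference_error")
  }
  complete <- med[stats::complete.cases(med[, c("early", "late")]), ]
  n_excluded <- nrow(med) - nrow(complete)
  if (nrow(complete) < 2) {
    abort("paired comparison needs at least 2 subjects with both halves",
          class = "ecog_inference_error")
  }
  tt <- safe_t_test(complete$early, complete$late, paired = TRUE,
                    alternative = alternative)
  tibble::tibble(mean_early = mean(complete$early),
                 mean_late = mean(complete$late),
                 estimate = tt$estimate, t = tt$statistic,
                 df = tt$parameter, p = tt$p.value,
                 n_subjects = nrow(complete), n_excluded = n_excluded)
}

#' Early/late signal-to-noise control for STWC comparisons
#'
#' STWC, like any correlation measure, is sensitive to signal-to-noise
#' changes.  Per electrode and trial half, SNR is defined as
#' (mean feedback HG - mean rest HG) / SD of the per-trial rest means;
#' electrodes whose per-trial activation (feedback minus rest mean)
#' decreases significantly from early to late trials (two-sample t-test,
#' p < 0.05) are flagged for exclusion in the repeat analysis.
#'
#' @param env An [ecog_envelope()] covering the session.
#' @param trials Trial table with `rest_on`, `targeting_on`, `feedback_on`,
#'   `reward_on` columns.
#' @return A tibble per electrode: `snr_early`, `snr_late`, `t`, `p`,
#'   `flagged` (significant decrease), `excluded` (degenerate rest SD).
#' @export
snr_control <- function(env, trials) {
  ntr <- nrow(trials)
  halves <- ifelse(seq_len(ntr) <= ntr / 2, "early", "late")
  purrr::map_dfr(seq_along(env$labels), function(i) {
    rest <- vapply(seq_len(ntr), function(j) {
      mean(env$data[i, sample_window(trials$rest_on[j],
                                     trials$targeting_on[j], env$rate)])
    }, numeric(1))
    fb <- vapply(seq_len(ntr), function(j) {
      mean(env$data[i, sample_window(trials$feedback_on[j],
                                     trials$reward_on[j], env$rate)])
    }, numeric(1))
    act <- fb - rest
    snr_half <- function(h) {
      r <- rest[halves == h]; f <- fb[halves == h]
      if (sd(r) == 0) return(NA_real_)
      (mean(f) - mean(r)) / sd(r)
    }
    se <- snr_half("early"); sl <- snr_half("late")
    if (is.na(se) || is.na(sl)) {
      return(tibble::tibble(electrode = env$labels[i], snr_early = se,
                            snr_late = sl, t = NA_real_, p = NA_real_,
                            flagged = FALSE, excluded = TRUE))
    }
    tt <- safe_t_test(act[halves == "early"], act[halves == "late"])
    tibble::tibble(electrode = env$labels[i], snr_early = se, snr_late = sl,
                   t = tt$statistic, p = tt$p.value,
                   flagged = tt$p.value < 0.05 && tt$estimate > 0,
                   excluded = FALSE)
  })
}

#' Spatial comparison of STWC and bPLV interaction distances
#'
#' Computes the Euclidean distance from each significant remote electrode
#' to the controlling electrode, reduces to a per-subject median for each
#' measure (one observation per subject, adjusting for repeated measures),
#' and compares the two median sets with a two-sample t-test.
#'
#' @param stwc_results,bplv_results Tibbles of significant interactions
#'   with columns `subject`, `ctl`, `remote` (electrode names).
#' @param montage Montage tibble with `name`, `x_mm`, `y_mm`, `z_mm` (a
#'   single frame for all subjects, or add a `subject` column).
#' @return A one-row tibble: mean per-subject median distance for each
#'   measure, `t`, `df`, `p`, subject counts, and skipped-pair count.
#' @export
distance_comparison <- function(stwc_results, bplv_results, montage) {
  dist_tbl <- function(res, measure) {
    coords <- function(nm) {
      i <- match(nm, montage$name)
      cbind(montage$x_mm[i], montage$y_mm[i], montage$z_mm[i])
    }
    a <- coords(res$ctl); b <- coords(res$remote)
    d <- sqrt(rowSums((a - b)^2))
    ok <- is.finite(d)
    tibble::tibble(subject = res$subject[ok], distance_mm = d[ok],
                   measure = measure, skipped = sum(!ok))
  }
  ds <- dist_tbl(stwc_results, "stwc")
  db <- dist_tbl(bplv_results, "bplv")
  med <- dplyr::bind_rows(ds, db) |>
    dplyr::group_by(.data$measure, .data$subject) |>
    dplyr::summarise(d = stats::median(.data$distance_mm), .groups = "drop")
  ms <- med$d[med$measure == "stwc"]
  mb <- med$d[med$measure == "bplv"]
  if (length(ms) < 2 || length(mb) < 2) {
    abort("distance comparison needs >= 2 subjects per measure",
          class = "ecog_inference_error")
  }
  tt <- safe_t_test(ms, mb)
  tibble::tibble(mean_stwc_mm = mean(ms), mean_bplv_mm = mean(mb),
                 t = tt$statistic, df = tt$parameter, p = tt$p.value,
                 n_stwc = length(ms), n_bplv = length(mb),
                 n_skipped = ds$skipped[1] + db$skipped[1])
}

#' Euclidean electrode distance
#' @param montage Montage tibble.
#' @param a,b Electrode names.
#' @return Distance in mm.
#' @export
electrode_distance <- function(montage, a, b) {
  i <- match(a, montage$name); j <- match(b, montage$name)
  if (is.na(i) || is.na(j)) {
    abort("unknown electrode name", class = "ecog_lookup_error")
  }
  sqrt((montage$x_mm[i] - montage$x_mm[j])^2 +
       (montage$y_mm[i] - montage$y_mm[j])^2 +
       (montage$z_mm[i] - montage$z_mm[j])^2)
}
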