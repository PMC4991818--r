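#' Pipeline configuration
#'
#' Assembles every setting for a full session analysis.  Exactly one input
#' source must be given: a `simulate` block ([sim_config()] plus optional
#' injection specs), or paths to a recording (EDF or TSV-matrix prefix),
#' an events TSV and a montage TSV.
#'
#' @param simulate Optional [sim_config()].
#' @param amp_specs,phase_specs Injection specs for the simulate block.
#' @param recording,events,montage Input paths (alternative to `simulate`).
#' @param subject Subject identifier used in reports.
#' @param band Envelope band, Hz.
#' @param stwc An [stwc_params()].
#' @param cue_window Cue-locked peak search window (s from feedback onset).
#' @param response_window Response-locked peak search window (s from onset).
#' @param bplv_f1,bplv_f2 bPLV frequency grids (1 Hz steps).
#' @param bplv_epoch Epoch window around the alignment zero, seconds.
#' @param bplv_integrate Integration interval, seconds.
#' @param n_iter STWC surrogate iterations.
#' @param n_resamples bPLV trial-shuffle resamples.
#' @param run_linear_plv Whether to run the linear PLV control.
#' @param plv_freqs Frequencies for the linear PLV control, Hz.
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Optional output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, amp_specs = list(),
                            phase_specs = list(),
                            recording = NULL, events = NULL, montage = NULL,
                            subject = "S1",
                            band = c(70, 150), stwc = stwc_params(),
                            cue_window = c(0, 1),
                            response_window = c(-0.5, 0.5),
                            bplv_f1 = 7:25, bplv_f2 = 70:100,
                            bplv_epoch = c(-3, 2.5),
                            bplv_integrate = c(0, 1),
                            n_iter = 100, n_resamples = 2000,
                            run_linear_plv = TRUE,
                            plv_freqs = seq(1, 199),
                            seed = 1, out_dir = NULL) {
  has_sim <- !is.null(simulate)
  has_paths <- !is.null(recording) && !is.null(events) && !is.null(montage)
  if (has_sim == has_paths) {
    abort("exactly one of `simulate` or input paths must be given",
          class = "ecog_config_error")
  }
  if (has_paths) {
    for (p in c(events, montage)) {
      if (!file.exists(p)) abort(sprintf("input file '%s' does not exist", p),
                                 class = "ecog_config_error")
    }
  }
  structure(list(simulate = simulate, amp_specs = amp_specs,
                 phase_specs = phase_specs, recording = recording,
                 events = events, montage = montage, subject = subject,
                 band = band, stwc = stwc, cue_window = cue_window,
                 response_window = response_window,
                 bplv_f1 = bplv_f1, bplv_f2 = bplv_f2,
                 bplv_epoch = bplv_epoch, bplv_integrate = bplv_integrate,
                 n_iter = n_iter, n_resamples = n_resamples,
                 run_linear_plv = run_linear_plv, plv_freqs = plv_freqs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_session <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    return(simulate_session(sim, config$amp_specs, config$phase_specs))
  }
  rec <- if (file.exists(config$recording) &&
             grepl("\\.edf$", config$recording, ignore.case = TRUE)) {
    read_edf(config$recording)
  } else {
    read_recording_tsv(config$recording)
  }
  montage <- read_montage_tsv(config$montage)
  rec$good <- montage$good[match(rec$labels, montage$name)]
  ctl <- montage$name[montage$is_ctl][1]
  structure(list(recording = rec, trials = read_events_tsv(config$events),
                 montage = montage,
                 config = list(ctl_channel = ctl, seed = config$seed),
                 truth = NULL),
            class = "ecog_session")
}

# STWC arm over one alignment: observed per-pair average maps + peaks +
# surrogate significance, plus per-half (early/late trial) peaks.
stwc_arm <- function(env, zeros, trial_ids, remotes, ctl, config,
                     epoch_window, analysis_window, alignment, log) {
  rate <- env$rate
  ex <- epoch_channel(env, ctl, zeros, epoch_window)
  eys <- lapply(remotes, function(ch) epoch_channel(env, ch, zeros,
                                                    epoch_window))
  names(eys) <- remotes
  maps <- lapply(eys, function(ey) {
    stwc_pair_map(ex, ey, rate, config$stwc, zero_s = epoch_window[1])
  })
  peaks <- purrr::map_dfr(remotes, function(ch) {
    dplyr::mutate(extract_peak(maps[[ch]], analysis_window),
                  remote = ch, .before = 1)
  })
  null <- stwc_null(ex, eys, rate, config$stwc, analysis_window,
                    zero_s = epoch_window[1], n_iter = config$n_iter,
                    seed = derive_seed(config$seed, paste0("stwc_", alignment)))
  peaks <- stwc_significance(peaks, null) |>
    dplyr::mutate(subject = config$subject, ctl = ctl,
                  alignment = alignment, .before = 1)
  # early/late: per-pair peaks on each half of the session's trials
  n_all <- length(zeros)
  first_half <- seq_len(n_all) <= n_all / 2
  halves <- purrr::map_dfr(c("early", "late"), function(h) {
    keep <- if (h == "early") first_half else !first_half
    if (sum(keep) < 2) return(tibble::tibble())
    purrr::map_dfr(remotes, function(ch) {
      m <- stwc_pair_map(ex[, keep, drop = FALSE],
                         eys[[ch]][, keep, drop = FALSE],
                         rate, config$stwc, zero_s = epoch_window[1])
      dplyr::mutate(extract_peak(m, analysis_window),
                    remote = ch, half = h, .before = 1)
    })
  })
  log(sprintf("stwc %s: %d pairs, %d trials, %d significant",
              alignment, length(remotes), n_all, sum(peaks$significant)))
  list(peaks = peaks, maps = maps, null = null, halves = halves)
}

# bPLV arm over one alignment: per-pair trial-shuffle inference.
bplv_arm <- function(broad, zeros, remotes, ctl, config, alignment, log) {
  src_freqs <- sort(unique(c(config$bplv_f1, config$bplv_f2)))
  fsum <- seq(min(config$bplv_f1) + min(config$bplv_f2),
              max(config$bplv_f1) + max(config$bplv_f2))
  ex <- epoch_channel(broad, ctl, zeros, config$bplv_epoch)
  tax <- config$bplv_epoch[1] +
    (seq_len(nrow(ex)) - 1) / broad$rate
  src <- wavelet_phase(ex, broad$rate, src_freqs, time_s = tax)
  res <- purrr::map_dfr(remotes, function(ch) {
    ey <- epoch_channel(broad, ch, zeros, config$bplv_epoch)
    tgt <- wavelet_phase(ey, broad$rate, fsum, time_s = tax)
    nl <- bplv_null(src, tgt, config$bplv_f1, config$bplv_f2,
                    t0 = config$bplv_integrate[1],
                    t1 = config$bplv_integrate[2],
                    n_resamples = config$n_resamples,
                    n_pairs = length(remotes),
                    seed = derive_seed(config$seed,
                                       paste0("bplv_", alignment, "_", ch)))
    am <- which(nl$observed$values == max(nl$observed$values),
                arr.ind = TRUE)[1, ]
    tibble::tibble(subject = config$subject, ctl = ctl, remote = ch,
                   alignment = alignment,
                   value = max(nl$observed$values),
                   f1 = config$bplv_f1[am[1]], f2 = config$bplv_f2[am[2]],
                   p = nl$p, p_corrected = nl$p_corrected,
                   significant = nl$significant)
  })
  log(sprintf("bplv %s: %d pairs, %d trials, %d significant",
              alignment, length(remotes), length(zeros),
              sum(res$significant)))
  res
}

#' Run the full session analysis pipeline
#'
#' Executes preprocessing (common average reference, notch, high-gamma
#' envelope + smoothing + 400 Hz resampling, and a broadband 400 Hz path
#' for phases), high-gamma onset detection and response-locked
#' realignment, cue-locked and response-locked STWC with surrogate
#' max-statistic inference, cue-locked and response-locked bPLV with
#' trial-shuffle inference, the linear PLV control, behavioral chance
#' bounds, the early/late SNR control, per-region summaries and
#' CTL-distance tables.  With `out_dir` set, writes interaction tables
#' (TSV), a machine-readable JSON summary, and a stage log; reruns with
#' the same config and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `session_report` list (tables, maps, summary).
#' @export
run_pipeline <- function(config) {
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  session <- load_session(config)
  rec <- session$recording
  trials <- session$trials
  ctl <- session$config$ctl_channel
  remotes <- setdiff(rec$labels[rec$good], ctl)
  log(sprintf("loaded session '%s': %d channels, %d trials, CTL = %s",
              config$subject, nrow(rec$data), nrow(trials), ctl))

  env <- preprocess_envelope(rec, band = config$band)
  broad <- preprocess_broadband(rec)
  log("preprocessed: envelope + broadband paths at 400 Hz")

  trials <- detect_session_onsets(env, trials, ctl)
  resp <- realign_trials(trials)
  log(sprintf("realignment: %d/%d up-target trials with detected onsets",
              nrow(resp), sum(trials$target == "up")))

  margin <- (config$stwc$window_ms / 2 + config$stwc$max_lag_ms) / 1000 + 0.05
  cue_epoch <- c(config$cue_window[1] - margin, config$cue_window[2] + margin)
  resp_epoch <- c(config$response_window[1] - margin,
                  config$response_window[2] + margin)

  stwc_cue <- stwc_arm(env, trials$feedback_on, trials$trial, remotes, ctl,
                       config, cue_epoch, config$cue_window, "cue", log)
  stwc_resp <- if (nrow(resp) >= 2) {
    stwc_arm(env, resp$response_zero, resp$trial, remotes, ctl, config,
             resp_epoch, config$response_window, "response", log)
  } else {
    log("stwc response: skipped (fewer than 2 realigned trials)")
    NULL
  }

  up <- trials[trials$target == "up", ]
  bplv_cue <- if (nrow(up) >= 5) {
    bplv_arm(broad, up$feedback_on, remotes, ctl, config, "cue", log)
  } else {
    log("bplv cue: skipped (fewer than 5 up-target trials)")
    NULL
  }
  bplv_resp <- if (nrow(resp) >= 5) {
    bplv_arm(broad, resp$response_zero, remotes, ctl, config, "response", log)
  } else {
    log("bplv response: skipped (fewer than 5 realigned trials)")
    NULL
  }

  plv <- NULL
  if (config$run_linear_plv && nrow(up) >= 2) {
    ex <- epoch_channel(broad, ctl, up$feedback_on, config$bplv_epoch)
    px <- wavelet_phase(ex, broad$rate, config$plv_freqs)
    plv <- purrr::map_dfr(remotes, function(ch) {
      ey <- epoch_channel(broad, ch, up$feedback_on, config$bplv_epoch)
      py <- wavelet_phase(ey, broad$rate, config$plv_freqs)
      sp <- tidy(linear_plv(px, py))
      tibble::tibble(remote = ch, peak_plv = max(sp$plv),
                     peak_freq_hz = sp$freq_hz[which.max(sp$plv)])
    })
    log("linear PLV control computed")
  }

  behavior <- chance_performance_ci(nrow(trials),
                                    seed = derive_seed(config$seed, "chance"))
  behavior$observed <- mean(trials$outcome == "hit")

  snr <- snr_control(env, trials)
  regions <- summarize_regions(
    dplyr::filter(stwc_cue$peaks, .data$significant), session$montage)

  sig_all <- function(arm) {
    if (is.null(arm)) return(tibble::tibble())
    dplyr::filter(arm$peaks, .data$significant)
  }
  dist_for <- function(res) {
    if (is.null(res) || nrow(res) == 0) return(tibble::tibble())
    res$distance_mm <- vapply(res$remote, function(ch)
      electrode_distance(session$montage, ctl, ch), numeric(1))
    res
  }
  distances <- dplyr::bind_rows(
    dist_for(dplyr::filter(stwc_cue$peaks, .data$significant)) |>
      dplyr::mutate(measure = "stwc"),
    dist_for(if (!is.null(bplv_cue))
      dplyr::filter(bplv_cue, .data$significant) else NULL) |>
      dplyr::mutate(measure = "bplv"))

  report <- structure(list(
    subject = config$subject, config = config, trials = trials,
    realigned = resp, montage = session$montage,
    stwc_cue = stwc_cue, stwc_response = stwc_resp,
    bplv_cue = bplv_cue, bplv_response = bplv_resp,
    linear_plv = plv, behavior = behavior, snr = snr,
    regions = regions, distances = distances,
    truth = session$truth, log = log_lines
  ), class = "session_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> subject %s\n", x$subject))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

round_num <- function(x, digits = 10) {
  if (is.numeric(x)) round(x, digits) else x
}

#' One-row summary of a session report
#' @param x A `session_report`.
#' @param ... Unused.
#' @return A tibble of headline counts and behavioral numbers.
#' @method glance session_report
#' @export
glance.session_report <- function(x, ...) {
  tibble::tibble(
    subject = x$subject,
    n_trials = nrow(x$trials),
    n_realigned = nrow(x$realigned),
    observed_performance = x$behavior$observed,
    chance_lo = x$behavior$lo, chance_hi = x$behavior$hi,
    stwc_cue_significant = sum(x$stwc_cue$peaks$significant),
    stwc_response_significant = if (is.null(x$stwc_response)) 0L
      else sum(x$stwc_response$peaks$significant),
    bplv_cue_significant = if (is.null(x$bplv_cue)) 0L
      else sum(x$bplv_cue$significant),
    bplv_response_significant = if (is.null(x$bplv_response)) 0L
      else sum(x$bplv_response$significant)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      readr::write_tsv(df, file.path(out_dir, name))
    }
  }
  wr(report$stwc_cue$peaks, "stwc_cue_interactions.tsv")
  if (!is.null(report$stwc_response)) {
    wr(report$stwc_response$peaks, "stwc_response_interactions.tsv")
  }
  wr(report$bplv_cue, "bplv_cue_interactions.tsv")
  wr(report$bplv_response, "bplv_response_interactions.tsv")
  wr(report$linear_plv, "linear_plv.tsv")
  wr(report$snr, "snr_control.tsv")
  wr(report$regions, "region_summary.tsv")
  wr(report$distances, "distances.tsv")
  wr(report$trials, "trials_with_onsets.tsv")
  summary <- list(
    subject = report$subject,
    seed = report$config$seed,
    n_trials = nrow(report$trials),
    n_realigned = nrow(report$realigned),
    behavior = lapply(as.list(report$behavior), round_num),
    stwc_cue = lapply(
      split(report$stwc_cue$peaks, report$stwc_cue$peaks$remote),
      function(r) lapply(as.list(r[, c("coef", "lag_ms", "t_s", "p",
                                       "significant")]), round_num)),
    bplv_cue = if (is.null(report$bplv_cue)) NULL else lapply(
      split(report$bplv_cue, report$bplv_cue$remote),
      function(r) lapply(as.list(r[, c("value", "f1", "f2", "p_corrected",
                                       "significant")]), round_num)),
    log = report$log
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Per-region summary of significant interactions
#'
#' Counts significant interactions per cortical region (montage labels;
#' unlabeled electrodes are grouped as "unknown"), with the integer-rounded
#' percentage of the total, per-region mean peak coefficient and mean lag,
#' and a two-sample t-test of each region's coefficients against all other
#' regions pooled.
#'
#' @param results Tibble of significant interactions with a `remote`
#'   column and optionally `coef` and `lag_ms`.
#' @param montage Montage tibble with `name` and `region`.
#' @return A tibble: `region`, `n`, `fraction_pct`, `mean_coef`,
#'   `mean_lag_ms`, `t`, `p`.
#' @export
summarize_regions <- function(results, montage) {
  if (nrow(results) == 0) {
    return(tibble::tibble(region = unique(montage$region), n = 0L,
                          fraction_pct = 0L, mean_coef = NA_real_,
                          mean_lag_ms = NA_real_, t = NA_real_, p = NA_real_))
  }
  reg <- montage$region[match(results$remote, montage$name)]
  reg[is.na(reg) | reg == ""] <- "unknown"
  results$region <- reg
  total <- nrow(results)
  has_coef <- "coef" %in% names(results)
  results |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_coef = if (has_coef) mean(.data$coef) else NA_real_,
      mean_lag_ms = if ("lag_ms" %in% names(results))
        mean(.data$lag_ms) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(fraction_pct = as.integer(round(100 * .data$n / total))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      t = if (has_coef && .data$n >= 2 && total - .data$n >= 2) {
        safe_t_test(results$coef[results$region == .data$region],
                    results$coef[results$region != .data$region])$statistic
      } else NA_real_,
      p = if (has_coef && .data$n >= 2 && total - .data$n >= 2) {
        safe_t_test(results$coef[results$region == .data$region],
                    results$coef[results$region != .data$region])$p.value
      } else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::select("region", "n", "fraction_pct", "mean_coef",
                  "mean_lag_ms", "t", "p") |>
    dplyr::arrange(dplyr::desc(.data$n))
}
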