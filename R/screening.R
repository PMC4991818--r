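#' Motor screening: rank candidate controlling electrodes
#'
#' For each electrode, extracts the high-gamma envelope (4th-order
#' Butterworth band-pass plus Hilbert magnitude), averages all samples
#' within each cue (activity) epoch and each inter-trial (rest) epoch to a
#' single per-trial activation value, and compares activity against rest
#' with an unpaired two-sample t-test.  Electrodes with p < `alpha` are
#' candidates for BCI control, ranked by effect size (Cohen's d); the
#' final selection among candidates remains a user decision.
#'
#' @param block A `screening_block` (see [simulate_screening_block()]):
#'   list with `recording` and a `cues` tibble (`onset_s`, `duration_s`).
#' @param band Envelope band in Hz (default high gamma, 70-150).
#' @param alpha Candidate significance threshold.
#' @return A tibble (electrode, t, p, d, candidate, rank) ordered by
#'   effect size within the candidate set; empty candidate sets are
#'   reported via a message.
#' @export
screen_electrodes <- function(block, band = c(70, 150), alpha = 0.05) {
  cues <- block$cues
  if (nrow(cues) < 10) {
    abort("motor screening requires at least 10 cue repetitions",
          class = "ecog_config_error")
  }
  rec <- block$recording
  env <- band_envelope(rec, band = band)
  rest_windows <- tibble::tibble(
    onset_s = cues$onset_s + cues$duration_s,
    duration_s = c(cues$onset_s[-1], ncol(rec$data) / rec$rate) -
      (cues$onset_s + cues$duration_s)
  )
  per_trial_means <- function(i, wins) {
    vapply(seq_len(nrow(wins)), function(k) {
      mean(env$data[i, sample_window(wins$onset_s[k],
                                     wins$onset_s[k] + wins$duration_s[k],
                                     env$rate)])
    }, numeric(1))
  }
  out <- purrr::map_dfr(seq_along(env$labels), function(i) {
    act <- per_trial_means(i, cues)
    rest <- per_trial_means(i, rest_windows)
    tt <- safe_t_test(act, rest)
    pooled <- sqrt(((length(act) - 1) * var(act) +
                    (length(rest) - 1) * var(rest)) /
                   (length(act) + length(rest) - 2))
    d <- if (pooled == 0) 0 else (mean(act) - mean(rest)) / pooled
    tibble::tibble(electrode = env$labels[i], t = tt$statistic,
                   p = tt$p.value, d = d)
  })
  out <- out |>
    dplyr::mutate(candidate = .data$p < alpha & .data$d > 0) |>
    dplyr::arrange(dplyr::desc(.data$candidate), dplyr::desc(.data$d)) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (!any(out$candidate)) {
    rlang::inform("no candidate electrodes at the screening threshold")
  }
  out
}
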