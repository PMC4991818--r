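pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Minimal European Data Format (EDF, 16-bit) writer: one data record per
#' second, per-channel physical scaling from the data range.  The sampling
#' rate must be an integer; a final partial second is zero-padded.
#'
#' @param rec An [ecog_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rate <- as.integer(round(rec$rate))
  if (abs(rate - rec$rate) > 1e-9) {
    abort("EDF writer requires an integer sampling rate",
          class = "ecog_config_error")
  }
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / rate)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  same <- pmax_ - pmin_ < 1e-12
  pmin_[same] <- pmin_[same] - 1
  pmax_[same] <- pmax_[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(paste0(pad_ascii(x, w), collapse = ""),
                                 con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (f in list(list(rec$labels, 16), list(rep("", ns), 80),
                 list(rep("uV", ns), 8),
                 list(formatC(pmin_, digits = 6, format = "g"), 8),
                 list(formatC(pmax_, digits = 6, format = "g"), 8),
                 list(rep("-32768", ns), 8), list(rep("32767", ns), 8),
                 list(rep("", ns), 80), list(rep(as.character(rate), ns), 8),
                 list(rep("", ns), 32))) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):min(r * rate, n)
    for (i in seq_len(ns)) {
      x <- rec$data[i, idx]
      if (length(x) < rate) x <- c(x, rep(0, rate - length(x)))
      dig <- as.integer(round((x - pmin_[i]) * scale[i]) - 32768)
      writeBin(pmin(32767L, pmax(-32768L, dig)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF files with a uniform per-signal rate, rescaling digital
#' values to physical units.
#'
#' @param path EDF file path.
#' @param good Optional logical good-channel mask.
#' @return An [ecog_recording()].
#' @export
read_edf <- function(path, good = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (k in seq_len(ns)) rd(80)             # transducer
  for (k in seq_len(ns)) rd(8)              # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (k in seq_len(ns)) rd(80)             # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (k in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    abort("mixed per-signal rates are not supported",
          class = "ecog_config_error")
  }
  rate <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) /
        (dmax_[i] - dmin_[i])
      data[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- phys
    }
  }
  if (is.null(good)) good <- rep(TRUE, ns)
  ecog_recording(data, rate, labels = labels, good = good)
}

#' Write a trial/event table as TSV
#'
#' Long format, one row per task phase, UTF-8 tab-separated with columns
#' `onset_s`, `duration_s`, `phase`, `target`, `outcome`.  A detected-onset
#' column `hg_onset_s` is appended when onsets are present.
#'
#' @param trials Wide trial table (see [simulate_session()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  long <- purrr::map_dfr(seq_len(nrow(trials)), function(j) {
    on <- c(trials$rest_on[j], trials$targeting_on[j],
            trials$feedback_on[j], trials$reward_on[j])
    tibble::tibble(
      onset_s = on,
      duration_s = c(diff(on), trials$end_s[j] - trials$reward_on[j]),
      phase = c("rest", "targeting", "feedback", "reward"),
      target = trials$target[j],
      outcome = trials$outcome[j],
      hg_onset_s = if ("onset_time" %in% names(trials))
        trials$onset_time[j] else NA_real_
    )
  })
  if (all(is.na(long$hg_onset_s))) long$hg_onset_s <- NULL
  readr::write_tsv(long, path)
  invisible(path)
}

#' Read a trial/event TSV back into a wide trial table
#'
#' @param path Events TSV path (see [write_events_tsv()]).
#' @return A wide trial table tibble.
#' @export
read_events_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("onset_s", "duration_s", "phase", "target", "outcome")
  if (!all(need %in% names(long))) {
    abort("events file lacks required columns", class = "ecog_config_error")
  }
  starts <- which(long$phase == "rest")
  purrr::map_dfr(seq_along(starts), function(k) {
    rows <- long[starts[k]:(starts[k] + 3L), ]
    if (!identical(rows$phase, c("rest", "targeting", "feedback", "reward"))) {
      abort("trial phases must cycle rest/targeting/feedback/reward",
            class = "ecog_config_error")
    }
    tibble::tibble(
      trial = k,
      target = rows$target[1], outcome = rows$outcome[1],
      rest_on = rows$onset_s[1], targeting_on = rows$onset_s[2],
      feedback_on = rows$onset_s[3], reward_on = rows$onset_s[4],
      end_s = rows$onset_s[4] + rows$duration_s[4],
      cue_time = rows$onset_s[3],
      onset_time = if ("hg_onset_s" %in% names(rows))
        rows$hg_onset_s[1] else NA_real_
    )
  })
}

#' Write / read an electrode montage TSV
#'
#' Tab-separated montage with columns `name`, `x_mm`, `y_mm`, `z_mm`,
#' `region`, `good`, `is_ctl`.
#'
#' @param montage Montage tibble.
#' @param path File path.
#' @return `path` (writer) or the montage tibble (reader).
#' @export
write_montage_tsv <- function(montage, path) {
  readr::write_tsv(montage[, c("name", "x_mm", "y_mm", "z_mm", "region",
                               "good", "is_ctl")], path)
  invisible(path)
}

#' @rdname write_montage_tsv
#' @export
read_montage_tsv <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm", "region", "good", "is_ctl")
  if (!all(need %in% names(m))) {
    abort("montage file lacks required columns", class = "ecog_config_error")
  }
  m
}

#' Write / read a recording as a plain text matrix with sidecar header
#'
#' The data file is a TSV with one column per channel (header row = channel
#' labels) and one row per sample; the sidecar JSON carries `rate` and the
#' `good` mask.  Intended for small fixtures and interchange without EDF.
#'
#' @param rec An [ecog_recording()].
#' @param prefix Path prefix: writes `<prefix>_data.tsv` and
#'   `<prefix>_header.json`.
#' @return `prefix` (writer) or an [ecog_recording()] (reader).
#' @export
write_recording_tsv <- function(rec, prefix) {
  df <- tibble::as_tibble(t(rec$data))
  names(df) <- rec$labels
  readr::write_tsv(df, paste0(prefix, "_data.tsv"))
  jsonlite::write_json(list(rate = rec$rate, labels = rec$labels,
                            good = rec$good),
                       paste0(prefix, "_header.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, "_header.json"),
                             simplifyVector = TRUE)
  df <- readr::read_tsv(paste0(prefix, "_data.tsv"), show_col_types = FALSE)
  ecog_recording(t(as.matrix(df)), rate = hdr$rate, labels = hdr$labels,
                 good = hdr$good)
}
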