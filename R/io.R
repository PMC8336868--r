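#' Write / read the plain epochs-table format
#'
#' A plain-text CSV interchange format for epoched recordings: a `#`-prefixed
#' metadata header (`sampling_rate`, `onset_index`, `channels`, per-trial
#' labels) followed by one row per trial x channel x sample with columns
#' `trial`, `channel`, `sample_index`, `value`. The round trip
#' `read_epochs_table(write_epochs_table(rec))` reproduces the recording
#' exactly (values are written with shortest round-trippable precision).
#'
#' @param rec an [epoched_recording()].
#' @param path file path.
#' @return `write_epochs_table()` returns `path` invisibly;
#'   `read_epochs_table()` returns an [epoched_recording()].
#' @export
write_epochs_table <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- dim(rec$data)
  onset_index <- which.min(abs(rec$time_axis))
  meta_str <- paste(
    paste(rec$meta$trial, rec$meta$task, rec$meta$session, rec$meta$day,
          sep = ":"),
    collapse = ";"
  )
  header <- c(
    "# miconn epochs-table v1",
    paste0("# sampling_rate=", format(rec$sampling_rate, digits = 15)),
    paste0("# onset_index=", onset_index),
    paste0("# n_trials=", d[1]),
    paste0("# n_channels=", d[2]),
    paste0("# n_samples=", d[3]),
    paste0("# channels=", paste(rec$montage$channels, collapse = ",")),
    paste0("# trial_meta=", meta_str)
  )
  tab <- tibble::tibble(
    trial = rep(rec$meta$trial, each = d[2] * d[3]),
    channel = rep(rep(rec$montage$channels, each = d[3]), times = d[1]),
    sample_index = rep(seq_len(d[3]), times = d[1] * d[2]),
    value = as.vector(aperm(rec$data, c(3, 2, 1)))
  )
  readr::write_lines(header, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

parse_header_field <- function(lines, key) {
  hit <- grep(paste0("^# ", key, "="), lines, value = TRUE)
  if (length(hit) == 0) {
    stop("epochs table is missing the '", key, "' metadata header",
         call. = FALSE)
  }
  sub(paste0("^# ", key, "="), "", hit[1])
}

#' @rdname write_epochs_table
#' @export
read_epochs_table <- function(path) {
  head_lines <- grep("^#", readr::read_lines(path, n_max = 50), value = TRUE)
  fs <- as.numeric(parse_header_field(head_lines, "sampling_rate"))
  onset_index <- as.integer(parse_header_field(head_lines, "onset_index"))
  n_trials <- as.integer(parse_header_field(head_lines, "n_trials"))
  n_channels <- as.integer(parse_header_field(head_lines, "n_channels"))
  n_samples <- as.integer(parse_header_field(head_lines, "n_samples"))
  channels <- strsplit(parse_header_field(head_lines, "channels"), ",")[[1]]
  meta_raw <- strsplit(parse_header_field(head_lines, "trial_meta"), ";")[[1]]
  meta_parts <- strsplit(meta_raw, ":")
  meta <- tibble::tibble(
    trial = as.integer(vapply(meta_parts, `[`, "", 1)),
    task = vapply(meta_parts, `[`, "", 2),
    session = as.integer(vapply(meta_parts, `[`, "", 3)),
    day = as.integer(vapply(meta_parts, `[`, "", 4))
  )
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) != n_trials * n_channels * n_samples) {
    stop("epochs table is ragged: expected ",
         n_trials * n_channels * n_samples, " rows, found ", nrow(tab),
         call. = FALSE)
  }
  counts <- tab |>
    dplyr::count(.data$trial, .data$channel) |>
    dplyr::pull(.data$n)
  if (any(counts != n_samples)) {
    stop("epochs table is ragged: unequal sample counts per trial/channel",
         call. = FALSE)
  }
  montage <- mi_montage()
  if (!setequal(channels, montage$channels)) {
    stop("epochs table channels do not match the 10-20 montage",
         call. = FALSE)
  }
  arr <- array(NA_real_, c(n_trials, n_channels, n_samples))
  ti <- match(tab$trial, meta$trial)
  ci <- match(tab$channel, montage$channels)
  arr[cbind(ti, ci, tab$sample_index)] <- tab$value
  time_axis <- (seq_len(n_samples) - onset_index) / fs
  epoched_recording(arr, fs, time_axis, meta, montage)
}

#' Write / read the per-trial events sidecar CSV
#'
#' Columns: `trial_index`, `session`, `day`, `task_label`, `onset_sample`
#' (1-based first action sample in the continuous record).
#'
#' @param events tibble with the columns above.
#' @param path file path.
#' @return The events tibble (reader) or `path` invisibly (writer).
#' @export
write_events_csv <- function(events, path) {
  required <- c("trial_index", "session", "day", "task_label", "onset_sample")
  stopifnot(all(required %in% names(events)))
  readr::write_csv(events[required], path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("trial_index", "session", "day", "task_label", "onset_sample")
  if (!all(required %in% names(ev))) {
    stop("events table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  for (s in unique(ev$session)) {
    on <- ev$onset_sample[ev$session == s]
    if (any(diff(on) <= 0)) {
      stop("event onsets must be strictly increasing within a session",
           call. = FALSE)
    }
  }
  ev
}

# fixed-width ASCII field helper for the EDF header
edf_field <- function(x, width) {
  s <- strtrim(as.character(x), width)
  formatC(s, width = -width)
}

#' Write a continuous multichannel record as EDF
#'
#' Minimal EDF (16-bit) writer: one 1 s data record per second, per-channel
#' symmetric physical range, physical dimension uV. The trailing partial
#' second is zero-padded.
#'
#' @param signal samples x channels numeric matrix (microvolts).
#' @param sampling_rate Hz (integer).
#' @param path output path.
#' @param channel_labels channel names (default the 10-20 montage order).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, sampling_rate, path,
                      channel_labels = mi_montage()$channels) {
  stopifnot(is.matrix(signal), ncol(signal) == length(channel_labels))
  fs <- as.integer(round(sampling_rate))
  ns <- ncol(signal)
  n_rec <- as.integer(ceiling(nrow(signal) / fs))
  padded <- rbind(signal,
                  matrix(0, n_rec * fs - nrow(signal), ns))
  pmax_raw <- pmax(apply(abs(padded), 2, max), 1e-6)
  # format the physical range into its 8-char header field and re-parse, so
  # writer and reader share the exact same scaling
  pmax_str <- strtrim(formatC(signif(pmax_raw * 1.0001, 6),
                              format = "g", digits = 6), 8)
  pmax <- as.numeric(pmax_str)
  pmin <- -pmax
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("synthetic subject", 80),
    edf_field("miconn simulated MI-BCI session", 80),
    edf_field("01.01.26", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(channel_labels,
                 function(l) edf_field(paste("EEG", l), 16), ""),
          collapse = ""),
    paste(rep(edf_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, function(x) edf_field(format(x), 8), ""),
          collapse = ""),
    paste(vapply(pmax, function(x) edf_field(format(x), 8), ""),
          collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(fs, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    rows <- (r - 1) * fs + seq_len(fs)
    chunk <- padded[rows, , drop = FALSE]
    dig <- round(sweep(sweep(chunk, 2, pmin), 2, scale, "*")) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

# low-level EDF reader: header + physical-valued signal matrix
read_edf_signal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  as.integer(rd(8))                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")      # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1) {
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  }
  if (any(dims != "" & toupper(dims) != "UV")) {
    warning("EDF physical dimension is not uV for all channels; ",
            "values passed through untransformed", call. = FALSE)
  }
  if (any(dims == "")) {
    warning("EDF physical dimension absent; assuming uV", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_rec * spr[1], ns)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    chunk <- matrix(raw, nrow = spr[1], ncol = ns)
    phys <- sweep(sweep(chunk, 2, dmin), 2, gain, "*")
    phys <- sweep(phys, 2, pmin, "+")
    sig[(r - 1) * spr[1] + seq_len(spr[1]), ] <- phys
  }
  list(signal = sig, sampling_rate = fs, labels = labels)
}

#' Read an EDF file and epoch it around event onsets
#'
#' Reads a 16-bit EDF record, normalizes channel labels (strips `EEG `
#' prefixes and reference suffixes, maps T7/T8/P7/P8 to T3/T4/T5/T6),
#' reorders channels to the canonical montage, and cuts epochs at
#' `[onset - 1, onset + 1]` s. Trials whose window exceeds the record are
#' dropped with a warning; the drop count is available as
#' `attr(rec, "dropped_trials")`.
#'
#' @param path EDF file path.
#' @param events events tibble (see [read_events_csv()]) for this record.
#' @param epoch_window epoch bounds in seconds around onset (default
#'   `c(-1, 1)`).
#' @param montage an [mi_montage()].
#' @return An [epoched_recording()].
#' @export
read_edf <- function(path, events, epoch_window = c(-1, 1),
                     montage = mi_montage()) {
  raw <- read_edf_signal(path)
  labels <- normalize_channel_labels(raw$labels)
  missing <- setdiff(montage$channels, labels)
  if (length(missing)) {
    stop("EDF is missing montage channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sig <- raw$signal[, match(montage$channels, labels), drop = FALSE]
  fs <- raw$sampling_rate
  lo <- round(epoch_window[1] * fs)
  hi <- round(epoch_window[2] * fs)
  keep <- events$onset_sample + lo >= 1 &
    events$onset_sample + hi <= nrow(sig)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warning(n_drop, " trial(s) dropped: epoch window exceeds the record",
            call. = FALSE)
  }
  ev <- events[keep, ]
  if (nrow(ev) == 0) {
    stop("no trials remain after boundary filtering", call. = FALSE)
  }
  n_samp <- hi - lo + 1
  arr <- array(0, c(nrow(ev), length(montage$channels), n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset_sample[i] + lo:hi
    arr[i, , ] <- t(sig[idx, ])
  }
  meta <- tibble::tibble(trial = ev$trial_index, task = ev$task_label,
                         session = ev$session, day = ev$day)
  rec <- epoched_recording(arr, fs, (lo:hi) / fs, meta, montage)
  attr(rec, "dropped_trials") <- n_drop
  rec
}

#' Write a simulated recording as an EDF session set
#'
#' One EDF file per session (`session<k>.edf`) plus a single events sidecar
#' (`events.csv`). Requires a simulation created with
#' `keep_continuous = TRUE`.
#'
#' @param sim an `mi_simulation` from [simulate_recording()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `edf` (file paths) and `events` (path).
#' @export
write_simulation_edf <- function(sim, dir) {
  stopifnot(inherits(sim, "mi_simulation"))
  if (is.null(sim$continuous)) {
    stop("simulate_recording() must be run with keep_continuous = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- sim$recording$sampling_rate
  paths <- character(length(sim$continuous))
  for (s in seq_along(sim$continuous)) {
    paths[s] <- file.path(dir, sprintf("session%d.edf", s))
    write_edf(sim$continuous[[s]]$signal, fs, paths[s])
  }
  events <- dplyr::bind_rows(purrr::map(sim$continuous, "events"))
  ev_path <- file.path(dir, "events.csv")
  write_events_csv(events, ev_path)
  invisible(list(edf = paths, events = ev_path))
}

#' Read an EDF session set written by [write_simulation_edf()]
#'
#' @param dir directory containing `session<k>.edf` files and `events.csv`.
#' @param epoch_window epoch bounds in seconds (default `c(-1, 1)`).
#' @return An [epoched_recording()] with all sessions concatenated; the
#'   total boundary-drop count is in `attr(rec, "dropped_trials")`.
#' @export
read_edf_sessions <- function(dir, epoch_window = c(-1, 1)) {
  events <- read_events_csv(file.path(dir, "events.csv"))
  sessions <- sort(unique(events$session))
  recs <- purrr::map(sessions, function(s) {
    read_edf(file.path(dir, sprintf("session%d.edf", s)),
             events[events$session == s, ], epoch_window)
  })
  out <- bind_recordings(recs)
  attr(out, "dropped_trials") <-
    sum(vapply(recs, function(r) attr(r, "dropped_trials"), numeric(1)))
  out
}
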