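#' Construct an epoched EEG recording
#'
#' The central signal container: a trials x channels x samples array of
#' microvolt values epoched around action onset, with per-trial metadata.
#' Downstream verbs ([select_trials()], [bandpass()], [make_trial_blocks()],
#' [musc_series()], ...) all take and/or return this container or tibbles
#' derived from it.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param time_axis numeric vector of length `dim(data)[3]`, seconds relative
#'   to action onset; must be strictly increasing with uniform step
#'   `1/sampling_rate`.
#' @param meta tibble with one row per trial and columns `trial`
#'   (chronological index), `task` (one of `"left"`, `"right"`, `"hold"`),
#'   `session` (integer), `day` (integer).
#' @param montage an [mi_montage()]; `dim(data)[2]` must equal the montage
#'   channel count and the channel order is taken to be the montage order.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, sampling_rate, time_axis, meta,
                              montage = mi_montage()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  if (length(time_axis) != dim(data)[3]) {
    stop("time_axis length must match the sample dimension", call. = FALSE)
  }
  steps <- diff(time_axis)
  if (any(steps <= 0) ||
      max(abs(steps - 1 / sampling_rate)) > 1e-6 / sampling_rate) {
    stop("time_axis must be strictly increasing with uniform step 1/sampling_rate",
         call. = FALSE)
  }
  if (dim(data)[2] != length(montage$channels)) {
    stop("channel dimension must match the montage (",
         length(montage$channels), " channels)", call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  required <- c("trial", "task", "session", "day")
  if (!all(required %in% names(meta))) {
    stop("meta must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) != dim(data)[1]) {
    stop("meta must have one row per trial", call. = FALSE)
  }
  if (!all(meta$task %in% c("left", "right", "hold"))) {
    stop("task labels must be left/right/hold", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  dimnames(data) <- list(NULL, montage$channels, NULL)
  structure(
    list(data = data, sampling_rate = sampling_rate,
         time_axis = as.numeric(time_axis), meta = meta, montage = montage),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_recording> ", d[1], " trials x ", d[2], " channels x ",
      d[3], " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("  window: [", min(x$time_axis), ", ", max(x$time_axis),
      "] s around action onset\n", sep = "")
  tab <- table(x$meta$task)
  cat("  tasks:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  sessions:", paste(sort(unique(x$meta$session)), collapse = " "),
      " days:", paste(sort(unique(x$meta$day)), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in a recording
#' @param rec an [epoched_recording()].
#' @return Integer trial count.
#' @export
n_trials <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  dim(rec$data)[1]
}

#' Tidy view of an epoched recording
#'
#' Long format: one row per trial x channel x sample. Intended for plotting
#' and interactive exploration of small selections, not as the compute path.
#'
#' @param x an [epoched_recording()].
#' @param ... unused.
#' @return A tibble with columns `trial`, `task`, `session`, `day`,
#'   `channel`, `time`, `value`.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(x$meta$trial, times = d[2] * d[3]),
    task = rep(x$meta$task, times = d[2] * d[3]),
    session = rep(x$meta$session, times = d[2] * d[3]),
    day = rep(x$meta$day, times = d[2] * d[3]),
    channel = rep(rep(x$montage$channels, each = d[1]), times = d[3]),
    time = rep(x$time_axis, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Subset trials by task label and/or session
#'
#' Preserves chronological order; metadata is filtered consistently. The
#' usual first step is dropping the no-imagery "hold" trials:
#' `select_trials(rec, tasks = c("left", "right"))`.
#'
#' @param rec an [epoched_recording()].
#' @param tasks character vector of task labels to keep (default: all).
#' @param sessions integer vector of sessions to keep (default: all).
#' @param days integer vector of days to keep (default: all).
#' @return An [epoched_recording()] with the selected trials.
#' @export
select_trials <- function(rec, tasks = NULL, sessions = NULL, days = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  keep <- rep(TRUE, n_trials(rec))
  if (!is.null(tasks)) keep <- keep & rec$meta$task %in% tasks
  if (!is.null(sessions)) keep <- keep & rec$meta$session %in% sessions
  if (!is.null(days)) keep <- keep & rec$meta$day %in% days
  if (!any(keep)) {
    stop("trial selection is empty (tasks=",
         paste(tasks, collapse = ","), " sessions=",
         paste(sessions, collapse = ","), ")", call. = FALSE)
  }
  out <- rec
  out$data <- rec$data[keep, , , drop = FALSE]
  out$meta <- rec$meta[keep, ]
  out
}

#' Concatenate epoched recordings (e.g. across days)
#'
#' @param ... [epoched_recording()] objects sharing sampling rate, time axis
#'   and montage.
#' @return A single [epoched_recording()]; trials keep their metadata and are
#'   stacked in the order given.
#' @export
bind_recordings <- function(...) {
  recs <- list(...)
  if (length(recs) == 1 && is.list(recs[[1]]) &&
      !inherits(recs[[1]], "epoched_recording")) {
    recs <- recs[[1]]
  }
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, TRUE, "epoched_recording")))
  r1 <- recs[[1]]
  for (r in recs[-1]) {
    if (r$sampling_rate != r1$sampling_rate ||
        length(r$time_axis) != length(r1$time_axis) ||
        max(abs(r$time_axis - r1$time_axis)) > 1e-9) {
      stop("recordings to bind must share sampling rate and time axis",
           call. = FALSE)
    }
  }
  dat <- do.call(abind3, lapply(recs, function(r) r$data))
  meta <- dplyr::bind_rows(lapply(recs, function(r) r$meta))
  epoched_recording(dat, r1$sampling_rate, r1$time_axis, meta, r1$montage)
}

# rbind for 3-d arrays along the trial dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# sample indices of the rest ([-1, 0) s) and task ([0, 1) s) windows
window_indices <- function(rec, window = c("task", "rest")) {
  window <- match.arg(window)
  t <- rec$time_axis
  if (window == "task") which(t >= 0 & t < 1) else which(t >= -1 & t < 0)
}
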