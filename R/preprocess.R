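#' Band definitions and the five-band scan grid
#'
#' The scan grid used for the initial degree-of-nodes inspection covers
#' 0.53-4, 3-6, 5-10, 8-16 and 15-30 Hz; the main analysis band is 3-30 Hz.
#'
#' @param lo,hi band edges in Hz.
#' @param name optional band name.
#' @return `band_definition()`: a one-row tibble with `name`, `lo`, `hi`.
#'   `band_grid()`: the default scan grid as a tibble.
#' @export
band_definition <- function(lo, hi, name = paste0(lo, "-", hi, "Hz")) {
  if (!(lo > 0 && hi > lo)) {
    stop("band must satisfy 0 < lo < hi", call. = FALSE)
  }
  tibble::tibble(name = name, lo = lo, hi = hi)
}

#' @rdname band_definition
#' @param include_analysis_band also append the 3-30 Hz analysis band.
#' @export
band_grid <- function(include_analysis_band = FALSE) {
  g <- dplyr::bind_rows(
    band_definition(0.53, 4), band_definition(3, 6), band_definition(5, 10),
    band_definition(8, 16), band_definition(15, 30)
  )
  if (include_analysis_band) g <- dplyr::bind_rows(g, band_definition(3, 30))
  g
}

# |H(e^jw)|^2 of the 4th-order Butterworth band-pass on the n-point FFT grid,
# memoised (reused for every epoch batch of the same length)
h2_cache <- new.env(parent = emptyenv())
butter_h2 <- function(n, fs, lo, hi) {
  key <- paste(n, fs, lo, hi, sep = "_")
  cached <- h2_cache[[key]]
  if (!is.null(cached)) return(cached)
  bw <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n            # digital rad/sample FFT grid
  nk <- max(length(bw$b), length(bw$a))
  z <- exp(-1i * outer(w, seq_len(nk) - 1))
  hb <- as.vector(z[, seq_along(bw$b), drop = FALSE] %*% bw$b)
  ha <- as.vector(z[, seq_along(bw$a), drop = FALSE] %*% bw$a)
  h2 <- Mod(hb / ha)^2
  h2_cache[[key]] <- h2
  h2
}

# Zero-phase 4th-order Butterworth band-pass applied in the frequency domain:
# the FFT of each (reflection-padded) column is multiplied by |H(e^jw)|^2 of
# the signal::butter design — exactly the forward-backward magnitude
# response — then inverted. Vectorized over columns.
fd_bandpass_matrix <- function(x, fs, lo, hi, pad = 0.5) {
  stopifnot(is.matrix(x))
  if (lo <= 0 || hi <= lo || hi >= fs / 2) {
    stop("band [", lo, ", ", hi, "] Hz violates 0 < lo < hi < Nyquist (fs = ",
         fs, " Hz)", call. = FALSE)
  }
  np <- min(round(pad * fs), nrow(x) - 1)
  if (np > 0) {
    top <- x[rev(seq_len(np) + 1), , drop = FALSE]       # reflect, no repeat
    bot <- x[nrow(x) - seq_len(np), , drop = FALSE]
    xp <- rbind(top, x, bot)
  } else {
    xp <- x
  }
  # zero-pad to a 2-3-5-smooth FFT length (arbitrary epoch lengths would hit
  # near-O(n^2) mixed-radix transforms)
  n <- stats::nextn(nrow(xp), c(2, 3, 5))
  if (n > nrow(xp)) {
    xp <- rbind(xp, matrix(0, n - nrow(xp), ncol(xp)))
  }
  h2 <- butter_h2(n, fs, lo, hi)
  xf <- stats::mvfft(xp)
  y <- Re(stats::mvfft(xf * h2, inverse = TRUE)) / n
  y[np + seq_len(nrow(x)), , drop = FALSE]
}

#' Zero-phase band-pass filter an epoched recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per trial and channel, with 0.5 s reflection padding against epoch-edge
#' transients. Zero phase preserves the ERP deflection latencies
#' (0.35/0.55/0.65 s) that the network analysis depends on. Output shape is
#' unchanged; the DC component is removed (lo > 0).
#'
#' @param rec an [epoched_recording()].
#' @param lo,hi band edges in Hz; either scalars or a single-row band tibble
#'   via `band`.
#' @param band optionally a one-row tibble from [band_definition()] instead
#'   of `lo`/`hi`.
#' @param pad reflection padding in seconds (default 0.5).
#' @return The filtered [epoched_recording()].
#' @export
bandpass <- function(rec, lo = NULL, hi = NULL, band = NULL, pad = 0.5) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (!is.null(band)) {
    stopifnot(nrow(band) == 1)
    lo <- band$lo
    hi <- band$hi
  }
  d <- dim(rec$data)
  # samples x (trials*channels) matrix, filter all traces in one pass
  m <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = d[3])
  y <- fd_bandpass_matrix(m, rec$sampling_rate, lo, hi, pad = pad)
  out <- rec
  out$data <- aperm(array(y, c(d[3], d[1], d[2])), c(2, 3, 1))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Average consecutive same-task trials into trial-block ERPs
#'
#' Within each (day, session, task) group, consecutive trials in
#' chronological order are chunked into blocks of `block_size` (default 20)
#' and averaged per channel and sample into one ERP; the trailing incomplete
#' chunk is dropped. The trial-block ERP is the unit on which functional
#' connectivity is computed. Blocks never span sessions or task labels.
#'
#' @param rec an [epoched_recording()] (normally band-passed, non-hold trials
#'   selected).
#' @param block_size trials per block (default 20; must be >= 2).
#' @return A tibble of class `trial_blocks`, one row per block, with columns
#'   `block` (index within its group), `day`, `session`, `task`, `n_trials`,
#'   and `data` (list-column of channels x samples matrices). Sampling rate,
#'   time axis and montage travel as attributes.
#' @export
make_trial_blocks <- function(rec, block_size = 20) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (block_size < 2) {
    stop("block_size must be at least 2", call. = FALSE)
  }
  groups <- dplyr::group_split(
    dplyr::mutate(rec$meta, .row = dplyr::row_number()),
    .data$day, .data$session, .data$task
  )
  rows <- purrr::map(groups, function(g) {
    g <- g[order(g$trial), ]
    n_blocks <- nrow(g) %/% block_size
    if (n_blocks == 0) return(NULL)
    purrr::map(seq_len(n_blocks), function(b) {
      idx <- g$.row[(b - 1) * block_size + seq_len(block_size)]
      dat <- rec$data[idx, , , drop = FALSE]
      erp <- colMeans(dat, dims = 1)
      tibble::tibble(
        block = b, day = g$day[1], session = g$session[1], task = g$task[1],
        n_trials = block_size, data = list(erp)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    stop("no complete trial-blocks (need >= ", block_size,
         " trials per session/task group)", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$day, .data$session, .data$task, .data$block)
  structure(out,
            class = c("trial_blocks", class(out)),
            sampling_rate = rec$sampling_rate,
            time_axis = rec$time_axis,
            channels = rec$montage$channels)
}

#' @export
`[.trial_blocks` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "sampling_rate") <- attr(x, "sampling_rate")
    attr(out, "time_axis") <- attr(x, "time_axis")
    attr(out, "channels") <- attr(x, "channels")
    class(out) <- unique(c("trial_blocks", class(out)))
  }
  out
}

#' Synchronize a per-block series across days
#'
#' Multi-day series are aligned at matching block index and averaged
#' element-wise; each day's series is first trimmed to the shortest day's
#' block count.
#'
#' @param df tibble with a day column, a block-index column and a value
#'   column.
#' @param value,day,block column names (tidy-eval) of the value, day and
#'   block-index variables.
#' @param ... additional grouping columns preserved in the output (e.g.
#'   `session`).
#' @return A tibble with the grouping columns, `block`, and the day-averaged
#'   `value`; length equals the shortest day's series.
#' @export
day_synchronize <- function(df, value, day = day, block = block, ...) {
  value <- rlang::enquo(value)
  day <- rlang::enquo(day)
  block <- rlang::enquo(block)
  dots <- rlang::enquos(...)
  ranked <- df |>
    dplyr::group_by(!!!dots, !!day) |>
    dplyr::arrange(!!block, .by_group = TRUE) |>
    dplyr::mutate(.k = dplyr::row_number()) |>
    dplyr::ungroup()
  # trim every day to the shortest day's block count, within each group
  n_min <- ranked |>
    dplyr::group_by(!!!dots, !!day) |>
    dplyr::summarise(.len = max(.data$.k), .groups = "drop_last") |>
    dplyr::summarise(.n_min = min(.data$.len), .groups = "drop")
  if (length(dots) == 0) {
    ranked$.n_min <- n_min$.n_min
  } else {
    ranked <- dplyr::left_join(ranked, n_min,
                               by = vapply(dots, rlang::as_name, ""))
  }
  ranked |>
    dplyr::filter(.data$.k <= .data$.n_min) |>
    dplyr::group_by(!!!dots, block = .data$.k) |>
    dplyr::summarise(value = mean(!!value), .groups = "drop")
}
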