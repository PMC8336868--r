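#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw` via the standard symmetric tridiagonal eigenproblem, together
#' with their spectral concentrations (eigenvalues of the sinc kernel).
#' Tapers are normalized to unit energy.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default 3).
#' @return A list with `tapers` (n x k matrix) and `eigen` (length-k
#'   concentrations, all close to 1 for k <= 2*nw - 1).
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 8, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  tri <- matrix(0, n, n)
  tri[cbind(seq_len(n), seq_len(n))] <- diag_main
  tri[cbind(seq_len(n - 1), 2:n)] <- diag_off
  tri[cbind(2:n, seq_len(n - 1))] <- diag_off
  ev <- eigen(tri, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
  # polarity convention: symmetric tapers positive mean, antisymmetric
  # positive initial slope
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (sum((n - t) * tapers[, j]) < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  # concentration in [-W, W]: quadratic form with the sinc kernel
  dt <- outer(t, t, "-")
  kern <- sin(2 * pi * w * dt) / (pi * dt)
  diag(kern) <- 2 * w
  conc <- vapply(seq_len(k),
                 function(j) drop(crossprod(tapers[, j], kern %*% tapers[, j])),
                 numeric(1))
  list(tapers = tapers, eigen = conc)
}

# memoised taper cache (taper computation is O(n^3) and reused constantly)
taper_cache <- new.env(parent = emptyenv())
get_dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(taper_cache[[key]])) {
    taper_cache[[key]] <- dpss_tapers(n, nw, k)
  }
  taper_cache[[key]]
}

#' Multitaper power spectral density of short segments
#'
#' Eigenvalue-weighted multitaper PSD (DPSS tapers, default NW = 2 with
#' 3 tapers) of one or more equal-length segments. One-sided density scaled
#' so that the PSD integrates to the signal variance; a 1 s segment yields
#' the natural 1 Hz frequency grid.
#'
#' @param x numeric vector (one segment) or samples x segments matrix.
#' @param fs sampling rate in Hz.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default 3).
#' @return A list with `freq` (Hz, 0..Nyquist) and `psd` (power per Hz;
#'   matrix frequencies x segments).
#' @export
multitaper_psd <- function(x, fs, nw = 2, k = 3) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  dp <- get_dpss(n, nw, k)
  lam <- dp$eigen / sum(dp$eigen)
  nf <- n %/% 2 + 1
  acc <- matrix(0, nf, ncol(x))
  for (j in seq_len(k)) {
    tf <- stats::mvfft(x * dp$tapers[, j])
    acc <- acc + lam[j] * (Mod(tf[seq_len(nf), , drop = FALSE])^2)
  }
  # one-sided scaling: double interior bins, per-Hz density
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  psd <- acc * scale / fs
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd)
}

#' Mean band power from a multitaper spectrum
#'
#' Mean PSD over frequency bins whose centers fall in `[lo, hi]` (inclusive).
#'
#' @param x single-channel segment (numeric vector), typically the 1 s task
#'   or rest window.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; must lie within `[0, fs/2]`.
#' @param nw,k multitaper parameters, see [multitaper_psd()].
#' @return Scalar band power (power per Hz averaged over the band).
#' @export
multitaper_band_power <- function(x, fs, lo, hi, nw = 2, k = 3) {
  if (lo < 0 || hi > fs / 2 || hi < lo) {
    stop("band [", lo, ", ", hi, "] Hz outside [0, Nyquist]", call. = FALSE)
  }
  sp <- multitaper_psd(x, fs, nw = nw, k = k)
  sel <- sp$freq >= lo & sp$freq <= hi
  if (!any(sel)) {
    stop("no frequency bins fall inside [", lo, ", ", hi, "] Hz",
         call. = FALSE)
  }
  mean(sp$psd[sel, 1])
}

#' The Mu-suppression score
#'
#' `MuSC = -((task_power - rest_power) / rest_power) * 100`: the negated
#' relative change of contralateral Mu-band power between the task state and
#' the immediately preceding 1 s resting state. Positive scores indicate
#' suppression (ERD, task power below rest); negative scores indicate
#' enhancement.
#'
#' @param task_power Mu-band power of the task state (vectorized).
#' @param rest_power Mu-band power of the resting state; must be positive.
#' @return The score(s), dimensionless on the x100 scale.
#' @examples
#' mu_suppression_score(0.5, 1.0) # 50
#' mu_suppression_score(1.2, 1.0) # -20
#' @export
mu_suppression_score <- function(task_power, rest_power) {
  if (any(rest_power <= 0)) {
    stop("rest_power must be positive (undefined baseline)", call. = FALSE)
  }
  -((task_power - rest_power) / rest_power) * 100
}

# candidate windows of the sliding band search: width-Hz windows advanced by
# `step` Hz while they fit in the search range
mu_band_windows <- function(search_range = c(5, 20), width = 3, step = 1) {
  lo <- seq(search_range[1], search_range[2] - width, by = step)
  tibble::tibble(lo = lo, hi = lo + width)
}

# per-trial MuSC at the task-appropriate contra (or ipsi) channel for each
# candidate band; returns trials x bands matrix
trial_musc_matrix <- function(rec, bands, role = "contra", nw = 2, k = 3) {
  task_idx <- window_indices(rec, "task")
  rest_idx <- window_indices(rec, "rest")
  chans <- role_channel(rec$meta$task, role, rec$montage)
  ci <- match(chans, rec$montage$channels)
  nt <- n_trials(rec)
  task_seg <- matrix(0, length(task_idx), nt)
  rest_seg <- matrix(0, length(rest_idx), nt)
  for (i in seq_len(nt)) {
    task_seg[, i] <- rec$data[i, ci[i], task_idx]
    rest_seg[, i] <- rec$data[i, ci[i], rest_idx]
  }
  sp_task <- multitaper_psd(task_seg, rec$sampling_rate, nw = nw, k = k)
  sp_rest <- multitaper_psd(rest_seg, rec$sampling_rate, nw = nw, k = k)
  out <- matrix(0, nt, nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- sp_task$freq >= bands$lo[b] & sp_task$freq <= bands$hi[b]
    tp <- colMeans(sp_task$psd[sel, , drop = FALSE])
    rp <- colMeans(sp_rest$psd[sel, , drop = FALSE])
    out[, b] <- mu_suppression_score(tp, rp)
  }
  out
}

#' Select the subject-specific Mu band by sliding frequency window
#'
#' Scans 3 Hz-wide windows over the 5-20 Hz alpha/low-beta search range
#' (0.67 overlap, i.e. 1 Hz steps), scores each window by the mean per-trial
#' Mu-suppression at the task-appropriate contralateral channel (MI 0-1 s
#' window vs the preceding -1-0 s rest window), and returns the most
#' suppressed window. Ties (within 1e-12) break toward the lowest-frequency
#' window. Intended to be run per subject per day on that day's non-hold
#' trials.
#'
#' @param rec an [epoched_recording()]; hold trials are ignored.
#' @param search_range frequency search range in Hz (default `c(5, 20)`).
#' @param width window width in Hz (default 3).
#' @param overlap fractional window overlap (default 0.67; with `width` 3
#'   this advances in 1 Hz steps).
#' @param nw,k multitaper parameters.
#' @return An object of class `mu_band_selection`: list with `lo`, `hi`,
#'   `score` (mean MuSC of the chosen window) and `table` (tibble of all
#'   windows with their mean scores).
#' @export
select_mu_band <- function(rec, search_range = c(5, 20), width = 3,
                           overlap = 0.67, nw = 2, k = 3) {
  stopifnot(inherits(rec, "epoched_recording"))
  rec <- select_trials(rec, tasks = c("left", "right"))
  step <- max(1, round(width * (1 - overlap) / 0.5) * 0.5)
  bands <- mu_band_windows(search_range, width, step)
  m <- trial_musc_matrix(rec, bands, role = "contra", nw = nw, k = k)
  scores <- colMeans(m)
  best <- which(scores >= max(scores) - 1e-12)[1]
  structure(
    list(lo = bands$lo[best], hi = bands$hi[best], score = scores[best],
         table = tibble::tibble(lo = bands$lo, hi = bands$hi, score = scores)),
    class = "mu_band_selection"
  )
}

#' @export
print.mu_band_selection <- function(x, ...) {
  cat("<mu_band_selection> [", x$lo, ", ", x$hi, "] Hz, mean MuSC = ",
      round(x$score, 2), "\n", sep = "")
  invisible(x)
}

#' Per-day Mu-band selection
#'
#' Runs [select_mu_band()] separately on each day of a recording.
#'
#' @inheritParams select_mu_band
#' @return A tibble with one row per day: `day`, `lo`, `hi`, `score`, and a
#'   `table` list-column with the full window-score table.
#' @export
select_mu_band_by_day <- function(rec, search_range = c(5, 20), width = 3,
                                  overlap = 0.67, nw = 2, k = 3) {
  days <- sort(unique(rec$meta$day))
  purrr::map_dfr(days, function(d) {
    sel <- select_mu_band(select_trials(rec, days = d), search_range, width,
                          overlap, nw = nw, k = k)
    tibble::tibble(day = d, lo = sel$lo, hi = sel$hi, score = sel$score,
                   table = list(sel$table))
  })
}

#' Block-averaged Mu-suppression score series
#'
#' Scores every non-hold trial at its contralateral (and ipsilateral)
#' channel with the selected Mu band, then averages consecutive trials in
#' 20-trial blocks within each (day, session), pooling left and right MI
#' trials (each trial scored at its own contralateral channel). Optionally
#' synchronizes days by averaging matching block indices.
#'
#' @param rec an [epoched_recording()].
#' @param band a `mu_band_selection`, or a numeric `c(lo, hi)` in Hz.
#' @param block_size trials per block (default 20); the trailing incomplete
#'   block is dropped.
#' @param synchronize_days average matching block indices across days
#'   (default `FALSE`).
#' @param nw,k multitaper parameters.
#' @return A tibble of class `musc_series`: columns `day`, `session`,
#'   `block`, `channel_role` (`"contra"`/`"ipsi"`), `musc`, `n_trials` (with
#'   `day` collapsed when `synchronize_days = TRUE`).
#' @export
musc_series <- function(rec, band, block_size = 20, synchronize_days = FALSE,
                        nw = 2, k = 3) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (inherits(band, "mu_band_selection")) band <- c(band$lo, band$hi)
  rec <- select_trials(rec, tasks = c("left", "right"))
  bands <- tibble::tibble(lo = band[1], hi = band[2])
  per_role <- purrr::map_dfr(c("contra", "ipsi"), function(role) {
    m <- trial_musc_matrix(rec, bands, role = role, nw = nw, k = k)
    tibble::tibble(
      trial = rec$meta$trial, day = rec$meta$day, session = rec$meta$session,
      channel_role = role, musc = m[, 1]
    )
  })
  blocks <- per_role |>
    dplyr::group_by(.data$channel_role, .data$day, .data$session) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(block = (dplyr::row_number() - 1) %/% block_size + 1) |>
    dplyr::group_by(.data$channel_role, .data$day, .data$session,
                    .data$block) |>
    dplyr::filter(dplyr::n() == block_size) |>
    dplyr::summarise(musc = mean(.data$musc), n_trials = dplyr::n(),
                     .groups = "drop")
  if (synchronize_days) {
    blocks <- blocks |>
      day_synchronize(musc, day = day, block = block,
                      channel_role, session) |>
      dplyr::rename(musc = "value") |>
      dplyr::mutate(n_trials = block_size)
  }
  blocks <- dplyr::arrange(blocks, .data$channel_role,
                           dplyr::across(dplyr::any_of("day")),
                           .data$session, .data$block)
  structure(blocks, class = c("musc_series", class(blocks)))
}
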