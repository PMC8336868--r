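#' Simulation configuration for synthetic MI-BCI sessions
#'
#' Describes one subject-day of motor-imagery BCI training: sessions of
#' cue-paced trials (random pause then a 1 s action phase), a contralateral
#' Mu-band ERD planted during the action window, an ERP template with three
#' deflections (negative 0.35 s, positive 0.55 s, negative 0.65 s), spatially
#' correlated 1/f background, and session-indexed trend vectors (`erd_depth`,
#' `shared_gain`) that emulate training effects.
#'
#' Amplitudes are in microvolts and default to physiologically typical EEG
#' scales: ~9 uV rms 1/f background, ~6 uV Mu rhythm at C3/C4, averaged-ERP
#' deflections on the order of 10 uV at central channels.
#'
#' @param sampling_rate Hz (default 200).
#' @param n_sessions number of training sessions (default 3).
#' @param trials_per_session trials per session (default 300).
#' @param pause_range pause duration bounds in seconds, drawn uniformly
#'   (default `c(1.5, 2.5)`).
#' @param action_duration action-phase duration in seconds (default 1).
#' @param task_mix named proportions over `left`/`right`/`hold`
#'   (default 1/3 each; must sum to 1).
#' @param mu_band planted Mu band in Hz (default `c(9, 12)`).
#' @param erd_depth fractional Mu-amplitude reduction at the contralateral
#'   channel during action, one value per session, each in `[0, 1)`
#'   (default 0.4 for every session).
#' @param erp_amplitudes positive magnitudes (uV) of the three ERP
#'   deflections at 0.35/0.55/0.65 s; signs (-, +, -) are applied internally
#'   (default `c(10, 8, 10)`).
#' @param shared_gain per-session scalar on the across-channel common ERP
#'   component; drives inter-channel correlation of trial-block ERPs
#'   (default 1 for every session).
#' @param noise_exponent slope of the 1/f^a background (default 1).
#' @param background_sd rms amplitude (uV) of the per-channel 1/f background
#'   (default 9).
#' @param mu_sd rms amplitude (uV) of the Mu rhythm at C3/C4 (default 6).
#' @param shared_sd rms amplitude (uV) of the mixed shared broadband sources
#'   per channel (default 4).
#' @param n_shared number of shared broadband sources (default 4).
#' @param erp_jitter_sd sd of the per-trial, per-channel multiplicative
#'   jitter on the ERP gain (default 0.1).
#' @param day day index stored in trial metadata (default 1).
#' @param seed integer seed; the same config (including seed) reproduces the
#'   recording bit-for-bit.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 200,
                       n_sessions = 3,
                       trials_per_session = 300,
                       pause_range = c(1.5, 2.5),
                       action_duration = 1.0,
                       task_mix = c(left = 1 / 3, right = 1 / 3, hold = 1 / 3),
                       mu_band = c(9, 12),
                       erd_depth = rep(0.4, n_sessions),
                       erp_amplitudes = c(10, 8, 10),
                       shared_gain = rep(1, n_sessions),
                       noise_exponent = 1,
                       background_sd = 9,
                       mu_sd = 6,
                       shared_sd = 4,
                       n_shared = 4,
                       erp_jitter_sd = 0.1,
                       day = 1L,
                       seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    pause_range = pause_range, action_duration = action_duration,
    task_mix = task_mix, mu_band = mu_band, erd_depth = erd_depth,
    erp_amplitudes = erp_amplitudes, shared_gain = shared_gain,
    noise_exponent = noise_exponent, background_sd = background_sd,
    mu_sd = mu_sd, shared_sd = shared_sd, n_shared = as.integer(n_shared),
    erp_jitter_sd = erp_jitter_sd, day = as.integer(day),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) {
    stop("sim_config: sampling_rate must be positive", call. = FALSE)
  }
  if (cfg$n_sessions < 1 || cfg$trials_per_session < 1) {
    stop("sim_config: need at least one session and one trial", call. = FALSE)
  }
  if (abs(sum(cfg$task_mix) - 1) > 1e-9) {
    stop("sim_config: task_mix must sum to 1", call. = FALSE)
  }
  if (!identical(sort(names(cfg$task_mix)), c("hold", "left", "right"))) {
    stop("sim_config: task_mix must be named left/right/hold", call. = FALSE)
  }
  if (length(cfg$erd_depth) != cfg$n_sessions ||
      any(cfg$erd_depth < 0) || any(cfg$erd_depth >= 1)) {
    stop("sim_config: erd_depth needs one value in [0, 1) per session",
         call. = FALSE)
  }
  if (length(cfg$shared_gain) != cfg$n_sessions) {
    stop("sim_config: shared_gain needs one value per session", call. = FALSE)
  }
  if (cfg$pause_range[1] > cfg$pause_range[2] || cfg$pause_range[1] < 1) {
    stop("sim_config: invalid pause_range (need >= 1 s for the rest window)",
         call. = FALSE)
  }
  if (cfg$action_duration <= 0) {
    stop("sim_config: action_duration must be positive", call. = FALSE)
  }
  if (length(cfg$erp_amplitudes) != 3 || any(cfg$erp_amplitudes < 0)) {
    stop("sim_config: erp_amplitudes must be three non-negative magnitudes",
         call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic task-label counts matching task_mix within rounding, then a
# seeded shuffle; keeps label accounting exact.
task_labels_for_session <- function(n, task_mix) {
  base <- floor(task_mix * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(task_mix * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(base), times = base))
}

# 1/f^alpha gaussian noise, unit sd per column, via spectral shaping;
# synthesized at a 2-3-5-smooth FFT length and truncated, so the transform
# stays O(n log n); one mvfft for all columns
one_over_f_noise <- function(n, alpha, ncol = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- m %/% 2 + 1
  f <- seq(0, 0.5, length.out = nf)
  amp <- c(0, f[-1]^(-alpha / 2))
  ph <- matrix(stats::runif(nf * ncol, 0, 2 * pi), nf, ncol)
  spec <- amp * exp(1i * ph)
  mirror <- Conj(spec[rev(2:(m - nf + 1)), , drop = FALSE])
  x <- Re(stats::mvfft(rbind(spec, mirror),
                       inverse = TRUE))[seq_len(n), , drop = FALSE]
  scale(x)[, , drop = FALSE]
}

# Gaussian-windowed triphasic ERP template over the action phase.
# Deflections at 0.35/0.55/0.65 s with signs (-, +, -), sigma = 40 ms.
erp_template <- function(t, amplitudes) {
  signs <- c(-1, 1, -1)
  centers <- c(0.35, 0.55, 0.65)
  g <- numeric(length(t))
  for (k in 1:3) {
    g <- g + signs[k] * amplitudes[k] * exp(-(t - centers[k])^2 / (2 * 0.04^2))
  }
  g
}

# ERP scalp weighting: strongest over the vertex, Gaussian decay with 10-20
# grid distance from Cz.
erp_spatial_weights <- function(montage) {
  cz <- montage$coords[montage$coords$channel == "Cz", ]
  d2 <- (montage$coords$x - cz$x)^2 + (montage$coords$y - cz$y)^2
  exp(-d2 / (2 * 0.6^2))
}

#' Generate a synthetic MI-BCI recording with known ground truth
#'
#' Builds a continuous multichannel record per session (pause/action trial
#' sequence), plants the configured ERD, ERP and background structure, then
#' epochs every trial at `[-1, +1]` s around action onset.
#'
#' Signal model per channel: 1/f background + mixed shared broadband sources
#' + (at C3/C4) a band-limited Mu rhythm whose amplitude is multiplied by
#' `1 - erd_depth[session]` at the contralateral channel during the action
#' window of MI trials + (non-hold trials) the ERP template scaled by
#' `shared_gain[session]`, channel weights decaying from the vertex, with
#' per-trial per-channel gain jitter. A weaker unmodulated posterior alpha
#' rhythm is planted at O1/O2.
#'
#' @param config a [sim_config()].
#' @param keep_continuous also return the continuous per-session signals and
#'   event tables (needed to write EDF files); default `FALSE`.
#' @return A list of class `mi_simulation`:
#'   * `recording` — an [epoched_recording()],
#'   * `truth` — planted ground truth (`erd_depth`, `shared_gain`, `mu_band`,
#'     per-session label sequences and onset samples),
#'   * `continuous` — if requested, one element per session with `signal`
#'     (samples x channels matrix) and `events` tibble.
#' @examples
#' sim <- simulate_recording(sim_config(n_sessions = 1,
#'                                      trials_per_session = 30, seed = 1))
#' sim$recording
#' @export
simulate_recording <- function(config, keep_continuous = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  montage <- mi_montage()
  fs <- config$sampling_rate
  n_ch <- length(montage$channels)
  act_n <- round(config$action_duration * fs)
  epoch_half <- round(1.0 * fs)

  withr::with_seed(config$seed, {
    mix <- matrix(stats::rnorm(n_ch * config$n_shared), n_ch, config$n_shared)
    mix <- mix / sqrt(rowSums(mix^2)) * config$shared_sd

    w_erp <- erp_spatial_weights(montage)
    g_erp <- erp_template(seq(0, by = 1 / fs, length.out = act_n),
                          config$erp_amplitudes)

    mu_channels <- c("C3", "C4")
    alpha_channels <- c("O1", "O2")
    ch_idx <- function(ch) match(ch, montage$channels)

    sessions <- vector("list", config$n_sessions)
    epochs <- vector("list", config$n_sessions)
    metas <- vector("list", config$n_sessions)
    truth_labels <- vector("list", config$n_sessions)
    truth_onsets <- vector("list", config$n_sessions)
    trial_counter <- 0L

    for (s in seq_len(config$n_sessions)) {
      nt <- config$trials_per_session
      tasks <- task_labels_for_session(nt, config$task_mix)
      pauses <- round(stats::runif(nt, config$pause_range[1],
                                   config$pause_range[2]) * fs)
      # onset = first sample of the action phase of each trial
      onsets <- cumsum(pauses) + c(0, cumsum(rep(act_n, nt - 1))) + 1L
      n_samp <- onsets[nt] + act_n - 1 + epoch_half

      sig <- one_over_f_noise(n_samp, config$noise_exponent, n_ch) *
        config$background_sd
      shared <- matrix(stats::rnorm(n_samp * config$n_shared),
                       n_samp, config$n_shared)
      sig <- sig + shared %*% t(mix)

      # Mu rhythm with planted contralateral ERD during MI action windows
      mu_mod <- matrix(1, n_samp, length(mu_channels))
      colnames(mu_mod) <- mu_channels
      depth <- config$erd_depth[s]
      for (i in seq_len(nt)) {
        if (tasks[i] %in% c("left", "right")) {
          contra <- montage$contralateral[[tasks[i]]]
          idx <- onsets[i] + 0:(act_n - 1)
          mu_mod[idx, contra] <- 1 - depth
        }
      }
      nb_channels <- c(mu_channels, alpha_channels)
      nb <- fd_bandpass_matrix(
        matrix(stats::rnorm(n_samp * length(nb_channels)), n_samp),
        fs, config$mu_band[1], config$mu_band[2]
      )
      nb <- scale(nb)
      nb_sd <- c(rep(config$mu_sd, length(mu_channels)),
                 rep(config$mu_sd / 2, length(alpha_channels)))
      for (j in seq_along(nb_channels)) {
        ch <- nb_channels[j]
        modv <- if (ch %in% mu_channels) mu_mod[, ch] else 1
        sig[, ch_idx(ch)] <- sig[, ch_idx(ch)] + nb[, j] * nb_sd[j] * modv
      }

      # ERP on non-hold trials, common template scaled by session gain
      gain <- config$shared_gain[s]
      for (i in seq_len(nt)) {
        if (tasks[i] %in% c("left", "right")) {
          idx <- onsets[i] + 0:(act_n - 1)
          jit <- 1 + stats::rnorm(n_ch, 0, config$erp_jitter_sd)
          sig[idx, ] <- sig[idx, ] + outer(g_erp, gain * w_erp * jit)
        }
      }

      # epoch [-1, +1] s around each onset
      ep <- array(0, c(nt, n_ch, 2 * epoch_half + 1))
      for (i in seq_len(nt)) {
        idx <- (onsets[i] - epoch_half):(onsets[i] + epoch_half)
        ep[i, , ] <- t(sig[idx, ])
      }
      epochs[[s]] <- ep
      metas[[s]] <- tibble::tibble(
        trial = trial_counter + seq_len(nt),
        task = tasks, session = s, day = config$day
      )
      trial_counter <- trial_counter + nt
      truth_labels[[s]] <- tasks
      truth_onsets[[s]] <- onsets
      if (keep_continuous) {
        sessions[[s]] <- list(
          signal = sig,
          events = tibble::tibble(
            trial_index = metas[[s]]$trial, session = s, day = config$day,
            task_label = tasks, onset_sample = onsets
          )
        )
      }
    }
  })

  time_axis <- seq(-epoch_half, epoch_half) / fs
  rec <- epoched_recording(
    do.call(abind3, epochs), fs, time_axis, dplyr::bind_rows(metas), montage
  )
  truth <- list(
    erd_depth = config$erd_depth, shared_gain = config$shared_gain,
    mu_band = config$mu_band, labels = truth_labels, onsets = truth_onsets,
    config = config
  )
  structure(
    list(recording = rec, truth = truth,
         continuous = if (keep_continuous) sessions else NULL),
    class = "mi_simulation"
  )
}

#' @export
print.mi_simulation <- function(x, ...) {
  cat("<mi_simulation>\n")
  print(x$recording)
  cat("  planted erd_depth:", paste(x$truth$erd_depth, collapse = " "),
      "| shared_gain:", paste(x$truth$shared_gain, collapse = " "), "\n")
  invisible(x)
}

#' Generate a matched feedback / non-feedback fixture pair
#'
#' The "feedback" condition plants a training effect: ERD deepening and
#' common-ERP gain shrinking across sessions (the network-degree correlate of
#' successful neurofeedback training). The "non-feedback" condition holds
#' both profiles constant. All other parameters (including the seed) are
#' shared, so the pair differs only in its trend vectors.
#'
#' @param config a [sim_config()]; its `erd_depth`/`shared_gain` are replaced
#'   by the condition profiles.
#' @param feedback_erd ERD profile for the feedback condition (default an
#'   increasing ramp 0.2 -> 0.6 over sessions).
#' @param feedback_gain shared-gain profile for the feedback condition
#'   (default a decreasing ramp 1.0 -> 0.6).
#' @param nonfeedback_erd,nonfeedback_gain constant profiles for the control
#'   condition (defaults 0.4 and 1.0).
#' @param keep_continuous passed to [simulate_recording()].
#' @return A list with elements `feedback` and `nonfeedback`, each an
#'   `mi_simulation`.
#' @export
simulate_condition_pair <- function(config = sim_config(),
                                    feedback_erd = NULL,
                                    feedback_gain = NULL,
                                    nonfeedback_erd = NULL,
                                    nonfeedback_gain = NULL,
                                    keep_continuous = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_sessions
  if (is.null(feedback_erd)) feedback_erd <- seq(0.2, 0.6, length.out = ns)
  if (is.null(feedback_gain)) feedback_gain <- seq(1.0, 0.6, length.out = ns)
  if (is.null(nonfeedback_erd)) nonfeedback_erd <- rep(0.4, ns)
  if (is.null(nonfeedback_gain)) nonfeedback_gain <- rep(1.0, ns)
  fb_cfg <- config
  fb_cfg$erd_depth <- feedback_erd
  fb_cfg$shared_gain <- feedback_gain
  nf_cfg <- config
  nf_cfg$erd_depth <- nonfeedback_erd
  nf_cfg$shared_gain <- nonfeedback_gain
  list(
    feedback = simulate_recording(fb_cfg, keep_continuous = keep_continuous),
    nonfeedback = simulate_recording(nf_cfg, keep_continuous = keep_continuous)
  )
}
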