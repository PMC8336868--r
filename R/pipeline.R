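#' End-to-end short-term MI training analysis
#'
#' Orchestrates the full assessment on one subject-day (or multi-day)
#' recording: drops hold trials, then
#' * **MuSC branch** — per-day subject-specific Mu-band selection, the
#'   block-averaged Mu-suppression series at the contralateral channel, and
#'   its OLS trend;
#' * **network branch** — 3-30 Hz zero-phase band-pass, 20-trial-block ERP
#'   averaging, Pearson connectivity, node/region/clustering indicators for
#'   task and rest windows, pairwise super-trial Welch t-tests, regional
#'   trend fits, and (optionally) the five-band degree scan.
#'
#' Analysis stages contain no randomness: the same input and parameters
#' reproduce every output bit-identically.
#'
#' @param input an [epoched_recording()], an `mi_simulation`, a
#'   [sim_config()] (simulated on the fly), a directory containing an EDF
#'   session set, or an epochs-table CSV path.
#' @param analysis_band band-pass for the network branch in Hz (default
#'   `c(3, 30)`).
#' @param block_size trials per trial-block (default 20).
#' @param threshold binarization threshold for clustering (default 0.6).
#' @param mu_search,mu_width,mu_overlap Mu-band search parameters (defaults
#'   5-20 Hz, 3 Hz window, 0.67 overlap).
#' @param scan_bands band grid for the degree scan, or `NULL` to skip it.
#' @param synchronize_days average the MuSC series across days (default
#'   `TRUE` when several days are present).
#' @param absolute binarize on `|rho|` instead of signed rho.
#' @param var_equal use pooled-variance t-tests.
#' @param out_dir if given, tidy CSVs, a JSON summary and a plain-text run
#'   log are written there.
#' @return An object of class `mi_report`: list with `band_selection`,
#'   `musc`, `musc_trend`, `metrics`, `comparisons`, `region_trends`,
#'   `band_scan`, `params`.
#' @export
run_pipeline <- function(input,
                         analysis_band = c(3, 30),
                         block_size = 20,
                         threshold = 0.6,
                         mu_search = c(5, 20),
                         mu_width = 3,
                         mu_overlap = 0.67,
                         scan_bands = band_grid(),
                         synchronize_days = NULL,
                         absolute = FALSE,
                         var_equal = FALSE,
                         out_dir = NULL) {
  rec <- resolve_input(input)
  montage <- rec$montage
  if (is.null(synchronize_days)) {
    synchronize_days <- length(unique(rec$meta$day)) > 1
  }

  nonhold <- tryCatch(
    select_trials(rec, tasks = c("left", "right")),
    error = function(e) stop("stage select_trials: ", conditionMessage(e),
                             call. = FALSE)
  )

  # --- MuSC branch ---------------------------------------------------------
  band_selection <- tryCatch(
    select_mu_band_by_day(nonhold, mu_search, mu_width, mu_overlap),
    error = function(e) stop("stage select_mu_band: ", conditionMessage(e),
                             call. = FALSE)
  )
  musc <- purrr::map_dfr(seq_len(nrow(band_selection)), function(i) {
    musc_series(select_trials(nonhold, days = band_selection$day[i]),
                c(band_selection$lo[i], band_selection$hi[i]),
                block_size = block_size)
  })
  if (synchronize_days) {
    musc <- musc |>
      day_synchronize(musc, day = day, block = block,
                      channel_role, session) |>
      dplyr::rename(musc = "value")
  }
  contra <- musc |>
    dplyr::filter(.data$channel_role == "contra") |>
    dplyr::arrange(dplyr::across(dplyr::any_of("day")),
                   .data$session, .data$block)
  musc_trend <- fit_slope(contra$musc, series_id = "MuSC contralateral")

  # --- network branch ------------------------------------------------------
  filt <- tryCatch(
    bandpass(nonhold, analysis_band[1], analysis_band[2]),
    error = function(e) stop("stage bandpass: ", conditionMessage(e),
                             call. = FALSE)
  )
  blocks <- tryCatch(
    make_trial_blocks(filt, block_size),
    error = function(e) stop("stage make_trial_blocks: ",
                             conditionMessage(e), call. = FALSE)
  )
  metrics <- network_metrics_all(blocks, montage, threshold,
                                 absolute = absolute)
  comparisons <- compare_super_trials(
    metrics, value, session, window_role, scale, indicator,
    var_equal = var_equal
  )
  region_trends <- metrics |>
    dplyr::filter(.data$scale == "region", .data$window_role == "task") |>
    dplyr::group_by(.data$task, .data$indicator) |>
    dplyr::arrange(.data$session, .data$block, .by_group = TRUE) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(d) {
      if (nrow(d) < 3) { # too few blocks for a line; report NA, not an error
        return(tibble::tibble(task = d$task[1], indicator = d$indicator[1],
                              slope = NA_real_, slope_se = NA_real_,
                              p = NA_real_, n_blocks = nrow(d)))
      }
      f <- fit_slope(d$value,
                     series_id = paste(d$task[1], d$indicator[1]))
      tibble::tibble(task = d$task[1], indicator = d$indicator[1],
                     slope = f$slope, slope_se = f$slope_se, p = f$p,
                     n_blocks = f$n)
    })

  band_scan <- if (!is.null(scan_bands)) {
    band_scan_degree(nonhold, scan_bands, montage, block_size)
  } else {
    NULL
  }

  report <- structure(
    list(
      band_selection = band_selection, musc = musc, musc_trend = musc_trend,
      metrics = metrics, comparisons = comparisons,
      region_trends = region_trends, band_scan = band_scan,
      params = list(
        analysis_band = analysis_band, block_size = block_size,
        threshold = threshold, mu_search = mu_search, mu_width = mu_width,
        mu_overlap = mu_overlap, absolute = absolute, var_equal = var_equal,
        synchronize_days = synchronize_days,
        n_trials = n_trials(rec),
        n_nonhold = n_trials(nonhold),
        sessions = sort(unique(rec$meta$session)),
        days = sort(unique(rec$meta$day)),
        seed = if (inherits(input, "sim_config")) input$seed else NULL
      )
    ),
    class = "mi_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

resolve_input <- function(input) {
  if (inherits(input, "epoched_recording")) return(input)
  if (inherits(input, "mi_simulation")) return(input$recording)
  if (inherits(input, "sim_config")) {
    return(simulate_recording(input)$recording)
  }
  if (is.character(input) && length(input) == 1) {
    if (dir.exists(input)) return(read_edf_sessions(input))
    if (file.exists(input)) return(read_epochs_table(input))
    stop("input path does not exist: ", input, call. = FALSE)
  }
  stop("unsupported input type: ", paste(class(input), collapse = "/"),
       call. = FALSE)
}

#' @export
print.mi_report <- function(x, ...) {
  cat("<mi_report>\n")
  cat("  Mu band (per day):",
      paste(sprintf("[%g, %g] Hz", x$band_selection$lo, x$band_selection$hi),
            collapse = "; "), "\n")
  cat("  MuSC slope:", signif(x$musc_trend$slope, 3),
      "(p =", signif(x$musc_trend$p, 3), ")\n")
  n13 <- x$comparisons |>
    dplyr::filter(.data$group_a == 1, .data$group_b == max(.data$group_b),
                  .data$window_role == "task", .data$scale == "region")
  cat("  task-window regional super-trial 1 vs", max(x$comparisons$group_b),
      "comparisons:\n")
  for (i in seq_len(nrow(n13))) {
    cat(sprintf("    %-4s t = %6.2f  p = %.3g %s\n", n13$indicator[i],
                n13$t[i], n13$p[i], n13$stars[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
#' @export
glance.mi_report <- function(x, ...) {
  deg13 <- x$comparisons |>
    dplyr::filter(.data$scale == "node", .data$window_role == "task",
                  .data$group_a == 1, .data$group_b == max(.data$group_b))
  tibble::tibble(
    musc_slope = x$musc_trend$slope,
    musc_slope_p = x$musc_trend$p,
    mu_lo = x$band_selection$lo[1],
    mu_hi = x$band_selection$hi[1],
    min_degree_p_1_vs_last = min(deg13$p),
    n_blocks = dplyr::n_distinct(
      paste(x$metrics$session, x$metrics$task, x$metrics$block)
    )
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$musc, file.path(out_dir, "musc.csv"))
  readr::write_csv(report$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(report$comparisons, file.path(out_dir, "comparisons.csv"))
  readr::write_csv(report$region_trends, file.path(out_dir, "trends.csv"))
  if (!is.null(report$band_scan)) {
    readr::write_csv(report$band_scan, file.path(out_dir, "band_scan.csv"))
  }
  jsonlite::write_json(
    list(per_day = report$band_selection |>
           dplyr::select("day", "lo", "hi", "score"),
         window_scores = purrr::map(report$band_selection$table, identity)),
    file.path(out_dir, "band_selection.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(
    list(
      params = report$params,
      mu_band = report$band_selection |>
        dplyr::select("day", "lo", "hi", "score"),
      musc_trend = unclass(tidy(report$musc_trend)),
      region_trends = report$region_trends,
      comparisons = report$comparisons
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  log_lines <- c(
    "miconn run log",
    paste0("generated: <deterministic; no timestamp for reproducibility>"),
    paste0("parameters:"),
    paste0("  ", names(report$params), " = ",
           vapply(report$params,
                  function(v) paste(format(v), collapse = " "), ""))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
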