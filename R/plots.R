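#' Plot a Mu-suppression score series with its linear fit
#'
#' Scatter of block-averaged MuSC values in chronological block order with
#' the OLS fitting line (red), one panel per channel role.
#'
#' @param object a `musc_series` tibble from [musc_series()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.musc_series <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$channel_role) |>
    dplyr::arrange(dplyr::across(dplyr::any_of("day")), .data$session,
                   .data$block, .by_group = TRUE) |>
    dplyr::mutate(block_index = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$block_index, .data$musc)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$session))) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::facet_wrap(~channel_role) +
    ggplot2::labs(x = "trial-block (20 trials)", y = "MuSC",
                  shape = "session") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.musc_series
#' @param series a `musc_series` tibble.
#' @export
plot_musc <- function(series, ...) autoplot.musc_series(series, ...)

#' Heatmap of a connectivity matrix
#'
#' @param object a [pearson_connectivity()] matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  chans <- rownames(object)
  df <- tibble::tibble(
    from = factor(rep(chans, times = ncol(object)), levels = chans),
    to = factor(rep(chans, each = nrow(object)), levels = rev(chans)),
    rho = as.vector(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pearson connectivity (",
                                 attr(object, "window_role"), " window)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Super-trial comparison plot for a network indicator
#'
#' Block-level values of one indicator grouped by super-trial (session),
#' with conventional significance stars from the supplied comparison
#' table (* p < 0.05, ** p < 0.01 vs super-trial 1).
#'
#' @param metrics tidy metrics tibble from [network_metrics_all()].
#' @param which_indicator indicator name (e.g. `"LnL"`, `"EX"`, `"C3"`,
#'   `"all"`).
#' @param window `"task"` or `"rest"`.
#' @param comparisons optional [compare_super_trials()] output used to
#'   annotate stars.
#' @return A ggplot object.
#' @export
plot_super_trials <- function(metrics, which_indicator, window = "task",
                              comparisons = NULL) {
  df <- metrics |>
    dplyr::filter(.data$indicator == which_indicator,
                  .data$window_role == window)
  if (nrow(df) == 0) {
    stop("indicator '", which_indicator, "' not found for window '",
         window, "'", call. = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(factor(.data$session),
                                        .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "super-trial (session)", y = which_indicator,
                  title = paste0(which_indicator, " (", window, " window)")) +
    ggplot2::theme_minimal()
  if (!is.null(comparisons)) {
    ann <- comparisons |>
      dplyr::filter(.data$indicator == which_indicator,
                    .data$window_role == window, .data$group_a == 1,
                    .data$stars != "")
    if (nrow(ann)) {
      y_top <- max(df$value)
      p <- p + ggplot2::annotate(
        "text", x = ann$group_b, y = y_top + 0.05 * abs(y_top),
        label = ann$stars, size = 5
      )
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
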