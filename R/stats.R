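#' Welch two-sample t-test between super-trial groups
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom) on block-level values, the comparison unit of the super-trial
#' analysis. If both groups are constant with equal means (degenerate), the
#' result is `t = 0, p = 1` rather than an error.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @param var_equal use the pooled-variance Student test instead
#'   (default `FALSE`).
#' @return A one-row tibble: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `t`, `df`, `p`, `sig_05`, `sig_01`, `stars`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  degenerate <- stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
    mean(group_a) == mean(group_b)
  if (degenerate) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  }
  p <- tt$p.value
  tibble::tibble(
    mean_a = mean(group_a), sd_a = stats::sd(group_a), n_a = length(group_a),
    mean_b = mean(group_b), sd_b = stats::sd(group_b), n_b = length(group_b),
    t = unname(tt$statistic), df = unname(tt$parameter), p = p,
    sig_05 = p < 0.05, sig_01 = p < 0.01,
    stars = ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  )
}

#' OLS trend fit over a block series
#'
#' Ordinary least squares of value on (1-based) block index — the "fitting
#' line slope" used to summarize MuSC and regional-degree series.
#'
#' @param values numeric series (>= 3 points).
#' @param index block indices (default `seq_along(values)`).
#' @param series_id optional label stored with the fit.
#' @return An object of class `trend_fit` with [generics::tidy()] and
#'   [generics::glance()] methods; elements `slope`, `intercept`,
#'   `slope_se`, `t`, `p`, `n`, `series_id`, `model`.
#' @examples
#' fit_slope(c(1, 3, 2))$slope # 0.5
#' @export
fit_slope <- function(values, index = seq_along(values), series_id = NULL) {
  if (length(values) < 3) {
    stop("trend fit needs at least 3 points", call. = FALSE)
  }
  fit <- stats::lm(values ~ index)
  cf <- summary(fit)$coefficients
  structure(
    list(
      slope = unname(cf["index", "Estimate"]),
      intercept = unname(cf["(Intercept)", "Estimate"]),
      slope_se = unname(cf["index", "Std. Error"]),
      t = unname(cf["index", "t value"]),
      p = unname(cf["index", "Pr(>|t|)"]),
      n = length(values), series_id = series_id, model = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", if (!is.null(x$series_id)) x$series_id else "",
      " slope = ", signif(x$slope, 4), " (se ", signif(x$slope_se, 3),
      ", p = ", signif(x$p, 3), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(summary(x$model)$coefficients["(Intercept)", "Std. Error"],
                  x$slope_se),
    statistic = c(summary(x$model)$coefficients["(Intercept)", "t value"],
                  x$t),
    p.value = c(summary(x$model)$coefficients["(Intercept)", "Pr(>|t|)"],
                x$p)
  )
}

#' @exportS3Method generics::glance
#' @export
glance.trend_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(slope = x$slope, p.value = x$p, r.squared = s$r.squared,
                 sigma = s$sigma, nobs = x$n)
}

#' Pairwise super-trial comparisons of an indicator table
#'
#' Groups block-level values by super-trial (session) and runs a Welch
#' t-test for every pair of super-trials (1-2, 1-3, 2-3 with three
#' sessions), for every combination of the stratifying columns. A
#' Benjamini-Hochberg adjusted p-value column (`p_bh`, computed across the
#' returned rows) is appended for transparency; the headline significance
#' flags follow the raw p-values.
#'
#' @param df tidy tibble of block-level values.
#' @param value column holding the value (tidy-eval).
#' @param group column holding the super-trial label (default `session`).
#' @param ... stratifying columns (e.g. `window_role`, `indicator`).
#' @param var_equal passed to [welch_t_test()].
#' @return A tibble: stratifiers, `group_a`, `group_b`, and the
#'   [welch_t_test()] columns plus `p_bh`.
#' @export
compare_super_trials <- function(df, value, group = session, ...,
                                 var_equal = FALSE) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  dots <- rlang::enquos(...)
  strata <- if (length(dots)) {
    dplyr::group_split(dplyr::group_by(df, !!!dots))
  } else {
    list(df)
  }
  out <- purrr::map_dfr(strata, function(d) {
    gvals <- sort(unique(dplyr::pull(d, !!group)))
    if (length(gvals) < 2) return(NULL)
    pairs <- utils::combn(gvals, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- dplyr::pull(dplyr::filter(d, !!group == pr[1]), !!value)
      b <- dplyr::pull(dplyr::filter(d, !!group == pr[2]), !!value)
      keys <- if (length(dots)) {
        dplyr::distinct(dplyr::select(d, !!!dots))
      } else {
        tibble::tibble(.rows = 1)
      }
      dplyr::bind_cols(keys,
                       tibble::tibble(group_a = pr[1], group_b = pr[2]),
                       welch_t_test(a, b, var_equal = var_equal))
    })
  })
  if (nrow(out)) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
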