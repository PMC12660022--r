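#' Run the full evidence-factor analysis
#'
#' The end-to-end pipeline: stratify on covariates, fix or select the
#' local-randomization window, residualize the level-1 outcome, build the
#' K factor comparisons, test each by randomization inference, and
#' combine the K p-values at the configured `q`. Every Monte-Carlo step
#' derives from `config$seed` (factor k uses `seed + k`), so a rerun is
#' bit-identical.
#'
#' @param data Subject tibble (standard layout; a `stratum` column is
#'   added via [ef_stratify()] if absent).
#' @param design An [ef_design()].
#' @param config An [ef_config()]; `config$q` must not exceed `design$K`.
#' @param candidates Optional candidate half-widths for
#'   [select_window()]; required when `design$window` is unset.
#' @return An object of class `ef_analysis`: a list with `tests` (one row
#'   per factor, see [randomization_pvalue()]), `combined`
#'   (see [fisher_combined()]), `factors`, `window`, `design`, `config`
#'   and `validation`.
#' @export
ef_analyze <- function(data, design, config, candidates = NULL) {
  stopifnot(inherits(design, "ef_design"), inherits(config, "ef_config"))
  if (config$q > design$K) {
    abort(sprintf("config error: q = %d exceeds K = %d.", config$q, design$K))
  }
  validation <- validate_design(data, design)
  if (!"stratum" %in% names(data)) data <- ef_stratify(data)
  if (!is.null(design$window)) {
    window <- design$window
    window_search <- NULL
  } else {
    if (is.null(candidates)) {
      abort("`design$window` is unset; supply `candidates` for select_window().")
    }
    window_search <- select_window(data, design, candidates,
                                   n_perm = config$n_perm, seed = config$seed)
    window <- window_search$chosen
  }
  factors <- build_factors(data, design, window,
                           residualize = config$residualize)
  tests <- purrr::map_dfr(seq_len(design$K), function(k) {
    randomization_pvalue(factors[k, ], alternative = config$alternative,
                         n_perm = config$n_perm, seed = config$seed + k)
  })
  combined <- combine_pvalues(tests$p_value, config)
  structure(
    list(tests = tests, combined = combined, factors = factors,
         window = window, window_search = window_search,
         design = design, config = config, validation = validation),
    class = "ef_analysis"
  )
}

#' Sensitivity analysis of a fitted evidence-factor analysis
#'
#' Convenience wrapper around [sensitivity_profile()] that reuses the
#' factors and configuration of an [ef_analyze()] result.
#'
#' @param analysis An `ef_analysis`.
#' @param gamma_grid Optional per-level list of Gamma vectors overriding
#'   `config$gamma_grid`.
#' @return An `ef_sensitivity` tibble.
#' @export
ef_sensitivity <- function(analysis, gamma_grid = NULL) {
  stopifnot(inherits(analysis, "ef_analysis"))
  config <- analysis$config
  if (!is.null(gamma_grid)) config$gamma_grid <- gamma_grid
  sensitivity_profile(analysis$factors, config)
}

#' @export
print.ef_analysis <- function(x, ...) {
  cat("Evidence-factor analysis (K =", x$design$K, "levels,",
      x$design$compliance, "non-compliance)\n")
  cat("window: (", x$window[1], ",", x$window[2], ")\n\n")
  print(dplyr::select(x$tests, "level", "statistic", "p_value",
                      "n_treat", "n_control", "n_strata_informative"))
  cat(sprintf("\ncombined p-value (%s, q = %d of %d): %.4g\n",
              x$combined$combiner, x$combined$q, x$design$K,
              x$combined$p_combined))
  invisible(x)
}

#' @describeIn ef_analyze One row per factor: level, statistic, p-value,
#'   arm sizes.
#' @param x,object An `ef_analysis`.
#' @param ... Unused.
#' @export
tidy.ef_analysis <- function(x, ...) {
  x$tests
}

#' @describeIn ef_analyze One-row summary: K, q, combiner, combined
#'   p-value, window.
#' @export
glance.ef_analysis <- function(x, ...) {
  tibble::tibble(
    K = x$design$K,
    q = x$combined$q,
    combiner = x$combined$combiner,
    statistic = x$combined$statistic,
    p_combined = x$combined$p_combined,
    window_lo = x$window[1],
    window_hi = x$window[2],
    n = sum(x$validation$factors$n_total[1])
  )
}

#' @export
autoplot.ef_analysis <- function(object, ...) {
  df <- object$tests
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$level), y = .data$p_value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$design$alpha, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$combined$p_combined,
                        colour = "firebrick") +
    ggplot2::annotate("text", x = Inf, y = object$combined$p_combined,
                      label = "combined", hjust = 1.1, vjust = -0.4,
                      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "evidence factor (level)", y = "one-sided p-value") +
    ggplot2::theme_minimal()
}
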