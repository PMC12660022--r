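#' Describe a fuzzy regression discontinuity design
#'
#' A design specification collects the structural facts about a sequential
#' fuzzy RD study: how many assignment levels there are, whether
#' non-compliance is one- or two-sided, where the eligibility cutoff sits on
#' the running variable, and (optionally) the local-randomization window.
#'
#' @param K Number of sequential treatment assignment levels. Must be at
#'   least 2: `K = 1` is a sharp RD design with a single comparison and no
#'   evidence-factor structure.
#' @param compliance `"one_sided"` (treatment statuses are nested: taking
#'   treatment at level k requires having taken it at all earlier levels) or
#'   `"two_sided"` (later statuses may be 1 even when an earlier one is 0).
#' @param cutoff Cutoff on the running variable. Subjects whose running
#'   value ties the cutoff are eligible.
#' @param eligibility_direction `"ge"` if values at or above the cutoff are
#'   eligible, `"le"` if values at or below are.
#' @param window Numeric length-2 `(lo, hi)` local-randomization window, or
#'   `NULL` if it will be chosen later with [select_window()].
#' @param balance_threshold Minimum covariate-balance p-value a candidate
#'   window must exceed. Default 0.15.
#' @param alpha Nominal test level used in reports. Default 0.05.
#'
#' @return An object of class `ef_design`.
#' @export
#' @examples
#' ef_design(K = 2, compliance = "two_sided", cutoff = 0)
ef_design <- function(K,
                      compliance = c("one_sided", "two_sided"),
                      cutoff = 0,
                      eligibility_direction = c("ge", "le"),
                      window = NULL,
                      balance_threshold = 0.15,
                      alpha = 0.05) {
  compliance <- match.arg(compliance)
  eligibility_direction <- match.arg(eligibility_direction)
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 2L) {
    abort(paste0(
      "`K` must be an integer >= 2 for a fuzzy design; K = 1 is a sharp RD ",
      "design with no evidence-factor structure."
    ))
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 2L || any(!is.finite(window))) {
      abort("`window` must be a finite numeric pair (lo, hi).")
    }
    if (!(window[1] < cutoff && cutoff < window[2])) {
      abort("`window` must satisfy lo < cutoff < hi.")
    }
  }
  if (!(balance_threshold > 0 && balance_threshold < 1)) {
    abort("`balance_threshold` must lie in (0, 1).")
  }
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  structure(
    list(
      K = K, compliance = compliance, cutoff = cutoff,
      eligibility_direction = eligibility_direction, window = window,
      balance_threshold = balance_threshold, alpha = alpha
    ),
    class = "ef_design"
  )
}

#' @export
print.ef_design <- function(x, ...) {
  cat("<ef_design> K =", x$K, "|", x$compliance, "non-compliance\n")
  cat("  cutoff:", x$cutoff, "eligible side:", x$eligibility_direction, "\n")
  if (is.null(x$window)) {
    cat("  window: unset\n")
  } else {
    cat("  window: (", x$window[1], ",", x$window[2], ")\n")
  }
  invisible(x)
}

#' Analysis configuration for an evidence-factor run
#'
#' @param q Conjectured minimum number of valid factors among the K
#'   comparisons; the combination step retains only the `q` largest
#'   p-values so that up to `K - q` biased factors cannot invalidate the
#'   combined p-value.
#' @param combiner `"fisher"` or `"truncated_product"`.
#' @param truncation Truncation point tau in (0, 1] for the truncated
#'   product combiner (ignored by Fisher). Default 1.
#' @param n_perm Monte-Carlo permutation draws per randomization test.
#' @param null_draws Monte-Carlo draws used when the combination null has no
#'   closed form. Default 1e5 (standard error below 0.0016 at p near 0.5).
#' @param gamma_grid Per-level list of sensitivity parameters Gamma >= 1,
#'   one numeric vector per assignment level; `NULL` until a sensitivity
#'   analysis is requested. Default grid per level is
#'   `c(1, 1.1, 1.2, 1.5, 2)`.
#' @param seed Integer seed controlling every Monte-Carlo draw.
#' @param alternative `"greater"` or `"less"` (one-sided tests).
#' @param null_method Reference distribution for the combined p-value when
#'   `q < K`: `"independent"` (the default) treats the q retained p-values
#'   as q independent uniforms, which keeps the combined p-value valid when
#'   up to `K - q` factors are biased; `"order_stat"` uses the exact null of
#'   the q largest order statistics of K independent uniforms, which is
#'   exact only when all K factors are valid. See the methods vignette.
#' @param residualize Should the level-1 (intent-to-treat) comparison use
#'   the outcome residualized on the running variable? Default `TRUE`.
#'
#' @return An object of class `ef_config`.
#' @export
ef_config <- function(q,
                      combiner = c("fisher", "truncated_product"),
                      truncation = 1,
                      n_perm = 999L,
                      null_draws = 1e5L,
                      gamma_grid = NULL,
                      seed = 1L,
                      alternative = c("greater", "less"),
                      null_method = c("independent", "order_stat"),
                      residualize = TRUE) {
  combiner <- match.arg(combiner)
  alternative <- match.arg(alternative)
  null_method <- match.arg(null_method)
  q <- as.integer(q)
  if (length(q) != 1L || is.na(q) || q < 1L) abort("`q` must be a positive integer.")
  if (!(truncation > 0 && truncation <= 1)) abort("`truncation` must lie in (0, 1].")
  if (n_perm < 1L || null_draws < 1L) abort("`n_perm` and `null_draws` must be >= 1.")
  if (!is.null(gamma_grid)) {
    if (!is.list(gamma_grid)) gamma_grid <- list(gamma_grid)
    if (any(unlist(gamma_grid) < 1)) abort("all gamma values must be >= 1.")
  }
  structure(
    list(
      q = q, combiner = combiner, truncation = truncation,
      n_perm = as.integer(n_perm), null_draws = as.integer(null_draws),
      gamma_grid = gamma_grid, seed = as.integer(seed),
      alternative = alternative, null_method = null_method,
      residualize = isTRUE(residualize)
    ),
    class = "ef_config"
  )
}

#' @export
print.ef_config <- function(x, ...) {
  cat("<ef_config> q =", x$q, "combiner:", x$combiner,
      "| alternative:", x$alternative, "\n")
  cat("  n_perm:", x$n_perm, " null_draws:", x$null_draws,
      " seed:", x$seed, " null_method:", x$null_method, "\n")
  invisible(x)
}

# default per-level sensitivity grid
default_gamma_grid <- function(K) {
  rep(list(c(1, 1.1, 1.2, 1.5, 2)), K)
}
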