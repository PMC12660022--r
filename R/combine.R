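#' Combine factor p-values: Fisher's method on the q largest
#'
#' Retains the `q` largest of the `K` factor p-values and combines them
#' with Fisher's statistic `H = -2 * sum(log p)`. Discarding the `K - q`
#' smallest p-values protects the combination when up to `K - q` factors
#' are biased: a biased factor tends toward a small p-value and is
#' dropped.
#'
#' Two reference distributions are available for `q < K`:
#' * `"independent"` (default): `H` is referred to the chi-square
#'   distribution with `2q` degrees of freedom, i.e. the retained
#'   p-values are treated as `q` independent p-values. Because the j-th
#'   largest of all K p-values is at least the j-th largest among any q
#'   valid ones, this combined p-value stays valid whenever at least `q`
#'   factors are valid; it is conservative when all `K` are.
#' * `"order_stat"`: `H` is referred to its exact null under the q
#'   largest order statistics of K independent uniforms (add-one Monte
#'   Carlo). This is exact when all `K` factors are valid but can
#'   anti-conservative when some are biased; it is provided for
#'   completeness and diagnostics.
#'
#' When `q = K` the two coincide and the chi-square(2K) closed form is
#' used. Ties among p-values at the retention boundary are kept by sorted
#' position with stable index order.
#'
#' @param pvals Numeric vector of K p-values in (0, 1].
#' @param q Number of largest p-values to retain, `1 <= q <= K`.
#' @param null_draws Monte-Carlo draws for the `"order_stat"` null.
#' @param seed Seed for the Monte-Carlo null.
#' @param null_method `"independent"` or `"order_stat"`.
#' @return A one-row tibble of class `ef_combined`: `q`, `combiner`,
#'   `statistic` (H), `p_combined`, `null_method` used
#'   (`"closed_form"` or `"monte_carlo"`), `null_draws`, `seed`, and
#'   list-columns `member_p`, `retained_p`, `retained_idx`.
#' @export
#' @examples
#' fisher_combined(c(0.5, 0.5), q = 2)  # chi-square(4) tail, p = 0.5966
fisher_combined <- function(pvals, q = length(pvals), null_draws = 1e5L,
                            seed = 1L,
                            null_method = c("independent", "order_stat")) {
  null_method <- match.arg(null_method)
  check_pvals(pvals, q)
  K <- length(pvals)
  ret <- retain_largest(pvals, q)
  H <- -2 * sum(log(ret$p))
  if (q == K || null_method == "independent") {
    p_comb <- pchisq(H, df = 2 * q, lower.tail = FALSE)
    p_comb <- max(p_comb, .Machine$double.xmin)  # keep in (0, 1]
    nm <- "closed_form"
    nd <- NA_integer_
  } else {
    set.seed(seed)
    Hnull <- order_stat_fisher_null(K, q, null_draws)
    p_comb <- (1 + sum(Hnull >= H - 1e-12)) / (null_draws + 1)
    nm <- "monte_carlo"
    nd <- as.integer(null_draws)
  }
  combined_result(pvals, ret, q, "fisher", H, p_comb, nm, nd, seed)
}

#' Combine factor p-values: truncated product on the q largest
#'
#' The statistic is `W = prod(p ^ (p <= tau))` over the `q` retained
#' (largest) p-values: only retained p-values at or below the truncation
#' point `tau` enter the product, so factors with unremarkable p-values
#' cannot dilute the evidence. Small `W` is evidence against the null;
#' the combined p-value is the add-one Monte-Carlo probability
#' `P(W_null <= W_obs)` under the chosen null (`"independent"`: q iid
#' uniforms; `"order_stat"`: q largest of K iid uniforms). At `tau = 1`
#' and `q = K` the ranking of W agrees with Fisher's statistic.
#'
#' @inheritParams fisher_combined
#' @param truncation Truncation point tau in (0, 1].
#' @return A one-row tibble of class `ef_combined`, as [fisher_combined()].
#' @export
truncated_product_combined <- function(pvals, q = length(pvals),
                                       truncation = 1, null_draws = 1e5L,
                                       seed = 1L,
                                       null_method = c("independent", "order_stat")) {
  null_method <- match.arg(null_method)
  check_pvals(pvals, q)
  if (!(truncation > 0 && truncation <= 1)) abort("`truncation` must lie in (0, 1].")
  K <- length(pvals)
  ret <- retain_largest(pvals, q)
  W <- prod(ret$p^(ret$p <= truncation))
  set.seed(seed)
  U <- matrix(runif(null_draws * K), null_draws, K)
  Wnull <- apply(U, 1, function(u) {
    keep <- if (null_method == "order_stat") {
      sort(u)[(K - q + 1):K]
    } else {
      u[seq_len(q)]  # q independent uniforms
    }
    prod(keep^(keep <= truncation))
  })
  p_comb <- (1 + sum(Wnull <= W + 1e-12)) / (null_draws + 1)
  combined_result(pvals, ret, q, "truncated_product", W, p_comb,
                  "monte_carlo", as.integer(null_draws), seed)
}

check_pvals <- function(pvals, q) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("all p-values must lie in (0, 1].")
  }
  if (q < 1 || q > length(pvals)) {
    abort(sprintf("`q` must lie in [1, %d].", length(pvals)))
  }
}

# q largest p-values, stable index order among ties
retain_largest <- function(pvals, q) {
  idx <- order(pvals, decreasing = TRUE)
  keep <- sort(head(idx, q))
  list(p = pvals[keep], idx = keep)
}

order_stat_fisher_null <- function(K, q, draws) {
  U <- matrix(runif(draws * K), draws, K)
  apply(U, 1, function(u) -2 * sum(log(sort(u)[(K - q + 1):K])))
}

combined_result <- function(pvals, ret, q, combiner, stat, p_comb,
                            null_method, null_draws, seed) {
  structure(
    tibble::tibble(
      q = as.integer(q),
      combiner = combiner,
      statistic = stat,
      p_combined = p_comb,
      null_method = null_method,
      null_draws = null_draws,
      seed = as.integer(seed),
      member_p = list(pvals),
      retained_p = list(ret$p),
      retained_idx = list(ret$idx)
    ),
    class = c("ef_combined", class(tibble::tibble()))
  )
}
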