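#' Stratified Wilcoxon rank-sum statistic
#'
#' Within each informative stratum (one containing both arms), outcomes
#' are ranked with mid-ranks for ties and the treated arm's rank sum is
#' taken; the statistic is the sum of those rank sums across strata.
#' Strata without assignment variation contribute zero. The statistic is
#' invariant to strictly monotone within-stratum transformations of the
#' outcome.
#'
#' @param y Outcome vector.
#' @param assignment 0/1 vector, same length.
#' @param strata Stratum labels, same length.
#' @return The statistic (a single number).
#' @export
#' @examples
#' stratified_rank_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1), rep("a", 4))  # 7
stratified_rank_statistic <- function(y, assignment, strata) {
  if (length(y) == 0) abort("empty input.")
  stopifnot(length(assignment) == length(y), length(strata) == length(y))
  info <- informative_strata(assignment, strata)
  total <- 0
  for (s in info) {
    idx <- strata == s
    r <- rank(y[idx], ties.method = "average")
    total <- total + sum(r[assignment[idx] == 1])
  }
  total
}

# --- internal machinery -----------------------------------------------------

# Decompose a comparison into informative strata with tilt scores.
# Scores are within-stratum mid-ranks, negated for alternative = "less" so
# that every tail computation is an upper tail of the tilt statistic.
prepare_strata <- function(comp, alternative) {
  comp <- as_comparison(comp)
  sign <- if (alternative == "less") -1 else 1
  info <- informative_strata(comp$assignment, comp$stratum)
  strata <- lapply(info, function(s) {
    idx <- which(comp$stratum == s)
    r <- rank(comp$outcome[idx], ties.method = "average")
    a <- comp$assignment[idx]
    ord <- order(sign * r, decreasing = TRUE)  # sorted by tilt score, desc
    list(
      scores = (sign * r)[ord],
      ranks = r[ord],
      treated_obs = which(a[ord] == 1),
      m = sum(a == 1),
      n = length(idx)
    )
  })
  strata
}

# Fisher noncentral hypergeometric pmf of t = #(treated drawn from the
# u = 1 group), for a stratum with n1 units at u = 1, n0 at u = 0, m treated.
nch_pmf <- function(n1, n0, m, gamma) {
  tvals <- max(0L, m - n0):min(m, n1)
  lw <- lchoose(n1, tvals) + lchoose(n0, m - tvals) + tvals * log(gamma)
  w <- exp(lw - max(lw))
  list(t = tvals, p = w / sum(w))
}

# Worst-case count of u = 1 units in a stratum: u is set to 1 on the b
# highest tilt scores, b chosen to maximize the expected tilted statistic
# (the separable, per-stratum rule; exact on strata of size 2).
choose_b <- function(scores, m, gamma) {
  n <- length(scores)
  best_b <- 0L
  best_e <- m * mean(scores)
  for (b in seq_len(n - 1L)) {
    pm <- nch_pmf(b, n - b, m, gamma)
    et <- sum(pm$t * pm$p)
    e <- et * mean(scores[seq_len(b)]) + (m - et) * mean(scores[(b + 1L):n])
    if (e > best_e + 1e-12) {
      best_e <- e
      best_b <- b
    }
  }
  best_b
}

# Monte-Carlo draws of the (possibly tilted) within-stratum statistic.
# gamma = 1: uniform sampling of m-subsets. gamma > 1: t ~ noncentral
# hypergeometric with odds gamma, then the treated set takes the first t
# of a random ordering of the u = 1 group plus the first m - t of the
# u = 0 group; since the u = 1 group holds the top scores, draws are
# monotone in t.
stratum_draws <- function(st, gamma, n_perm) {
  s <- st$scores
  n <- st$n
  m <- st$m
  if (gamma == 1) {
    return(vapply(seq_len(n_perm),
                  function(b) sum(s[sample.int(n, m)]), numeric(1)))
  }
  b <- choose_b(s, m, gamma)
  if (b == 0L) {
    return(vapply(seq_len(n_perm),
                  function(b_) sum(s[sample.int(n, m)]), numeric(1)))
  }
  pm <- nch_pmf(b, n - b, m, gamma)
  cw <- cumsum(pm$p)
  out <- numeric(n_perm)
  g1 <- seq_len(b)
  g0 <- if (b < n) (b + 1L):n else integer(0)
  for (i in seq_len(n_perm)) {
    v <- runif(1)
    t_i <- pm$t[findInterval(v, cw, left.open = TRUE) + 1L]
    k1 <- if (t_i > 0) g1[sample.int(b, t_i)] else integer(0)
    need0 <- m - t_i
    k0 <- if (need0 > 0) g0[sample.int(n - b, need0)] else integer(0)
    out[i] <- sum(s[k1]) + sum(s[k0])
  }
  out
}

# Shared Monte-Carlo tail engine behind randomization_pvalue() and
# worst_case_pvalue(). Returns the add-one upper-tail p of the tilt
# statistic, together with bookkeeping.
tilted_pvalue <- function(comp, alternative, gamma, n_perm, seed = NULL) {
  comp <- as_comparison(comp)
  if (isTRUE(comp$degenerate)) {
    return(list(p = 1, statistic = NA_real_, n_strata = 0L, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  strata <- prepare_strata(comp, alternative)
  if (length(strata) == 0) {
    return(list(p = 1, statistic = NA_real_, n_strata = 0L, degenerate = TRUE))
  }
  t_obs <- sum(vapply(strata, function(st) sum(st$scores[st$treated_obs]),
                      numeric(1)))
  draws <- numeric(n_perm)
  for (st in strata) draws <- draws + stratum_draws(st, gamma, n_perm)
  p <- (1 + sum(draws >= t_obs - 1e-9)) / (n_perm + 1)
  stat <- sum(vapply(strata, function(st) sum(st$ranks[st$treated_obs]),
                     numeric(1)))
  list(p = p, statistic = stat, n_strata = length(strata), degenerate = FALSE)
}

test_result <- function(comp, res, method, alternative, n_perm, seed) {
  comp <- as_comparison(comp)
  tibble::tibble(
    level = comp$level %||% NA_integer_,
    statistic = res$statistic,
    p_value = res$p,
    method = method,
    alternative = alternative,
    n_perm = n_perm %||% NA_integer_,
    seed = seed %||% NA_integer_,
    n_treat = sum(comp$assignment == 1),
    n_control = sum(comp$assignment == 0),
    n_strata_informative = res$n_strata,
    degenerate = res$degenerate
  )
}

# --- user-facing tests ------------------------------------------------------

#' Randomization p-value for one factor
#'
#' Holds outcomes fixed and permutes the assignment independently within
#' each stratum, preserving the within-stratum treated counts (the
#' conditional randomization distribution implied by assignment
#' probabilities that are constant within strata). The one-sided
#' Monte-Carlo p-value uses the add-one convention
#' `(1 + #(T* >= T_obs)) / (n_perm + 1)`, which is valid at any finite
#' number of draws and never exactly zero. A degenerate comparison
#' reports p = 1.
#'
#' @param comp One factor: a one-row slice of [build_factors()] output.
#' @param alternative `"greater"` or `"less"`.
#' @param n_perm Number of permutation draws.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A one-row tibble (level, statistic, p_value, method, n_perm,
#'   seed, arm sizes, informative stratum count, degenerate flag).
#' @export
randomization_pvalue <- function(comp, alternative = c("greater", "less"),
                                 n_perm = 999L, seed = NULL) {
  alternative <- match.arg(alternative)
  res <- tilted_pvalue(comp, alternative, gamma = 1, n_perm = n_perm,
                       seed = seed)
  test_result(comp, res, "monte_carlo", alternative, n_perm, seed)
}

#' Exact randomization p-value by full enumeration
#'
#' Enumerates the within-stratum assignment space exactly (the product
#' over strata of all equal-count treated sets), convolving the
#' independent per-stratum distributions of the rank-sum contribution.
#' Intended as the oracle against which Monte-Carlo p-values are checked;
#' refuses spaces larger than `limit`.
#'
#' @inheritParams randomization_pvalue
#' @param gamma Sensitivity parameter; `gamma = 1` (default) is the
#'   uniform randomization distribution, `gamma > 1` the worst-case tilted
#'   law used by [worst_case_pvalue()].
#' @param limit Maximum size of the enumeration space (product over
#'   strata of the per-stratum assignment counts).
#' @return A one-row tibble as in [randomization_pvalue()], with
#'   `method = "exact"`; the p-value is a ratio of integers when
#'   `gamma = 1`.
#' @export
exact_enumeration_pvalue <- function(comp, alternative = c("greater", "less"),
                                     gamma = 1, limit = 1e6) {
  alternative <- match.arg(alternative)
  comp <- as_comparison(comp)
  if (isTRUE(comp$degenerate)) {
    return(test_result(comp, list(p = 1, statistic = NA_real_, n_strata = 0L,
                                  degenerate = TRUE),
                       "exact", alternative, NULL, NULL))
  }
  if (gamma < 1) abort("`gamma` must be >= 1.")
  strata <- prepare_strata(comp, alternative)
  if (length(strata) == 0) {
    return(test_result(comp, list(p = 1, statistic = NA_real_, n_strata = 0L,
                                  degenerate = TRUE),
                       "exact", alternative, NULL, NULL))
  }
  space <- prod(vapply(strata, function(st) choose(st$n, st$m), numeric(1)))
  if (space > limit) {
    abort(sprintf(
      "enumeration space has %.3g assignments (> limit %.3g); use the Monte-Carlo test.",
      space, limit))
  }
  # per-stratum exact distribution of the tilt statistic, then convolution
  dist <- list(value = 0, prob = 1)
  t_obs <- 0
  for (st in strata) {
    t_obs <- t_obs + sum(st$scores[st$treated_obs])
    b <- if (gamma > 1) choose_b(st$scores, st$m, gamma) else 0L
    sets <- combn(st$n, st$m)
    vals <- apply(sets, 2, function(ix) sum(st$scores[ix]))
    w <- if (b > 0) {
      gamma^apply(sets, 2, function(ix) sum(ix <= b))
    } else {
      rep(1, ncol(sets))
    }
    w <- w / sum(w)
    key <- round(vals, 9)
    tab <- rowsum(w, key)
    sd <- list(value = as.numeric(rownames(tab)), prob = as.numeric(tab))
    # convolve
    v <- outer(dist$value, sd$value, `+`)
    p <- outer(dist$prob, sd$prob, `*`)
    key2 <- round(as.numeric(v), 9)
    tab2 <- rowsum(as.numeric(p), key2)
    dist <- list(value = as.numeric(rownames(tab2)), prob = as.numeric(tab2))
  }
  pv <- sum(dist$prob[dist$value >= t_obs - 1e-9])
  stat <- sum(vapply(strata, function(st) sum(st$ranks[st$treated_obs]),
                     numeric(1)))
  test_result(comp, list(p = pv, statistic = stat,
                         n_strata = length(strata), degenerate = FALSE),
              "exact", alternative, NULL, NULL)
}
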