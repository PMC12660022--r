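# Shared fixtures and an independent brute-force oracle.

# A comparison object from bare vectors (bypasses build_factors).
make_comp <- function(y, assignment, strata = rep("s1", length(y)),
                      level = 1L) {
  list(level = level, rows = seq_along(y),
       assignment = as.integer(assignment), stratum = as.character(strata),
       outcome = as.numeric(y), degenerate = FALSE)
}

# Independent oracle: enumerate the full within-stratum assignment product
# space directly (no convolution, no shared code with the package) and
# compute the tail probability of the stratified treated rank sum under
# the uniform or a Gamma-tilted law with a given binary u.
brute_force_pvalue <- function(y, assignment, strata,
                               alternative = "greater",
                               gamma = 1, u = NULL) {
  strata <- as.character(strata)
  if (is.null(u)) u <- rep(0, length(y))
  labs <- unique(strata)
  per <- lapply(labs, function(s) {
    idx <- which(strata == s)
    m <- sum(assignment[idx] == 1)
    sets <- utils::combn(length(idx), m)
    list(idx = idx, sets = sets)
  })
  # keep only strata with assignment variation (others contribute a
  # constant and cancel from the tail comparison only if dropped on both
  # sides; the statistic below uses every stratum, matching the package)
  stat_of <- function(assign_vec) {
    tot <- 0
    for (s in labs) {
      idx <- which(strata == s)
      if (length(unique(assignment[idx])) < 2) next  # non-informative
      r <- rank(y[idx], ties.method = "average")
      sgn <- if (alternative == "less") -1 else 1
      tot <- tot + sum((sgn * r)[assign_vec[idx] == 1])
    }
    tot
  }
  t_obs <- stat_of(assignment)
  combo_idx <- lapply(per, function(p) seq_len(ncol(p$sets)))
  grid <- expand.grid(combo_idx)
  tail_w <- 0
  tot_w <- 0
  for (g in seq_len(nrow(grid))) {
    av <- integer(length(y))
    for (j in seq_along(per)) {
      chosen <- per[[j]]$idx[per[[j]]$sets[, grid[g, j]]]
      av[chosen] <- 1L
    }
    w <- gamma^sum(u[av == 1])
    tot_w <- tot_w + w
    if (stat_of(av) >= t_obs - 1e-9) tail_w <- tail_w + w
  }
  tail_w / tot_w
}

# Random small enumerable fixture (strata of size 2-6).
random_fixture <- function(n_strata = 2, sizes = NULL, seed = 1) {
  set.seed(seed)
  sizes <- sizes %||% sample(2:6, n_strata, replace = TRUE)
  y <- numeric(0); a <- integer(0); s <- character(0)
  for (j in seq_len(n_strata)) {
    n <- sizes[j]
    m <- sample(seq_len(n - 1), 1)
    y <- c(y, round(rnorm(n), 2))
    a <- c(a, sample(rep(c(1L, 0L), c(m, n - m))))
    s <- c(s, rep(paste0("s", j), n))
  }
  make_comp(y, a, s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-sided K=2 toy table covering all window x status patterns.
toy_table_k2 <- function() {
  pats <- expand.grid(win = c(TRUE, FALSE), z1 = 0:1, z2 = 0:1)
  n <- nrow(pats) * 2
  tibble::tibble(
    id = as.character(seq_len(n)),
    running = rep(ifelse(pats$win, ifelse(pats$z1 == 1, 0.3, -0.3),
                         ifelse(pats$z1 == 1, 2, -2)), each = 2),
    z1 = rep(pats$z1, each = 2),
    z2 = rep(pats$z2, each = 2),
    y = seq_len(n) * 1.0,
    cov_g = rep(c("a", "b"), n / 2)
  )
}
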