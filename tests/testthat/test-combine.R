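test_that("Fisher combination reproduces closed-form values", {
  # boundary: all retained p-values are 1
  expect_equal(fisher_combined(c(1, 1), q = 2)$p_combined, 1)
  # chi-square(4) upper tail at H = -4 log 0.5: (1 + H/2) exp(-H/2)
  r <- fisher_combined(c(0.5, 0.5), q = 2)
  H <- -4 * log(0.5)
  expect_equal(r$statistic, H, tolerance = 1e-12)
  expect_equal(r$p_combined, (1 + H / 2) * exp(-H / 2), tolerance = 1e-12)
  expect_equal(r$null_method, "closed_form")
  # q < K, independent reference: chi-square(2q) on the q largest
  r2 <- fisher_combined(c(0.001, 0.8), q = 1)
  expect_equal(r2$retained_p[[1]], 0.8)
  expect_equal(r2$p_combined, 0.8, tolerance = 1e-12)  # chisq(2) tail of -2log(0.8)
  # q < K, order-statistic reference: max-of-two-uniforms law gives 0.8^2
  r3 <- fisher_combined(c(0.001, 0.8), q = 1, null_method = "order_stat",
                        null_draws = 1e5, seed = 3)
  se <- sqrt(0.64 * 0.36 / 1e5)
  expect_lt(abs(r3$p_combined - 0.64), 3 * se)
  expect_error(fisher_combined(c(0, 0.5), q = 1), "\\(0, 1\\]")
  expect_error(fisher_combined(c(0.4, 0.5), q = 3), "q")
})

test_that("truncated product handles truncation boundaries and matches Fisher at tau = 1", {
  # every retained p above tau: empty product, W = 1, p = 1
  r <- truncated_product_combined(c(0.7, 0.9), q = 2, truncation = 0.5,
                                  null_draws = 2000, seed = 1)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_combined, 1)
  # tau = 1, q = K: same evidence ordering as Fisher
  p <- c(0.1, 0.35)
  rf <- fisher_combined(p, q = 2)
  rt <- truncated_product_combined(p, q = 2, truncation = 1,
                                   null_draws = 2e4, seed = 2)
  expect_lt(abs(rt$p_combined - rf$p_combined),
            3 * sqrt(rf$p_combined * (1 - rf$p_combined) / 2e4) + 1e-3)
  # K=2, q=2, tau=0.5, p=(0.1,0.9): W = 0.1. Closed form for two uniforms:
  # P(W <= w) = w (2 + log(tau^2 / w)) here = 0.1 (2 + log 2.5) = 0.29163
  ref <- 0.1 * (2 + log(2.5))
  r2 <- truncated_product_combined(c(0.1, 0.9), q = 2, truncation = 0.5,
                                   null_draws = 5e4, seed = 4)
  expect_equal(r2$statistic, 0.1)
  expect_lt(abs(r2$p_combined - ref), 3 * sqrt(ref * (1 - ref) / 5e4) + 1e-3)
})

test_that("discarding small (possibly biased) p-values never strengthens the evidence", {
  # the protective regime the retention rule exists for: the discarded
  # p-values are small (as biased factors tend to be), the retained ones
  # ordinary; lowering q must then not decrease the combined p. (With
  # large discarded p-values the combined p can move either way -- losing
  # a near-1 p-value genuinely removes support for the null.)
  set.seed(12)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    q <- sample(seq_len(K - 1), 1)
    p <- c(runif(K - q, 0.0001, 0.1), runif(q, 0.15, 1))
    pc_lo <- fisher_combined(p, q = q)$p_combined
    pc_hi <- fisher_combined(p, q = q + 1)$p_combined
    expect_gte(pc_lo, pc_hi - 1e-12)
  }
  # order-stat null with common random numbers behaves the same way
  p <- c(0.02, 0.3, 0.6)
  pcs <- vapply(c(3, 2), function(q) {
    fisher_combined(p, q = q, null_method = "order_stat", null_draws = 2e4,
                    seed = 99)$p_combined
  }, numeric(1))
  expect_true(diff(pcs) >= -0.01)
})

test_that("combined p-value depends on the p-values only through their multiset", {
  p <- c(0.03, 0.5, 0.77)
  for (q in 1:3) {
    a <- fisher_combined(p, q = q, seed = 5)$p_combined
    b <- fisher_combined(rev(p), q = q, seed = 5)$p_combined
    expect_identical(a, b)
  }
})

test_that("with independent uniform inputs the combined p-value is superuniform", {
  set.seed(8)
  nsim <- 4000
  U <- matrix(runif(nsim * 3), nsim, 3)
  for (q in c(2, 3)) {
    pc <- apply(U, 1, function(u) {
      h <- -2 * sum(log(sort(u, decreasing = TRUE)[seq_len(q)]))
      pchisq(h, 2 * q, lower.tail = FALSE)
    })
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_lte(mean(pc <= alpha),
                 alpha + 3 * sqrt(alpha * (1 - alpha) / nsim))
    }
  }
  # spot-check that the vectorized null above matches the package function
  u0 <- U[1, ]
  expect_equal(fisher_combined(u0, q = 2)$p_combined,
               pchisq(-2 * sum(log(sort(u0, decreasing = TRUE)[1:2])), 4,
                      lower.tail = FALSE))
})
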