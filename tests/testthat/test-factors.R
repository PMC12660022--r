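# Expected membership follows the two treatment-status tables of the
# construction: level 1 compares eligibility inside the window; level
# k >= 2 keeps only subjects with all earlier statuses 1 (in or out of
# the window) and compares status k; everyone else is excluded.

test_that("K = 2 two-sided membership matches the construction cell-for-cell", {
  des <- ef_design(K = 2, compliance = "two_sided", cutoff = 0,
                   window = c(-1, 1))
  tab <- toy_table_k2()
  mem <- factor_membership(tab, des)
  expected <- function(win, z1, z2) {
    ef1 <- if (win) (if (z1 == 1) "T" else "C") else "."
    ef2 <- if (z1 == 1) (if (z2 == 1) "T" else "C") else "."
    c(ef1, ef2)
  }
  for (i in seq_len(nrow(mem))) {
    e <- expected(mem$in_window[i], tab$z1[i], tab$z2[i])
    expect_identical(c(mem$ef1[i], mem$ef2[i]), e,
                     label = paste("row", i, mem$pattern[i]))
  }
  # spot checks called out explicitly: inside window (0,1) -> EF1 control,
  # EF2 excluded; outside window (1,0) -> EF1 excluded, EF2 control
  r_in_01 <- which(mem$in_window & mem$pattern == "01")
  expect_true(all(mem$ef1[r_in_01] == "C" & mem$ef2[r_in_01] == "."))
  r_out_10 <- which(!mem$in_window & mem$pattern == "10")
  expect_true(all(mem$ef1[r_out_10] == "." & mem$ef2[r_out_10] == "C"))
})

toy_table_k3 <- function() {
  pats <- expand.grid(win = c(TRUE, FALSE),
                      p = c("000", "100", "110", "111"),
                      stringsAsFactors = FALSE)
  z <- do.call(rbind, strsplit(pats$p, ""))
  n <- nrow(pats) * 2
  tibble::tibble(
    id = as.character(seq_len(n)),
    running = rep(ifelse(pats$win, ifelse(z[, 1] == "1", 0.4, -0.4),
                         ifelse(z[, 1] == "1", 3, -3)), each = 2),
    z1 = rep(as.integer(z[, 1]), each = 2),
    z2 = rep(as.integer(z[, 2]), each = 2),
    z3 = rep(as.integer(z[, 3]), each = 2),
    y = seq_len(n) * 1.0,
    cov_g = rep(c("a", "b"), n / 2)
  )
}

test_that("K = 3 one-sided membership matches the construction cell-for-cell", {
  des <- ef_design(K = 3, compliance = "one_sided", cutoff = 0,
                   window = c(-1, 1))
  tab <- toy_table_k3()
  mem <- factor_membership(tab, des)
  expected <- function(win, z1, z2, z3) {
    c(if (win) (if (z1 == 1) "T" else "C") else ".",
      if (z1 == 1) (if (z2 == 1) "T" else "C") else ".",
      if (z1 == 1 && z2 == 1) (if (z3 == 1) "T" else "C") else ".")
  }
  for (i in seq_len(nrow(mem))) {
    e <- expected(mem$in_window[i], tab$z1[i], tab$z2[i], tab$z3[i])
    expect_identical(c(mem$ef1[i], mem$ef2[i], mem$ef3[i]), e,
                     label = paste("row", i, mem$pattern[i]))
  }
  # (1,1,0) inside the window: treated in EF1 and EF2, control in EF3
  r <- which(mem$in_window & mem$pattern == "110")
  expect_true(all(mem$ef1[r] == "T" & mem$ef2[r] == "T" & mem$ef3[r] == "C"))
})

test_that("factor subject sets nest across levels in the one-sided design", {
  des <- ef_design(K = 3, compliance = "one_sided", cutoff = 0,
                   window = c(-1, 1))
  dat <- ef_stratify(sim_generate(sim_case("design1", n = 400, seed = 21)),
                     "cov_c")
  facs <- build_factors(dat, des)
  expect_true(all(facs$rows[[3]] %in% facs$rows[[2]]))
  # no subject enters EF k (k >= 2) with an earlier status of 0
  for (k in 2:3) {
    prior <- as.matrix(dat[facs$rows[[k]], paste0("z", seq_len(k - 1))])
    expect_true(all(prior == 1))
  }
  # construction is deterministic and row-order invariant
  perm <- sample(nrow(dat))
  facs2 <- build_factors(dat[perm, ], des)
  for (k in 1:3) {
    expect_setequal(dat$id[facs$rows[[k]]], dat$id[perm][facs2$rows[[k]]])
  }
})

test_that("unconditioned comparisons ignore earlier statuses except at level 1", {
  des <- ef_design(K = 2, compliance = "two_sided", cutoff = 0,
                   window = c(-1, 1))
  tab <- ef_stratify(toy_table_k2(), "cov_g")
  ef <- build_factors(tab, des, residualize = FALSE)
  un <- build_unconditioned(tab, des, residualize = FALSE)
  # level 1 coincides element-for-element
  expect_identical(un$rows[[1]], ef$rows[[1]])
  expect_identical(un$assignment[[1]], ef$assignment[[1]])
  # level 2 uses every subject, with (0,1) subjects in the treated arm
  expect_equal(un$rows[[2]], seq_len(nrow(tab)))
  i01 <- which(tab$z1 == 0 & tab$z2 == 1)
  expect_true(all(un$assignment[[2]][i01] == 1))
  expect_equal(sum(un$assignment[[2]] == 0), sum(tab$z2 == 0))
})

test_that("degenerate factors are flagged and report p = 1", {
  des <- ef_design(K = 2, compliance = "one_sided", cutoff = 0,
                   window = c(-1, 1))
  tab <- tibble::tibble(
    id = as.character(1:6), running = c(-0.5, 0.5, -0.5, 0.5, -0.5, 0.5),
    z1 = rep(c(0L, 1L), 3), z2 = rep(c(0L, 1L), 3), y = rnorm(6),
    cov_g = "a"
  )
  tab <- ef_stratify(tab, "cov_g")
  expect_warning(facs <- build_factors(tab, des), "degenerate")
  expect_true(facs$degenerate[2])  # all z1 = 1 subjects have z2 = 1
  res <- randomization_pvalue(facs[2, ], n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})
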