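# Heavier simulation runs shared across test files, computed at most once
# per session. Profile: n = 500 subjects, 500 replicates, 400 permutation
# draws -- tight enough Monte-Carlo bands to detect level violations of
# about 0.03 while keeping the default test run inside a few minutes.

.study_cache <- new.env(parent = emptyenv())

get_null_study <- function() {
  if (is.null(.study_cache$null)) {
    .study_cache$null <- run_study(
      sim_case("design1", n = 500, lambdas = c(0, 0, 0), effect = 0),
      replicates = 500, n_perm = 400L, seed = 2024L,
      include_unconditioned = FALSE, keep_pvalues = TRUE
    )
  }
  .study_cache$null
}

get_biased_study <- function() {
  if (is.null(.study_cache$biased)) {
    .study_cache$biased <- run_study(
      design1_case(2, lambda = 2, n = 500),
      replicates = 500, n_perm = 400L, seed = 4048L,
      include_unconditioned = TRUE
    )
  }
  .study_cache$biased
}
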