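# efrd — evidence factors for fuzzy regression discontinuity designs

Regression discontinuity (RD) designs assign *eligibility* for a treatment
by a cutoff `c` on a running variable `X`, but eligibility rarely
determines actual use. When uptake unfolds through a sequence of decisions
— a policy rule sets eligibility (`Z1`), an administrator grants the
treatment (`Z2`), the subject chooses to use it (`Z3`) — each step is
exposed to its *own* unmeasured biases. `efrd` turns this sequential
structure into **evidence factors**: up to `K` nearly independent tests of
the same sharp null hypothesis

&nbsp;&nbsp;&nbsp;&nbsp;`H0 : Y(z) = Y(z')` for all admissible treatment vectors `z, z'`,

built from one dataset, such that a bias that invalidates one factor
leaves the others intact.

The construction, for subjects stratified exactly on discrete covariates:

* **Factor 1** is the intent-to-treat RD comparison: subjects inside a
  local-randomization window `(c - w, c + w)` compared by `Z1`, using the
  outcome residualized on the running variable.
* **Factor k ≥ 2** keeps only subjects with `Z1 = … = Z_{k-1} = 1` (inside
  or outside the window) and compares them by `Z_k`. Variation of `Z_k`
  among subjects with an earlier status 0 is never used — those "exception"
  mechanisms carry no assignment model.

Each factor is tested by randomization inference on the stratified
Wilcoxon rank-sum statistic: assignments are permuted within strata with
treated counts fixed, outcomes held fixed. The `K` one-sided p-values are
combined into one valid p-value from their `q` largest order statistics
(Fisher's `H = -2 Σ log p` against χ² with `2q` df, or the truncated
product), so that up to `K - q` biased factors — which tend toward small
p-values and are discarded — cannot invalidate the combination. Each
factor also admits a Rosenbaum-style sensitivity analysis: a worst-case
p-value under within-stratum assignment odds tilted by up to `Γ_k ≥ 1`.

A built-in simulator generates the two benchmark designs (K = 3 with
one-sided non-compliance; K = 2 with two-sided non-compliance), with
per-level bias coefficients `λ_k`, and `run_study()` reproduces the
validity/power comparison between the conditioned evidence factors and
naive unconditioned (as-treated style) comparisons.

## Worked example

Two-level design (eligibility, use) with two-sided non-compliance and a
true effect of 0.6 on the final status:

```r
library(efrd)

dat    <- sim_generate(sim_case("design2", n = 400, effect = 0.6, seed = 42))
dat    <- ef_stratify(dat, "cov_c")
design <- ef_design(K = 2, compliance = "two_sided", cutoff = 0,
                    window = c(-0.5, 0.5))
config <- ef_config(q = 2, n_perm = 2000, seed = 7)

(ana <- ef_analyze(dat, design, config))
#> Evidence-factor analysis (K = 2 levels, two_sided non-compliance)
#> window: ( -0.5 , 0.5 )
#>
#> # A tibble: 2 × 6
#>   level statistic p_value n_treat n_control n_strata_informative
#>   <int>     <dbl>   <dbl>   <int>     <int>                <int>
#> 1     1      4187 0.0335       91        78                    2
#> 2     2      7611 0.00150     122        97                    2
#>
#> combined p-value (fisher, q = 2 of 2): 0.0005472
```

Factor 1 (the RD comparison of 169 subjects near the cutoff, p = 0.034)
and factor 2 (use vs non-use among the 219 eligible, p = 0.0015) agree;
Fisher's combination gives p = 0.00055. `tidy(ana)` returns the per-factor
table, `glance(ana)` the one-row summary, `autoplot(ana)` a p-value chart.

How much hidden bias would overturn this?

```r
ef_sensitivity(ana, gamma_grid = list(c(1, 1.5, 2), c(1, 1.5, 2)))
#>   gamma_1 gamma_2    p_1    p_2 p_combined
#> 1     1.0     1.0 0.0335 0.0015   0.000547
#> 2     1.5     1.0 0.2394 0.0015   0.003206
#> ...
#> 6     2.0     1.5 0.5082 0.0300   0.079001
#> 9     2.0     2.0 0.5082 0.1939   0.326910
```

The joint conclusion survives `Γ = 1.5` at both levels (worst-case
combined p = 0.043) but not `Γ = 2` at the eligibility level together with
`Γ = 1.5` at the use level.

The simulation study comparing evidence factors with unconditioned
comparisons across bias cases:

```r
st <- run_study(design1_case(2, lambda = 2, n = 500), replicates = 500,
                n_perm = 400, seed = 1)
plot_rejection_rates(st)
```

File-level entry points (`ef_cmd_analyze()`, `ef_cmd_sensitivity()`,
`ef_cmd_simulate()`, `ef_cmd_validate()`) read a delimited subject table
plus a YAML/JSON config and write JSON results, delimited audit tables and
a run manifest; `inst/cli/efrd.R` wraps them for the shell.

## Scope

The package tests the sharp null only: it produces no effect-size
estimates or confidence intervals, and no continuity-based (regression
extrapolation) RD analysis. Covariates must be discrete (pre-bin
continuous ones); ordinal running variables need a numeric surrogate
before use.
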