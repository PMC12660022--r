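---
title: "Evidence factors in fuzzy RD designs: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence factors in fuzzy RD designs: models, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical content: the
model behind each step, the tunable parameters and their defaults, the
numerical decisions taken where the method leaves room, and what the
simulation evidence does and does not establish.

## The design and its assumptions

A fuzzy RD design with sequential treatment assignments records, for each
subject, a running variable $X$, discrete covariates, an outcome $Y$, and
$K \ge 2$ binary statuses $Z_1, \dots, Z_K$: $Z_1$ is eligibility, set
deterministically by a cutoff $c$ on $X$ (ties eligible), and each later
$Z_k$ is a decision taken after $Z_{k-1}$. Under one-sided non-compliance
the statuses are nested ($Z_k = 1$ requires $Z_{k-1} = 1$); under
two-sided non-compliance ineligible subjects may still obtain treatment.

The package tests the sharp null that treatment has exactly no effect:
all potential outcomes coincide. Three substantive assumptions carry the
construction:

1. **Exclusion**: the status vector affects $Y$ only through the final
   status $Z_K$ (actual use).
2. **Causal ordering without shared hidden causes**: the $Z_k$ are
   causally ordered and no unmeasured variable is a common cause of two
   of them. This is untestable from data; `validate_design()` surfaces
   it as a caveat, never as a check.
3. **Local randomization**: within a window $(c - w,\, c + w)$ and within
   strata formed by exact matching on the covariates, eligibility is as
   good as randomly assigned.

Factor 1 compares eligible with ineligible subjects inside the window
(intent-to-treat). Factor $k \ge 2$ conditions on $Z_1 = \dots =
Z_{k-1} = 1$ and compares $Z_k$ there, with no window restriction.
Conditioning is what isolates bias: an unmeasured covariate acting on
level $j$'s assignment can invalidate factor $j$ only, because every
other factor either precedes $j$ or holds $Z_j$'s antecedents fixed.
Variation of $Z_k$ among subjects with an earlier status 0 ("exceptions",
e.g. treatment uptake among the ineligible) is never used: no assignment
model is posited for it. The unconditioned benchmarks
(`build_unconditioned()`) deliberately break this rule to demonstrate the
spillover.

## Inference

Each factor is tested by randomization inference on the stratified
Wilcoxon rank-sum statistic: within every stratum containing both arms,
outcomes are mid-ranked and the treated arm's rank sum taken; strata
without assignment variation contribute nothing. The null distribution
permutes assignments independently within strata with treated counts
fixed — the conditional distribution implied by assignment probabilities
constant within strata. Monte-Carlo p-values use the add-one convention
$(1 + \#\{T^* \ge T_{\mathrm{obs}}\})/(B + 1)$, valid at any number of
draws and never zero; `exact_enumeration_pvalue()` convolves the exact
per-stratum distributions for small problems and is the oracle the test
suite compares against. A factor whose strata contain no assignment
variation is *degenerate* and reports $p = 1$ with a warning — a
conservative value that preserves validity and keeps batch simulations
alive.

The statistic is the rank-sum (two-sample) form throughout. Descriptions
of this family of methods sometimes name the signed-rank statistic, but
every comparison here is between two independent arms within strata —
there are no matched pairs — so the rank-sum form is the one the data
structure admits; mid-ranks handle ties.

### Residualization at level 1

Factor 1 replaces $Y$ by the residuals of an OLS fit of $Y$ on $X$, to
absorb the outcome's trend in the running variable. Two numerical
choices matter and both were driven by calibration analysis, not
convenience:

* **Fit on the full sample, not the window.** Inside a narrow window the
  eligibility indicator is nearly collinear with $X$ (correlation above
  0.85 in the simulated designs), so residuals from a window-only fit are
  nearly orthogonal to the assignment and the test collapses toward
  $p \approx 0.5$ — in a 1500-replicate null experiment the window-fit
  version rejected at rate 0.000 at $\alpha = 0.05$.
* **Include stratum intercepts.** When covariates shift both $X$ and
  $Y$, the marginal slope of $Y$ on $X$ contains a between-strata
  component that does not exist inside any stratum; removing it tilts
  the one-sided stratified comparison. A plain $Y \sim X$ fit measured
  0.039 rejection at $\alpha = 0.05$ (0.211 at $\alpha = 0.25$) under the
  null, while the stratum-intercept fit restored 0.048 (0.251). The
  pipeline therefore fits one intercept per stratum plus a common slope;
  `residualize_outcome()` keeps the plain line as its default for
  stand-alone use.

## Window selection

`select_window()` implements the covariate-balance rule: for each
candidate symmetric width, every covariate gets a two-sided randomization
p-value for the difference in means between eligible and ineligible
subjects inside the window, permuting eligibility freely; the chosen
window is the *largest* candidate whose minimum per-covariate p-value
exceeds the threshold (default 0.15). Free permutation (rather than
within-stratum permutation) is used because the balance test asks whether
stratification is needed at all inside the window; this choice is
deliberate and a user who wants the stricter variant can pre-stratify and
test balance per stratum. No candidate passing is an error, never a
silent fallback. Candidates are symmetric in running-variable units,
matching how such windows are reported in practice.

## Combining the factor p-values

With up to $K - q$ factors conjectured biased, the combination retains
the $q$ largest p-values — biased factors tend toward small p-values and
are discarded — and computes Fisher's $H = -2 \sum \log p$ (or the
truncated product $W = \prod p^{1(p \le \tau)}$, which additionally keeps
unremarkable retained p-values out of the product).

Two reference distributions are implemented, and the difference matters:

* `"independent"` (default): $H$ is referred to $\chi^2_{2q}$, i.e. the
  retained values are treated as $q$ independent p-values. Since the
  $j$-th largest of all $K$ p-values is at least the $j$-th largest of
  any $q$ valid ones, this stays valid whenever at least $q$ factors are
  valid — the guarantee the whole construction exists for. It is
  conservative when all $K$ factors are valid and $q < K$.
* `"order_stat"`: $H$ is referred to its exact Monte-Carlo null under
  the $q$ largest order statistics of $K$ independent uniforms. This is
  exact when **all** $K$ factors are valid, but a direct calculation
  shows it does not survive bias: with $K = 3$, $q = 2$ and one factor
  pushed to $p \approx 0$, its rejection rate at nominal 0.05 is about
  0.23. It is provided as a diagnostic and for the exact-null boundary
  case, never as the default.

At $q = K$ the two coincide (closed-form $\chi^2_{2K}$). Ties at the
retention boundary are kept by sorted position with stable index order.
Degenerate factors enter as $p = 1$, which is conservative.

One property deserves a warning because it is often assumed: lowering
$q$ does **not** universally increase the combined p-value. When the
discarded p-values are small — the regime the retention rule exists
for — it does (verified over 50,000 random configurations with discarded
values below 0.1); but discarding a p-value near 1 genuinely removes
support for the null and can lower the combined p-value. The test suite
asserts the property in its valid regime only.

## Sensitivity analysis

For factor $k$, an unmeasured binary covariate $u$ may tilt
within-stratum assignment odds by at most $\Gamma_k \ge 1$: treated sets
$a$ receive probability proportional to $\Gamma^{\sum_i a_i u_i}$ with
treated counts fixed. The reported bound is the tail probability at the
worst-case $u$:

* $u$ is set to 1 on the units with the **largest** within-stratum rank
  scores (mirrored for `alternative = "less"`): tilting toward
  high-score units stochastically increases the statistic.
* The **number** of such units per stratum is chosen by the separable
  rule — maximize the stratum's expected tilted statistic — the standard
  per-stratum device in stratified sensitivity analysis. On strata of
  size two it is exactly optimal, which the closed form
  $\Gamma/(1+\Gamma)$ on the paired fixture confirms.
* $u$ is per-subject and binary. The maximization over $u \in [0,1]^n$
  is attained at extreme points for exponential tilts of a one-sided
  tail, so binary $u$ loses nothing.

Sampling from the tilted law exploits that with binary $u$ the tilt acts
only through $t$, the number of treated drawn from the $u = 1$ group:
$t$ follows Fisher's noncentral hypergeometric distribution with odds
$\Gamma$, after which the sets within each group are uniform. Draws are
therefore exact (inverse-CDF on $t$, uniform subsets within groups), and
at $\Gamma = 1$ the sampler *is* the uniform permutation sampler, so the
bound at $\Gamma = 1$ equals the unadjusted p-value bit-for-bit at the
same seed. `sensitivity_profile()` reuses one seed per level across its
$\Gamma$ grid (common random numbers), keeping each level's curve
monotone up to Monte-Carlo noise; grids default to
$\{1, 1.1, 1.2, 1.5, 2\}$ per level, small steps near 1 where causal
conclusions typically tip.

## The simulator

`sim_generate()` fixes the causal structure of the benchmark designs and
exposes every coefficient as a parameter (`sim_params()`), with defaults
chosen once to give a realistic, moderately fuzzy design:

* $C \sim \mathrm{Bern}(0.5)$ — one binary baseline covariate, the
  stratification variable;
* $X \sim N(0.3\,C,\ 1)$, cutoff 0, eligible iff $X \ge 0$ — covariates
  shift the running variable, so eligibility is confounded by $C$ and
  stratification is genuinely needed;
* $U_1, \dots, U_K \sim \mathrm{Unif}(0,1)$ i.i.d. — level-specific
  unmeasured covariates;
* $Z_2 \mid Z_1{=}1 \sim \mathrm{Bern}(\mathrm{logit}^{-1}(-0.2 + 0.4\,C
  + \lambda_2 U_2))$, and analogously $Z_3$ given $Z_2 = 1$ — uptake
  around 50–60% per level, rising with $C$ and, when $\lambda_k \ne 0$,
  with the unmeasured $U_k$;
* $Y(z) = 0.5\,C + \lambda_1 U_1 z_1 + \lambda_2 U_2 + \lambda_3 U_3 +
  \beta z_K + \varepsilon$, $\varepsilon \sim N(0,1)$ — $\lambda_1$
  opens a direct eligibility-to-outcome path (an exclusion violation
  window selection cannot repair), $\lambda_2, \lambda_3$ confound their
  levels, and the effect $\beta$ enters only through the final status;
* Design 2 (two-sided): uptake among the ineligible follows its own
  covariate-only exception mechanism,
  $\mathrm{Bern}(\mathrm{logit}^{-1}(-1.5 + 0.4\,C))$, on which the
  analysis places no model;
* nonzero $\lambda_k$ default to 2 — large enough that a biased level is
  unmistakably invalid (its factor rejects essentially always), making
  the isolation property a sharp test rather than a borderline one.

The seven Design-1 cases set $\lambda = 0$ (case 1), one nonzero
$\lambda$ (cases 2–4), or two (cases 5–7); the correctly specified
retention count is $q = K - \#\{\lambda_k \ne 0\}$, applied to the
conditioned and unconditioned combinations alike.

`run_study()` fixes the level-1 window a priori at $(-w, w)$ with
$w = 0.5$ (per-replicate reselection is available behind
`reselect_window = TRUE`; it multiplies runtime roughly by the number of
candidates and is off because the study targets test validity, not
window choice). The study profile used throughout the test suite and the
acceptance script is $n = 500$ subjects, 500 replicates, 400 permutation
draws — Monte-Carlo bands of about $\pm 0.03$ around a nominal 0.05,
tight enough to detect meaningful level violations, with the full
seven-statistic study running in about a minute per case on one CPU.

**What the simulator does not emulate.** Real running variables can be
ordinal or manipulated near the cutoff; real strata are many and small
(the simulator has two large ones); outcomes can be heavy-tailed,
discrete, or heteroscedastic; missingness exists; and real assignment
processes need not follow logistic models, or any model, among the
"exceptions". Passing the simulation study therefore shows that the
machinery — construction, conditioning, randomization inference,
combination, sensitivity bounds — behaves as the theory says *under a
data-generating process satisfying the assumptions*; it is not evidence
about any particular application, and the untestable no-shared-hidden-
causes assumption is as load-bearing in practice as it is here.

## Other numerical conventions

* Tail comparisons use a $10^{-9}$ slack on rank-sum values (mid-ranks
  are halves; convolution keys round to 9 decimals).
* `exact_enumeration_pvalue()` refuses product spaces above $10^6$
  assignments and says to use Monte Carlo.
* Eligibility ties at the cutoff are eligible, on both cutoff sides via
  `eligibility_direction`.
* Missing outcome or covariate values drop the row with a logged count;
  nothing is imputed.
* All seeds are explicit; `run_study()` consumes one stream from its
  study seed so replicate-level results are reproducible as a block, and
  `ef_analyze()` gives factor $k$ the seed `config$seed + k`.

## Limitations

Stratification is exact matching only — no calipers, no coarsening —
so high-dimensional covariates will shred the sample into singleton
strata and drain power. The method tests the sharp null; it does not
estimate effect sizes or produce confidence intervals. The sensitivity
model tilts one level at a time with a scalar $\Gamma_k$ per level;
two-parameter sensitivity models and design-sensitivity calculations are
out of scope, as are survey weights, clustered assignment and
continuity-based RD estimation.
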