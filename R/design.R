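#' Eligibility under the sharp cutoff rule
#'
#' Level-1 assignment in an RD design is the deterministic cutoff rule on
#' the running variable. Ties at the cutoff count as eligible.
#'
#' @param running Numeric vector of running-variable values.
#' @param design An [ef_design()].
#' @param z1 Optional observed level-1 statuses; when supplied they are
#'   checked against the computed rule and a mismatch is an error naming
#'   the offending rows.
#' @return Integer 0/1 vector of eligibility.
#' @export
#' @examples
#' assign_eligibility(c(-2, 0, 3), ef_design(K = 2, cutoff = 0))
assign_eligibility <- function(running, design, z1 = NULL) {
  stopifnot(inherits(design, "ef_design"))
  if (any(!is.finite(running))) abort("`running` must be finite.")
  elig <- if (design$eligibility_direction == "ge") {
    as.integer(running >= design$cutoff)
  } else {
    as.integer(running <= design$cutoff)
  }
  if (!is.null(z1)) {
    bad <- which(elig != z1)
    if (length(bad) > 0) {
      abort(paste0(
        "observed Z1 disagrees with the eligibility rule in row(s): ",
        paste(head(bad, 10), collapse = ", ")
      ))
    }
  }
  elig
}

#' Exact-matching stratification on discrete covariates
#'
#' Groups subjects that share an identical covariate tuple into one
#' stratum. Stratum labels are the pasted covariate values, so the
#' partition does not depend on row order. Strata without variation in a
#' comparison's assignment contribute nothing to the test statistic
#' downstream; singleton strata are therefore harmless but uninformative.
#'
#' @param data Subject tibble.
#' @param covariates Character vector of covariate column names; defaults
#'   to every column whose name starts with `cov_`.
#' @return `data` with a `stratum` character column added.
#' @export
ef_stratify <- function(data, covariates = NULL) {
  covariates <- covariates %||% grep("^cov_", names(data), value = TRUE)
  if (length(covariates) == 0) abort("no covariate columns found to stratify on.")
  key <- do.call(paste, c(data[covariates], sep = "|"))
  dplyr::mutate(data, stratum = key)
}

#' Select a local-randomization window by covariate balance
#'
#' Tests, for each candidate symmetric window around the cutoff, whether
#' eligibility looks randomly assigned with respect to the covariates:
#' each covariate gets a two-sided randomization p-value for the
#' difference in means between eligible and ineligible subjects inside the
#' window, permuting eligibility freely within the window. The chosen
#' window is the largest candidate whose minimum per-covariate p-value
#' exceeds the design's balance threshold.
#'
#' @param data Subject tibble (needs `running`, `z1` and `cov_*` columns).
#' @param design An [ef_design()].
#' @param candidates Increasing numeric vector of symmetric half-widths w;
#'   each candidate window is `(cutoff - w, cutoff + w)`.
#' @param n_perm Permutation draws per balance test.
#' @param seed Integer seed.
#' @param covariates Covariate columns; default all `cov_*` columns.
#' @return A list of class `ef_window`: `chosen` (the `(lo, hi)` pair),
#'   `width`, `threshold`, and `candidates`, a tibble with one row per
#'   candidate x covariate giving the balance p-values (the audit trail).
#' @export
select_window <- function(data, design, candidates, n_perm = 999L,
                          seed = 1L, covariates = NULL) {
  stopifnot(inherits(design, "ef_design"))
  if (length(candidates) < 1) abort("supply at least one candidate width.")
  if (is.unsorted(candidates, strictly = TRUE)) {
    abort("`candidates` must be strictly increasing widths.")
  }
  covariates <- covariates %||% grep("^cov_", names(data), value = TRUE)
  if (length(covariates) == 0) abort("no covariate columns found.")
  set.seed(seed)
  res <- purrr::map_dfr(candidates, function(w) {
    lo <- design$cutoff - w
    hi <- design$cutoff + w
    inside <- data$running >= lo & data$running <= hi
    sub <- data[inside, , drop = FALSE]
    elig <- assign_eligibility(sub$running, design)
    purrr::map_dfr(covariates, function(cv) {
      x <- sub[[cv]]
      if (!is.numeric(x)) x <- as.numeric(factor(x))
      p <- balance_pvalue(x, elig, n_perm)
      tibble::tibble(width = w, lo = lo, hi = hi, covariate = cv, p_balance = p)
    })
  })
  ok <- res |>
    dplyr::summarise(min_p = min(.data$p_balance), .by = "width") |>
    dplyr::filter(.data$min_p > design$balance_threshold)
  if (nrow(ok) == 0) {
    abort(paste0(
      "no candidate window passes the balance threshold of ",
      design$balance_threshold,
      "; supply narrower candidates or lower the threshold."
    ))
  }
  w <- max(ok$width)
  structure(
    list(chosen = c(design$cutoff - w, design$cutoff + w), width = w,
         threshold = design$balance_threshold, candidates = res),
    class = "ef_window"
  )
}

#' @export
print.ef_window <- function(x, ...) {
  cat("<ef_window> chosen: (", x$chosen[1], ",", x$chosen[2],
      ") at balance threshold", x$threshold, "\n")
  print(x$candidates)
  invisible(x)
}

# Two-sided free-permutation p-value for a difference in means.
balance_pvalue <- function(x, elig, n_perm) {
  n1 <- sum(elig == 1)
  n0 <- sum(elig == 0)
  if (n1 == 0 || n0 == 0) return(1)
  n <- length(x)
  tot <- sum(x)
  d_obs <- abs(sum(x[elig == 1]) / n1 - (tot - sum(x[elig == 1])) / n0)
  if (d_obs == 0) return(1)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    s1 <- sum(x[sample.int(n, n1)])
    d <- abs(s1 / n1 - (tot - s1) / n0)
    if (d >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' Residualize the outcome on the running variable
#'
#' Fits an ordinary least-squares line of the outcome on the running
#' variable over `subset` and returns the residuals for that subset. The
#' level-1 intent-to-treat factor uses these residuals in place of the raw
#' outcome to absorb the smooth trend of the outcome in the running
#' variable inside the window; later factors use the raw outcome.
#'
#' When `strata` is supplied the fit adds one intercept per stratum
#' (a common slope with stratum fixed effects). This is the form the
#' stratified test calls for: when covariates shift both the running
#' variable and the outcome, the marginal slope of the outcome on the
#' running variable includes a between-strata component that does not
#' exist inside any stratum, and removing it would systematically tilt
#' the within-stratum comparison. Only the within-stratum slope can
#' confound a stratified window comparison.
#'
#' @param y Outcome vector (full length).
#' @param running Running-variable vector (full length).
#' @param subset Integer indices of the rows to fit over (default all).
#' @param strata Optional stratum labels (full length); adds stratum
#'   intercepts to the fit.
#' @return Numeric residuals, one per element of `subset`.
#' @export
#' @examples
#' residualize_outcome(c(0, 1, 4), c(0, 1, 2))  # slope 2, intercept -1/3
residualize_outcome <- function(y, running, subset = seq_along(y),
                                strata = NULL) {
  ys <- y[subset]
  xs <- running[subset]
  if (length(ys) < 3) abort("`subset` must contain at least 3 rows.")
  if (diff(range(xs)) == 0) {
    abort("running variable is constant over `subset`; slope unidentifiable.")
  }
  X <- if (is.null(strata)) {
    cbind(1, xs)
  } else {
    f <- factor(strata[subset])
    ind <- outer(f, levels(f), `==`) * 1  # one intercept per stratum
    cbind(ind, xs)
  }
  fit <- stats::lm.fit(X, ys)
  as.numeric(ys - X %*% ifelse(is.na(fit$coefficients), 0,
                               fit$coefficients))
}
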