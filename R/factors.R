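#' Construct the K evidence-factor comparisons
#'
#' Builds one comparison per assignment level. The level-1 factor is the
#' intent-to-treat RD comparison: every subject inside the
#' local-randomization window, compared by eligibility `z1`, optionally on
#' the residualized outcome. The level-k factor (k >= 2) conditions on all
#' earlier statuses being 1: it keeps exactly the subjects with
#' `z1 = ... = z_{k-1} = 1` (inside or outside the window) and compares
#' them by `z_k`. Variation of `z_k` among subjects with any earlier
#' status 0 is never used -- those assignment mechanisms are "exceptions"
#' the design places no model on. Under two-sided non-compliance this
#' means the level-2 factor drops every ineligible subject regardless of
#' `z2` while retaining eligible subjects outside the window.
#'
#' A factor whose strata contain no assignment variation is flagged
#' degenerate and will report p = 1 downstream rather than abort.
#'
#' @param data Subject tibble with a `stratum` column (see [ef_stratify()]).
#' @param design An [ef_design()].
#' @param window `(lo, hi)`; defaults to `design$window`.
#' @param residualize Use the residualized outcome for level 1?
#' @return A tibble of class `ef_factors`, one row per level, with
#'   list-columns `rows` (row indices into `data`), `assignment`,
#'   `stratum` and `outcome`, plus `window_applied`, `outcome_used`,
#'   `n_treat`, `n_control` and `degenerate`.
#' @export
build_factors <- function(data, design, window = design$window,
                          residualize = TRUE) {
  factors_impl(data, design, window, residualize, conditioned = TRUE)
}

#' Unconditioned benchmark comparisons
#'
#' The benchmark the evidence-factor construction is judged against:
#' level k compares `z_k = 1` with `z_k = 0` over *all* subjects,
#' stratified on covariates but ignoring earlier statuses (an as-treated
#' analysis at level K). Level 1 coincides with the first evidence factor
#' by construction. Bias at one level can spill into later unconditioned
#' comparisons, which is what the conditioned factors avoid.
#'
#' @inheritParams build_factors
#' @return A tibble of class `ef_factors` (see [build_factors()]).
#' @export
build_unconditioned <- function(data, design, window = design$window,
                                residualize = TRUE) {
  factors_impl(data, design, window, residualize, conditioned = FALSE)
}

factors_impl <- function(data, design, window, residualize, conditioned) {
  stopifnot(inherits(design, "ef_design"))
  if (is.null(window)) abort("`window` is unset; select or supply one first.")
  if (!"stratum" %in% names(data)) {
    abort("`data` has no `stratum` column; call ef_stratify() first.")
  }
  assign_eligibility(data$running, design, z1 = data$z1)
  K <- design$K
  zmat <- as.matrix(data[, paste0("z", seq_len(K)), drop = FALSE])
  in_window <- data$running >= window[1] & data$running <= window[2]

  purrr::map_dfr(seq_len(K), function(k) {
    if (k == 1) {
      rows <- which(in_window)
      if (residualize) {
        # trend fitted on the full sample with stratum intercepts: inside
        # a narrow window the eligibility indicator is nearly collinear
        # with the running variable, so a window-only fit would leave
        # residuals nearly orthogonal to the assignment (a severely
        # conservative test), and a fit without stratum intercepts would
        # remove a between-strata trend that does not exist within strata
        outcome <- residualize_outcome(data$y, data$running,
                                       strata = data$stratum)[rows]
        outcome_used <- "residualized"
      } else {
        outcome <- data$y[rows]
        outcome_used <- "raw"
      }
      window_applied <- TRUE
    } else {
      rows <- if (conditioned) {
        which(rowSums(zmat[, seq_len(k - 1), drop = FALSE] == 1) == (k - 1))
      } else {
        seq_len(nrow(data))
      }
      outcome <- data$y[rows]
      outcome_used <- "raw"
      window_applied <- FALSE
    }
    assignment <- as.integer(zmat[rows, k])
    stratum <- data$stratum[rows]
    informative <- informative_strata(assignment, stratum)
    degenerate <- length(informative) == 0
    if (degenerate) {
      warn(sprintf("factor at level %d is degenerate (no stratum with both arms); it will report p = 1", k))
    }
    n_t <- sum(assignment == 1)
    n_c <- sum(assignment == 0)
    tibble::tibble(
      level = k,
      rows = list(rows),
      assignment = list(assignment),
      stratum = list(stratum),
      outcome = list(outcome),
      window_applied = window_applied,
      outcome_used = outcome_used,
      n_treat = n_t,
      n_control = n_c,
      degenerate = degenerate
    )
  }) |>
    structure(class = c("ef_factors", class(tibble::tibble())))
}

# stratum labels containing both assignment arms
informative_strata <- function(assignment, stratum) {
  t1 <- unique(stratum[assignment == 1])
  t0 <- unique(stratum[assignment == 0])
  intersect(t1, t0)
}

# normalize a factor row (one-row tibble or list) to a plain list
as_comparison <- function(comp) {
  if (inherits(comp, "data.frame")) {
    stopifnot(nrow(comp) == 1)
    list(
      level = comp$level[[1]],
      rows = comp$rows[[1]],
      assignment = comp$assignment[[1]],
      stratum = comp$stratum[[1]],
      outcome = comp$outcome[[1]],
      degenerate = comp$degenerate[[1]]
    )
  } else {
    comp
  }
}

#' Per-subject factor membership table
#'
#' Audit view of the construction: for every subject and level, whether
#' the subject sits in the treatment arm (`"T"`), control arm (`"C"`) or
#' is excluded (`"."`) from that factor.
#'
#' @inheritParams build_factors
#' @return A tibble with `id`, `pattern`, `in_window` and one `ef1..efK`
#'   column per level.
#' @export
factor_membership <- function(data, design, window = design$window) {
  if (!"stratum" %in% names(data)) data$stratum <- "all"
  facs <- factors_impl(data, design, window, residualize = FALSE,
                       conditioned = TRUE)
  K <- design$K
  zmat <- as.matrix(data[, paste0("z", seq_len(K)), drop = FALSE])
  out <- tibble::tibble(
    id = data$id,
    pattern = apply(zmat, 1, paste, collapse = ""),
    in_window = data$running >= window[1] & data$running <= window[2]
  )
  for (k in seq_len(K)) {
    col <- rep(".", nrow(data))
    rows <- facs$rows[[k]]
    col[rows] <- ifelse(facs$assignment[[k]] == 1, "T", "C")
    out[[paste0("ef", k)]] <- col
  }
  out
}
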