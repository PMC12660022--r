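#' Read and validate a subject table
#'
#' Reads a delimited text file of subjects and standardizes it to the
#' column layout the rest of the package expects: `id`, `running`, `y`,
#' treatment statuses `z1 ... zK`, and covariates renamed `cov_<name>`.
#' Covariates are treated as discrete codes; continuous covariates must be
#' binned by the user before stratification.
#'
#' Rows with missing outcome or covariate values are dropped with a
#' message (the method has no imputation step). Structural violations --
#' non-binary treatment statuses, or a one-sided design whose statuses are
#' not nested within a row -- are errors that name the offending rows.
#'
#' @param path Path to a comma- or tab-separated file with a header.
#' @param design An [ef_design()].
#' @param columns Named list mapping the standard roles to the file's
#'   column names: `id`, `running`, `outcome`, `z` (character vector of
#'   length K, in level order) and `covariates` (character vector).
#' @param delim Field delimiter; guessed from the file when `NULL`.
#'
#' @return A tibble with columns `id`, `running`, `y`, `z1..zK`, `cov_*`.
#' @export
read_subject_table <- function(path, design, columns, delim = NULL) {
  stopifnot(inherits(design, "ef_design"))
  required <- c("id", "running", "outcome", "z")
  missing_roles <- setdiff(required, names(columns))
  if (length(missing_roles) > 0) {
    abort(paste0("`columns` must name: ", paste(missing_roles, collapse = ", ")))
  }
  if (length(columns$z) != design$K) {
    abort(sprintf("`columns$z` must list %d column names (one per level).", design$K))
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  wanted <- c(columns$id, columns$running, columns$outcome,
              columns$z, columns$covariates)
  absent <- setdiff(wanted, names(raw))
  if (length(absent) > 0) {
    abort(paste0("column(s) not found in ", path, ": ",
                 paste(absent, collapse = ", ")))
  }
  out <- tibble::tibble(
    id = as.character(raw[[columns$id]]),
    running = as.numeric(raw[[columns$running]]),
    y = as.numeric(raw[[columns$outcome]])
  )
  for (k in seq_len(design$K)) {
    out[[paste0("z", k)]] <- as.numeric(raw[[columns$z[k]]])
  }
  for (cv in columns$covariates %||% character()) {
    out[[paste0("cov_", cv)]] <- raw[[cv]]
  }
  validate_subject_table(out, design)
}

#' Write a subject table back to delimited text
#'
#' Numeric columns round-trip bit-exactly through
#' [read_subject_table()] / `write_subject_table()`.
#'
#' @param data Subject tibble in standard layout.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(data, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

# Structural checks shared by read_subject_table() and the simulators.
validate_subject_table <- function(data, design) {
  K <- design$K
  zcols <- paste0("z", seq_len(K))
  stopifnot(all(zcols %in% names(data)))
  covcols <- grep("^cov_", names(data), value = TRUE)

  # missingness: drop, never impute
  keep <- stats::complete.cases(data[, c("y", covcols), drop = FALSE])
  if (any(!keep)) {
    inform(sprintf("dropped %d row(s) with missing outcome or covariate values",
                   sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }

  bad_finite <- which(!is.finite(data$running) | !is.finite(data$y))
  if (length(bad_finite) > 0) {
    abort(paste0("non-finite running or outcome values in row(s): ",
                 paste(head(bad_finite, 10), collapse = ", ")))
  }
  zmat <- as.matrix(data[, zcols, drop = FALSE])
  bad_bin <- which(apply(zmat, 1, function(z) any(is.na(z) | !(z %in% c(0, 1)))))
  if (length(bad_bin) > 0) {
    abort(paste0("treatment statuses must be 0/1; offending row(s): ",
                 paste(head(bad_bin, 10), collapse = ", ")))
  }
  if (design$compliance == "one_sided") {
    # z_k = 1 requires z_{k-1} = 1: rows must be nonincreasing
    nonmono <- which(apply(zmat, 1, function(z) any(diff(z) > 0)))
    if (length(nonmono) > 0) {
      abort(paste0(
        "one-sided compliance violated (a later status is 1 while an ",
        "earlier one is 0) in row(s): ",
        paste(head(nonmono, 10), collapse = ", ")
      ))
    }
  }
  tibble::as_tibble(data)
}

#' Enumerate the admissible treatment-status patterns of a design
#'
#' Under one-sided compliance the statuses are nested, so only the `K + 1`
#' nonincreasing patterns can occur (for K = 3: 000, 100, 110, 111); under
#' two-sided compliance any of the `2^K` patterns may appear.
#'
#' @param design An [ef_design()].
#' @return Character vector of admissible patterns, e.g. `"110"`.
#' @export
admissible_patterns <- function(design) {
  K <- design$K
  if (design$compliance == "one_sided") {
    vapply(0:K, function(m) paste(rep(c(1, 0), c(m, K - m)), collapse = ""),
           character(1))
  } else {
    grid <- expand.grid(rep(list(c(0, 1)), K))[, K:1, drop = FALSE]
    apply(grid, 1, paste, collapse = "")
  }
}

#' Structural report on a subject table
#'
#' Counts subjects in every observed treatment-status pattern, tallies the
#' treated and control arms available to each evidence factor, and warns
#' about empty comparison arms. Reporting only: the causal assumption that
#' the sequential statuses share no unmeasured common causes is untestable
#' from data and is surfaced as a documented caveat, not a check.
#'
#' @param data Subject tibble in standard layout.
#' @param design An [ef_design()].
#' @return A list of class `ef_validation` with elements `patterns`
#'   (tibble: pattern, n, admissible), `factors` (tibble: level, n_total,
#'   n_treat, n_control, degenerate) and `warnings` (character).
#' @export
validate_design <- function(data, design) {
  data <- validate_subject_table(data, design)
  K <- design$K
  zmat <- as.matrix(data[, paste0("z", seq_len(K)), drop = FALSE])
  pattern <- apply(zmat, 1, paste, collapse = "")
  adm <- admissible_patterns(design)
  pat_tbl <- tibble::tibble(pattern = adm) |>
    dplyr::left_join(
      tibble::tibble(pattern = pattern) |> dplyr::count(.data$pattern),
      by = "pattern"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L), admissible = TRUE)

  warnings <- character()
  fac <- purrr::map_dfr(seq_len(K), function(k) {
    if (k == 1) {
      use <- rep(TRUE, nrow(data))
    } else {
      use <- rowSums(zmat[, seq_len(k - 1), drop = FALSE] == 1) == (k - 1)
    }
    n_t <- sum(zmat[use, k] == 1)
    n_c <- sum(zmat[use, k] == 0)
    tibble::tibble(level = k, n_total = sum(use), n_treat = n_t,
                   n_control = n_c, degenerate = n_t == 0 || n_c == 0)
  })
  for (k in which(fac$degenerate)) {
    arm <- if (fac$n_treat[k] == 0) "treatment" else "control"
    warnings <- c(warnings,
                  sprintf("EF %d has an empty %s arm", k, arm))
  }
  structure(list(patterns = pat_tbl, factors = fac, warnings = warnings),
            class = "ef_validation")
}

#' @export
print.ef_validation <- function(x, ...) {
  cat("Treatment-status patterns:\n")
  print(x$patterns)
  cat("\nPer-factor comparison arms:\n")
  print(x$factors)
  if (length(x$warnings) > 0) cat("\nWarnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}
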