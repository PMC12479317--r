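#' Read a cohort table from delimited text
#'
#' Loads a per-individual table holding the outcome, one or more categorical
#' treatment columns (e.g. genotypes coded 0/1/2 or allele strings),
#' confounders (e.g. principal components) and optional outcome-only
#' covariates. Declared treatment columns are coerced to factors with an
#' explicit level ordering.
#'
#' @param path Path to a TSV/CSV file with header (delimiter sniffed by
#'   [data.table::fread()]).
#' @param outcome Outcome column name. Binary outcomes must be coded 0/1.
#' @param treatments Character vector of treatment column names.
#' @param confounders,covariates Column name vectors (covariates optional).
#' @param treatment_levels Optional named list of level orderings, one entry
#'   per treatment (a character vector or a [treatment_levels()] object).
#'   Unlisted treatments get their sorted observed values.
#' @param id Optional sample-id column name, kept for GRM alignment.
#' @return A `cohort` object: list with `$data` (data.frame), the role
#'   columns, and `$n_dropped` (listwise deletions over referenced columns).
#' @export
read_cohort <- function(path, outcome, treatments, confounders,
                        covariates = character(), treatment_levels = NULL,
                        id = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  cohort_table(df, outcome = outcome, treatments = treatments,
               confounders = confounders, covariates = covariates,
               treatment_levels = treatment_levels, id = id)
}

#' Build a cohort from an in-memory data.frame
#'
#' @param data A data.frame.
#' @inheritParams read_cohort
#' @return A `cohort` object; see [read_cohort()].
#' @export
cohort_table <- function(data, outcome, treatments, confounders,
                         covariates = character(), treatment_levels = NULL,
                         id = NULL) {
  cols <- c(outcome, treatments, confounders, covariates, id)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("schema error: column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data[, cols, drop = FALSE]
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("cohort: dropped ", n_dropped, " row(s) with missing values (listwise)")
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  if (!is.numeric(df[[outcome]]))
    stop("outcome '", outcome, "' must be numeric (binary outcomes coded 0/1)",
         call. = FALSE)
  for (tn in treatments) {
    lv <- NULL
    if (!is.null(treatment_levels) && !is.null(treatment_levels[[tn]])) {
      lv <- treatment_levels[[tn]]
      if (inherits(lv, "treatment_levels")) lv <- lv$levels
    }
    obs <- as.character(df[[tn]])
    if (is.null(lv)) {
      lv <- sort(unique(obs))
    } else if (!all(obs %in% lv)) {
      stop("treatment '", tn, "' has values outside its declared levels",
           call. = FALSE)
    }
    df[[tn]] <- factor(obs, levels = as.character(lv))
  }
  structure(list(data = df, outcome = outcome, treatments = treatments,
                 confounders = confounders, covariates = covariates,
                 id = id, n_dropped = n_dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n =", nrow(x$data),
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped)"), "\n")
  cat("  outcome:    ", x$outcome,
      if (is_binary(x$data[[x$outcome]])) "(binary)" else "(continuous)", "\n")
  cat("  treatments: ", paste(x$treatments, collapse = ", "), "\n")
  cat("  confounders:", paste(x$confounders, collapse = ", "), "\n")
  if (length(x$covariates))
    cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

is_binary <- function(y) all(y %in% c(0, 1))

# Coerce either a cohort or a raw data.frame (+ an estimand, which names the
# columns) into the analysis sample: listwise-complete rows over referenced
# columns, treatments as factors.
analysis_sample <- function(data, spec) {
  if (inherits(data, "cohort")) {
    df <- data$data
  } else {
    df <- as.data.frame(data)
  }
  cols <- c(spec$outcome, spec$treatments, spec$confounders, spec$covariates)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("schema error: column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, cols, drop = FALSE]
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message("estimation: dropped ", sum(!keep), " row(s) with missing values")
    df <- df[keep, , drop = FALSE]
  }
  for (tn in spec$treatments)
    if (!is.factor(df[[tn]])) df[[tn]] <- factor(as.character(df[[tn]]))
  rownames(df) <- NULL
  df
}
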