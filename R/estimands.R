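#' Declare the levels of a categorical treatment
#'
#' Treatments (genotypes, discretized exposures) are opaque category labels
#' with an explicit declared ordering. The ordering matters for "additional
#' allelic copy" contrasts such as 0->1 and 1->2 at a biallelic locus.
#'
#' @param treatment_name Column name of the treatment variable.
#' @param levels Ordered vector (character or numeric) of distinct category
#'   labels, e.g. `c("TT","TC","CC")` or `0:2`.
#' @return An object of class `treatment_levels`.
#' @export
treatment_levels <- function(treatment_name, levels) {
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("treatment '", treatment_name, "' needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("treatment '", treatment_name, "' has duplicated levels", call. = FALSE)
  structure(list(treatment_name = as.character(treatment_name),
                 levels = levels),
            class = "treatment_levels")
}

#' Per-treatment baseline/target contrast
#'
#' One (baseline, target) level pair per treatment entering a k-point
#' estimand. Arbitrary level pairs are allowed, not only adjacent ones.
#'
#' @param baseline,target Vectors of length k, one entry per treatment.
#' @param treatments Character vector of k treatment names.
#' @return An object of class `tx_contrast`: a list of k `(baseline, target)`
#'   pairs, named by treatment.
#' @export
tx_contrast <- function(treatments, baseline, target) {
  k <- length(treatments)
  baseline <- as.character(baseline); target <- as.character(target)
  if (length(baseline) != k || length(target) != k)
    stop("baseline and target must each have one level per treatment", call. = FALSE)
  if (anyDuplicated(treatments))
    stop("treatment names must be distinct", call. = FALSE)
  if (any(baseline == target))
    stop("baseline and target levels must differ for every treatment", call. = FALSE)
  pairs <- lapply(seq_len(k), function(i) c(baseline = baseline[i], target = target[i]))
  names(pairs) <- treatments
  structure(pairs, class = "tx_contrast")
}

new_estimand <- function(kind, outcome, treatments, contrast, confounders,
                         covariates, k) {
  structure(list(kind = kind, k = k, outcome = outcome,
                 treatments = treatments, contrast = contrast,
                 confounders = confounders, covariates = covariates),
            class = "estimand")
}

#' Treatment-specific covariate-adjusted mean E_W[ E(Y | A = a, W) ]
#'
#' @param outcome Outcome column name.
#' @param treatments Character vector of treatment column names.
#' @param levels Target level, one per treatment.
#' @param confounders Confounder column names (W), e.g. principal components.
#' @param covariates Optional outcome-only covariate names (C), e.g. age, sex.
#' @return An `estimand` of kind `"counterfactual_mean"`.
#' @export
counterfactual_mean <- function(outcome, treatments, levels, confounders,
                                covariates = character()) {
  k <- length(treatments)
  levels <- as.character(levels)
  if (length(levels) != k) stop("one target level per treatment", call. = FALSE)
  if (anyDuplicated(treatments)) stop("treatment names must be distinct", call. = FALSE)
  pairs <- lapply(levels, function(l) c(baseline = NA_character_, target = l))
  names(pairs) <- treatments
  new_estimand("counterfactual_mean", outcome, treatments,
               structure(pairs, class = "tx_contrast"),
               confounders, covariates, k)
}

#' Average treatment effect of one categorical treatment
#'
#' The covariate-adjusted mean difference between `target` and `baseline`
#' levels of a single treatment (k = 1).
#'
#' @inheritParams counterfactual_mean
#' @param treatment Treatment column name.
#' @param baseline,target The two levels being contrasted.
#' @return An `estimand` of kind `"ate"`.
#' @export
ate <- function(outcome, treatment, baseline, target, confounders,
                covariates = character()) {
  new_estimand("ate", outcome, treatment,
               tx_contrast(treatment, baseline, target),
               confounders, covariates, 1L)
}

#' k-point average interaction effect (AIE)
#'
#' The alternating-sum generalization of the ATE over the 2^k vertices of the
#' joint baseline-to-target change of k treatments; quantifies non-additivity
#' (epistasis for k variants, GxE when a treatment is environmental).
#'
#' @inheritParams counterfactual_mean
#' @param baseline,target Length-k level vectors, one per treatment.
#' @return An `estimand` of kind `"aie"` with `k = length(treatments)`.
#' @export
aie <- function(outcome, treatments, baseline, target, confounders,
                covariates = character()) {
  k <- length(treatments)
  if (k < 2L) stop("aie needs k >= 2 treatments; use ate() for k = 1", call. = FALSE)
  new_estimand("aie", outcome, treatments,
               tx_contrast(treatments, baseline, target),
               confounders, covariates, as.integer(k))
}

#' @export
print.estimand <- function(x, ...) {
  cat("<estimand:", x$kind, "k =", x$k, ">\n")
  cat("  outcome:   ", x$outcome, "\n")
  for (tn in x$treatments) {
    p <- x$contrast[[tn]]
    if (is.na(p[["baseline"]]))
      cat("  treatment: ", tn, "at", p[["target"]], "\n")
    else
      cat("  treatment: ", tn, p[["baseline"]], "->", p[["target"]], "\n")
  }
  cat("  confounders:", paste(x$confounders, collapse = ", "), "\n")
  if (length(x$covariates))
    cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Vertex level assignments and alternating signs of a k-point estimand
#'
#' Enumerates the 2^k corners s of the baseline/target hypercube in
#' lexicographic order of s (s = 0..0 first), each with its level assignment
#' a(s) and sign (-1)^(k - sum(s)). A counterfactual mean has the single
#' vertex a(1) with sign +1.
#'
#' @param contrast A `tx_contrast` (or an `estimand`, whose contrast is used).
#' @param k Interaction order; defaults to the number of pairs in `contrast`.
#' @return A data.frame with one row per vertex: columns `sign`, `s` (matrix
#'   of 0/1), and `a` (matrix of level labels, one column per treatment).
#' @export
vertex_weights <- function(contrast, k = NULL) {
  if (inherits(contrast, "estimand")) {
    est <- contrast
    contrast <- est$contrast
    if (est$kind == "counterfactual_mean") {
      a <- matrix(vapply(contrast, `[[`, "", "target"), nrow = 1L,
                  dimnames = list(NULL, names(contrast)))
      return(data.frame(sign = 1, s = I(matrix(1L, 1L, est$k)), a = I(a)))
    }
    k <- est$k
  }
  if (is.null(k)) k <- length(contrast)
  if (k <= 0L) stop("invalid estimand: interaction order k must be >= 1", call. = FALSE)
  if (length(contrast) != k) stop("contrast must have k treatment pairs", call. = FALSE)
  # lexicographic order of s: first index varies slowest
  grid <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  grid <- grid[order(apply(grid, 1L, paste, collapse = "")), , drop = FALSE]
  storage.mode(grid) <- "integer"
  dimnames(grid) <- list(NULL, names(contrast))
  sign <- (-1)^(k - rowSums(grid))
  a <- grid
  amat <- matrix("", nrow(grid), k, dimnames = dimnames(grid))
  for (j in seq_len(k)) {
    p <- contrast[[j]]
    amat[, j] <- ifelse(grid[, j] == 1L, p[["target"]], p[["baseline"]])
  }
  out <- data.frame(sign = sign)
  out$s <- grid
  out$a <- amat
  out
}

#' Substitution (plug-in) estimate from vertex outcome predictions
#'
#' The signed sum over vertices of the empirical mean of the outcome
#' regression evaluated at each vertex level assignment, i.e. the plug-in
#' estimator under the empirical covariate distribution.
#'
#' @param vertices Output of [vertex_weights()].
#' @param qbar_at_vertices n x n_vertex matrix: per-individual predicted
#'   outcome at each vertex level assignment (columns in vertex order).
#' @return The plug-in estimate (scalar).
#' @export
plugin_estimate <- function(vertices, qbar_at_vertices) {
  qv <- as.matrix(qbar_at_vertices)
  if (ncol(qv) != nrow(vertices) || anyNA(qv))
    stop("incomplete nuisance: need predictions for every individual at every vertex",
         call. = FALSE)
  sum(vertices$sign * colMeans(qv))
}

# Internal: per-individual signed vertex prediction sums (the plug-in's
# individual-level contribution, reused by the EIF).
signed_vertex_sums <- function(vertices, qbar_at_vertices) {
  as.vector(as.matrix(qbar_at_vertices) %*% vertices$sign)
}
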