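# EIF assembly and downstream inference.

#' Per-individual efficient influence function values
#'
#' `D*_i = sum_s sign_s [ 1{a_i = a(s)} / g(a_i, w_i) (y_i - Qbar(a_i, w_i))
#'        + Qbar(a(s), w_i) ] - psi_hat`.
#'
#' @param fits A [fit_nuisances()] object.
#' @param qbar_obs,qbar_vertex Optional replacements for the stored
#'   predictions (e.g. the targeted fits after fluctuation).
#' @param psi_hat Point estimate subtracted from each value.
#' @return Numeric vector of length n.
#' @export
eif_values <- function(fits, qbar_obs = fits$qbar_obs,
                       qbar_vertex = fits$qbar_vertex, psi_hat) {
  cc <- clever_covariates(fits, "canonical")
  cc$h_obs * (fits$y - qbar_obs) +
    signed_vertex_sums(fits$vertices, qbar_vertex) - psi_hat
}

#' IID sample variance of the EIF
#'
#' `sigma2 = (1/n) sum_i D*_i^2` — the efficiency-bound variance estimate
#' under independent sampling.
#'
#' @param eif Numeric vector of EIF values.
#' @return Scalar variance estimate.
#' @export
iid_variance <- function(eif) mean(eif^2)

#' Wald confidence interval and two-sided p-value
#'
#' `psi_hat +/- z_{1-alpha/2} * sigma / sqrt(n)`; the p-value comes from
#' `sqrt(n) psi_hat / sigma` against the standard normal.
#'
#' @param psi_hat Point estimate.
#' @param sigma2 EIF variance estimate (see [iid_variance()]).
#' @param n Sample size.
#' @param alpha Significance level (default 0.05).
#' @return List with `se`, `ci` (length-2 vector), `p`, and `degenerate`
#'   (TRUE when `sigma2 == 0`, in which case the interval collapses to the
#'   point estimate and p is 0 or 1).
#' @export
wald_ci <- function(psi_hat, sigma2, n, alpha = 0.05) {
  se <- sqrt(sigma2 / n)
  degenerate <- sigma2 <= 0
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(psi_hat - z * se, psi_hat + z * se)
  p <- if (degenerate) as.numeric(psi_hat == 0)
       else 2 * stats::pnorm(-abs(psi_hat) / se)
  list(se = se, ci = ci, p = p, degenerate = degenerate)
}

#' Joint covariance and Hotelling test of several components
#'
#' Stacks the per-individual EIF values of p component estimates computed on
#' the same individuals, forms the p x p sample covariance
#' `Sigma_jk = (1/n) sum_i D_j(o_i) D_k(o_i)`, and tests the joint null
#' `psi_0 = 0` with Hotelling's `t2 = n psi' Sigma^-1 psi`, referred to
#' `p(n-1)/(n-p) F_{p,n-p}`.
#'
#' @param components List of `estimate_record`s on the same sample.
#' @return A `joint_estimate`: `psi` (length p), `sigma` (p x p), `t2`,
#'   `df`, `p_value`, `n`, and the EIF matrix.
#' @export
joint_test <- function(components) {
  p <- length(components)
  n <- components[[1L]]$n
  if (any(vapply(components, `[[`, 0L, "n") != n))
    stop("components must be estimated on the same individuals", call. = FALSE)
  if (p >= n) stop("need p < n for the Hotelling test", call. = FALSE)
  eifs <- vapply(components, `[[`, numeric(n), "eif")
  psi <- vapply(components, `[[`, 0, "psi")
  sigma <- crossprod(eifs) / n
  inv <- tryCatch(solve(sigma), error = function(e) NULL)
  rank <- p
  if (is.null(inv)) {
    warning("singular EIF covariance; using pseudo-inverse with reduced rank",
            call. = FALSE)
    inv <- MASS::ginv(sigma)
    rank <- qr(sigma)$rank
  }
  t2 <- as.numeric(n * t(psi) %*% inv %*% psi)
  fstat <- t2 * (n - rank) / (rank * (n - 1))
  p_value <- stats::pf(fstat, rank, n - rank, lower.tail = FALSE)
  structure(list(psi = psi, sigma = sigma, eif = eifs, t2 = t2,
                 df = c(rank, n - rank), p_value = p_value, n = n,
                 rank = rank),
            class = "joint_estimate")
}

#' @export
print.joint_estimate <- function(x, ...) {
  cat("<joint_estimate> p =", length(x$psi), " t2 =", format(x$t2, digits = 4),
      " p-value =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Delta-method functional of several component estimands
#'
#' For a differentiable `f`, the functional delta method gives the EIF of
#' `f(psi)` as `grad f(psi) . (component EIFs)`; for the allelic effect
#' difference `f(x1, x2) = x2 - x1` the variance is
#' `Var D1 - 2 Cov(D1, D2) + Var D2`.
#'
#' @param components List of `estimate_record`s on the same sample.
#' @param f Function of the component estimate vector.
#' @param grad Optional gradient function; central finite differences are
#'   used when omitted.
#' @param alpha Significance level.
#' @return An `estimate_record` for `f(psi)`.
#' @export
delta_method <- function(components, f, grad = NULL, alpha = 0.05) {
  psi <- vapply(components, `[[`, 0, "psi")
  n <- components[[1L]]$n
  eifs <- vapply(components, `[[`, numeric(n), "eif")
  g <- if (!is.null(grad)) grad(psi) else num_gradient(f, psi)
  eif <- as.vector(eifs %*% g)
  val <- f(psi)
  fits_stub <- list(spec = components[[1L]]$spec)
  rec <- new_record(structure(fits_stub, class = "nuisance_fits"),
                    estimator = paste0("delta(",
                                       components[[1L]]$estimator, ")"),
                    psi = val, eif = eif, alpha = alpha)
  rec$components <- psi
  rec
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h * max(1, abs(x[j]))
    (f(x + e) - f(x - e)) / (2 * e[j])
  }, 0)
}

#' Allelic effect difference of two single-copy contrasts
#'
#' Convenience wrapper for `delta_method(list(rec1, rec2), f = x2 - x1)`:
#' contrasts the effect of the second allele copy (1->2) against the first
#' (0->1); a nonzero value indicates genetic non-linearity.
#'
#' @param rec1,rec2 `estimate_record`s of the 0->1 and 1->2 contrasts.
#' @param alpha Significance level.
#' @return An `estimate_record` for `psi_2 - psi_1`.
#' @export
allelic_effect_difference <- function(rec1, rec2, alpha = 0.05)
  delta_method(list(rec1, rec2), f = function(x) x[2L] - x[1L],
               grad = function(x) c(-1, 1), alpha = alpha)

#' Positivity pruning of estimand components by vertex frequency
#'
#' Computes the marginal (unconditional) empirical frequency of every vertex
#' level assignment — the joint frequency across the k treatments — for each
#' candidate estimand, and drops only the components whose required vertices
#' fall below the threshold, rather than discarding whole estimands.
#'
#' @param data A `cohort` or data.frame.
#' @param specs A single `estimand` or list of them (the components).
#' @param threshold Minimum vertex frequency (e.g. 0.01).
#' @param per_treatment If TRUE, prune on per-treatment marginal level
#'   frequencies instead of joint vertex frequencies.
#' @return A `pruning_report`: `$kept` and `$dropped` lists of estimands,
#'   and `$table` of vertex frequencies per component.
#' @export
positivity_prune <- function(data, specs, threshold, per_treatment = FALSE) {
  if (inherits(specs, "estimand")) specs <- list(specs)
  rows <- list()
  kept <- list(); dropped <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    df <- analysis_sample(data, spec)
    n <- nrow(df)
    vertices <- vertex_weights(spec)
    freq <- if (n == 0L) rep(0, nrow(vertices)) else
      vapply(seq_len(nrow(vertices)), function(v) {
      if (per_treatment) {
        min(vapply(spec$treatments, function(tn)
          mean(as.character(df[[tn]]) == vertices$a[v, tn]), 0))
      } else {
        assign <- vertices$a[v, , drop = TRUE]
        obs <- vapply(spec$treatments, function(tn) as.character(df[[tn]]),
                      character(n))
        mean(rowSums(matrix(obs, n) != matrix(assign, n, length(assign),
                                              byrow = TRUE)) == 0L)
      }
    }, 0)
    ok <- all(freq >= threshold)
    rows[[i]] <- data.frame(component = i,
                            vertex = apply(vertices$a, 1L, paste,
                                           collapse = "/"),
                            frequency = freq, kept = ok)
    if (ok) kept <- c(kept, list(spec)) else dropped <- c(dropped, list(spec))
  }
  structure(list(kept = kept, dropped = dropped,
                 table = do.call(rbind, rows), threshold = threshold,
                 per_treatment = per_treatment),
            class = "pruning_report")
}

#' @export
print.pruning_report <- function(x, ...) {
  cat("<pruning_report> threshold =", x$threshold, ":",
      length(x$kept), "kept,", length(x$dropped), "dropped\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across a batch of tests; adjusted values are
#' monotone nondecreasing in the rank of the raw p-value.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")
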