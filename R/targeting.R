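# Targeting: turn nuisance fits into efficient estimators. The clever
# covariate at the observed data is
#   H(g)(A, W)  = sum_s sign_s 1{A = a(s)} / g(a(s), W)     (canonical)
#   H'(A, W)    = sum_s sign_s 1{A = a(s)}                  (weighted mode;
#                 1/g moves into the fluctuation loss as a weight)
# and the fluctuation is an offset one-parameter regression of Y on H
# (identity link for continuous Y, logit link for binary Y).

clever_covariates <- function(fits, mode = c("canonical", "weighted")) {
  mode <- match.arg(mode)
  sgn <- fits$vertices$sign
  m <- fits$match_vertex
  if (mode == "canonical") {
    h_vertex <- sweep(1 / fits$g_vertex, 2L, sgn, `*`)
    h_obs <- rowSums(m * h_vertex)
    w <- rep(1, length(fits$y))
  } else {
    h_vertex <- matrix(sgn, nrow(m), length(sgn), byrow = TRUE)
    h_obs <- rowSums(sweep(m, 2L, sgn, `*`))
    w <- rowSums(m / fits$g_vertex)  # 1/g(A,W) on vertex-matching rows
    w[h_obs == 0 & rowSums(m) == 0L] <- 0
  }
  list(h_obs = h_obs, h_vertex = h_vertex, w = w)
}

#' Empirical first-order bias term B_n
#'
#' The EIF-weighted mean residual
#' `(1/n) sum_i [ sum_s sign_s 1{a_i = a(s)} / g(a_i, w_i) ] (y_i - Qbar(a_i, w_i))`,
#' i.e. the inverse-propensity-weighted signed residual that the one-step
#' estimator adds back and TMLE fluctuates away.
#'
#' @param fits A [fit_nuisances()] object.
#' @param qbar_obs Optional replacement for the observed-data Qbar
#'   predictions (used internally after fluctuation).
#' @return Scalar B_n.
#' @export
first_order_bias <- function(fits, qbar_obs = fits$qbar_obs) {
  cc <- clever_covariates(fits, "canonical")
  mean(cc$h_obs * (fits$y - qbar_obs))
}

default_tol <- function(fits)
  if (fits$family == "gaussian") 1e-8 * max(stats::sd(fits$y), 1) else 1e-8

#' TMLE fluctuation of the outcome regression
#'
#' Fits an intercept-free one-parameter regression of Y on the clever
#' covariate with the initial Qbar as offset (identity link for continuous,
#' logit link for binary outcomes), canonical or weighted mode, iterating
#' until `|B_n| <= tol` or `max_iter`. The linear fluctuation is solved in
#' closed form (one step exact).
#'
#' @param fits A [fit_nuisances()] object.
#' @param mode `"canonical"` (inverse-propensity clever covariate, unit
#'   weights) or `"weighted"` (signed indicator covariate, `1/g` weights).
#' @param tol Convergence tolerance on `|B_n|`; default `1e-8 * sd(Y)` for
#'   continuous, `1e-8` for binary outcomes.
#' @param max_iter Maximum fluctuation iterations.
#' @return A `targeted_fit`: updated observed/vertex predictions, the
#'   fluctuation coefficients, iteration count, final `B_n`, convergence
#'   flag.
#' @export
tmle_fluctuate <- function(fits, mode = c("canonical", "weighted"),
                           tol = NULL, max_iter = 10L) {
  mode <- match.arg(mode)
  if (is.null(tol)) tol <- default_tol(fits)
  cc <- clever_covariates(fits, mode)
  if (all(cc$h_obs == 0))
    stop(structure(class = c("genetmle_empty_support", "error", "condition"),
                   list(message = "empty support: no individual at any vertex",
                        call = NULL)))
  y <- fits$y
  q_obs <- fits$qbar_obs
  q_vertex <- fits$qbar_vertex
  eps_path <- numeric(0)
  bn <- first_order_bias(fits, q_obs)
  iter <- 0L
  while (abs(bn) > tol && iter < max_iter) {
    iter <- iter + 1L
    if (fits$family == "gaussian") {
      num <- sum(cc$w * cc$h_obs * (y - q_obs))
      den <- sum(cc$w * cc$h_obs^2)
      eps <- if (den > 0) num / den else 0
      q_obs <- q_obs + eps * cc$h_obs
      q_vertex <- q_vertex + eps * cc$h_vertex
    } else {
      off <- stats::qlogis(q_obs)
      fit <- suppressWarnings(stats::glm.fit(
        x = matrix(cc$h_obs, ncol = 1L), y = y, weights = cc$w,
        offset = off, family = stats::binomial()))
      eps <- fit$coefficients[[1L]]
      if (is.na(eps)) eps <- 0
      q_obs <- stats::plogis(off + eps * cc$h_obs)
      q_vertex <- stats::plogis(stats::qlogis(q_vertex) + eps * cc$h_vertex)
    }
    eps_path <- c(eps_path, eps)
    bn <- first_order_bias(fits, q_obs)
  }
  converged <- abs(bn) <= tol
  if (!converged)
    warning("TMLE fluctuation did not reach |B_n| <= ", signif(tol, 3),
            " after ", max_iter, " iterations (|B_n| = ", signif(abs(bn), 3),
            ")", call. = FALSE)
  structure(list(qbar_obs = q_obs, qbar_vertex = q_vertex,
                 epsilon = eps_path, iterations = iter, Bn = bn,
                 converged = converged, mode = mode),
            class = "targeted_fit")
}

new_record <- function(fits, estimator, psi, eif, alpha, extra = list()) {
  n <- length(eif)
  sigma2 <- mean(eif^2)
  w <- wald_ci(psi, sigma2, n, alpha)
  structure(c(list(spec = fits$spec, estimator = estimator, psi = psi,
                   eif = eif, sigma2 = sigma2, n = n, se = w$se,
                   ci = w$ci, p = w$p, alpha = alpha, svp = FALSE),
              extra),
            class = "estimate_record")
}

estimate_from_fits <- function(fits, estimator, alpha = 0.05, tol = NULL,
                               max_iter = 10L) {
  vertices <- fits$vertices
  if (estimator %in% c("plugin", "ose")) {
    psi0 <- plugin_estimate(vertices, fits$qbar_vertex)
    bn <- first_order_bias(fits)
    psi <- if (estimator == "ose") psi0 + bn else psi0
    eif <- eif_values(fits, psi_hat = psi)
    return(new_record(fits, estimator, psi, eif, alpha,
                      list(Bn = bn, plugin = psi0)))
  }
  if (!estimator %in% c("tmle", "wtmle"))
    stop("unknown estimator '", estimator, "'", call. = FALSE)
  tf <- tmle_fluctuate(fits, mode = if (estimator == "wtmle") "weighted"
                                    else "canonical",
                       tol = tol, max_iter = max_iter)
  psi <- plugin_estimate(vertices, tf$qbar_vertex)
  eif <- eif_values(fits, qbar_obs = tf$qbar_obs,
                    qbar_vertex = tf$qbar_vertex, psi_hat = psi)
  new_record(fits, estimator, psi, eif, alpha,
             list(Bn = tf$Bn, iterations = tf$iterations,
                  converged = tf$converged, epsilon = tf$epsilon))
}

parse_estimator <- function(estimator) {
  cv <- startsWith(estimator, "cv_")
  list(cv = cv, base = sub("^cv_", "", estimator))
}

default_plan <- function(df, spec, folds, seed) {
  strata <- df[, spec$treatments, drop = FALSE]
  y <- df[[spec$outcome]]
  if (is_binary(y)) strata$..y <- y
  crossfit_plan(nrow(df), k_folds = folds,
                strata = interaction(strata, drop = TRUE), seed = seed)
}

#' Estimate a genetic main or interaction effect
#'
#' The front door of the package: fits nuisance functions with the requested
#' learners (full-sample for the canonical estimators, cross-fit for the
#' `cv_*` versions, in which case a single pooled fluctuation / pooled bias
#' correction is applied over all held-out predictions) and computes the
#' requested estimator with EIF-based Wald inference.
#'
#' @param spec An `estimand` from [ate()], [aie()] or
#'   [counterfactual_mean()].
#' @param data A `cohort` or data.frame.
#' @param estimator One of `"plugin"`, `"ose"`, `"tmle"`, `"wtmle"`,
#'   `"cv_ose"`, `"cv_tmle"`, `"cv_wtmle"`.
#' @param q_learner,g_learner Nuisance learners (see [learners]).
#' @param folds Fold count for `cv_*` estimators (stratified on treatments
#'   and, for binary outcomes, on the outcome).
#' @param seed Seed for the fold assignment.
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @param joint_propensity,g_floor Passed to [fit_nuisances()].
#' @param tol,max_iter Passed to [tmle_fluctuate()].
#' @return An `estimate_record` with the point estimate, per-individual EIF
#'   values, variance, CI and p-value.
#' @export
estimate_effect <- function(spec, data, estimator = "wtmle",
                            q_learner = lrn_glm(), g_learner = lrn_glm(),
                            folds = 3L, seed = 1L, alpha = 0.05,
                            joint_propensity = FALSE, g_floor = 1e-5,
                            tol = NULL, max_iter = 10L) {
  est <- parse_estimator(estimator)
  df <- analysis_sample(data, spec)
  plan <- if (est$cv) default_plan(df, spec, folds, seed) else NULL
  fits <- fit_nuisances(df, spec, q_learner, g_learner, plan = plan,
                        joint_propensity = joint_propensity,
                        g_floor = g_floor)
  rec <- estimate_from_fits(fits, est$base, alpha = alpha, tol = tol,
                            max_iter = max_iter)
  rec$estimator <- estimator
  rec
}

#' Estimate several contrasts of the same treatments jointly
#'
#' Components (e.g. the two single-allele-copy changes 0->1 and 1->2 of one
#' variant) share a single initial outcome regression and propensity fit;
#' each component then gets its own targeting step, and the per-individual
#' EIF values are kept side by side so the joint covariance, Hotelling test
#' and delta-method functionals are available.
#'
#' @param specs List of `estimand`s with identical outcome, treatments,
#'   confounders and covariates (contrasts differ).
#' @inheritParams estimate_effect
#' @return A list with `$records` (one `estimate_record` per component) and
#'   `$joint` (the [joint_test()] result).
#' @export
estimate_joint <- function(specs, data, estimator = "wtmle",
                           q_learner = lrn_glm(), g_learner = lrn_glm(),
                           folds = 3L, seed = 1L, alpha = 0.05,
                           joint_propensity = FALSE, g_floor = 1e-5,
                           tol = NULL, max_iter = 10L) {
  stopifnot(length(specs) >= 1L)
  ref <- specs[[1L]]
  for (s in specs[-1L])
    if (!identical(s$outcome, ref$outcome) ||
        !identical(sort(s$treatments), sort(ref$treatments)) ||
        !identical(s$confounders, ref$confounders) ||
        !identical(s$covariates, ref$covariates))
      stop("joint components must share outcome, treatments, confounders and covariates",
           call. = FALSE)
  est <- parse_estimator(estimator)
  df <- analysis_sample(data, ref)
  plan <- if (est$cv) default_plan(df, ref, folds, seed) else NULL
  qm <- fit_q_models(df, ref, q_learner, plan)
  gm <- fit_g_models(df, ref, g_learner, plan, joint = joint_propensity)
  records <- lapply(specs, function(spec) {
    vertices <- vertex_weights(spec)
    check_vertex_support(df, spec, vertices)
    fits <- assemble_fits(df, spec, vertices, qm, gm, plan, g_floor)
    rec <- estimate_from_fits(fits, est$base, alpha = alpha, tol = tol,
                              max_iter = max_iter)
    rec$estimator <- estimator
    rec
  })
  list(records = records, joint = joint_test(records))
}

#' @export
print.estimate_record <- function(x, ...) {
  cat("<estimate_record>", x$spec$kind, "via", x$estimator,
      if (isTRUE(x$svp)) "(SVP-corrected)", "\n")
  cat(sprintf("  psi = %.6g  se = %.3g  %d%% CI [%.6g, %.6g]  p = %.3g  n = %d\n",
              x$psi, x$se, round(100 * (1 - x$alpha)), x$ci[1L], x$ci[2L],
              x$p, x$n))
  if (!is.null(x$Bn)) cat("  |B_n| =", format(abs(x$Bn), digits = 3), "\n")
  invisible(x)
}
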