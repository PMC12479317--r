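# Synthetic cohorts with the dependence structure of the two benchmark
# designs: a null design (trait, genotypes and covariates mutually
# independent, every genetic estimand truly 0) and a confounded design
# generated by ancestral sampling PCs,C -> A -> Y with a declared parametric
# mean function, so Monte-Carlo ground truth is available to arbitrary
# precision. Columns: y, A1..Am, PC1..PCq, age, sex.

#' Null-simulation scenario
#'
#' Genotypes are drawn `Binomial(2, MAF)` independently of the outcome and
#' of all covariates, so the true value of every genetic estimand is 0.
#'
#' @param n Sample size.
#' @param mafs Minor allele frequency per variant (vector; one variant per
#'   entry).
#' @param outcome `"continuous"` (standard normal) or `"binary"`.
#' @param case_fraction Case probability for binary outcomes.
#' @param n_pcs Number of (inert) principal-component covariates.
#' @return A `null_scenario`.
#' @export
null_scenario <- function(n = 5000L, mafs = 0.3,
                          outcome = c("continuous", "binary"),
                          case_fraction = 0.1, n_pcs = 6L) {
  structure(list(n = as.integer(n), mafs = mafs,
                 outcome = match.arg(outcome),
                 case_fraction = case_fraction, n_pcs = as.integer(n_pcs)),
            class = c("null_scenario", "scenario"))
}

#' Confounded-simulation scenario
#'
#' Ancestral sampling: `PCs ~ N(0, I)`, `age ~ N(0, 1)`,
#' `sex ~ Bernoulli(0.5)`; each variant's allele probability is
#' `expit(af_logit_j + pc_weights_j . PCs)` and the genotype is
#' `Binomial(2, .)` (two-stage binomial-logistic); the outcome mean is
#' `intercept + pc_out . PCs + age_eff * age + sex_eff * sex
#'  + sum_j beta_j d_j + sum_j dom_j 1{d_j = 2} + sum_pairs gamma d_j1 d_j2`
#' with `d_j` the allele dosage, plus gaussian noise (continuous) or a
#' Bernoulli draw through the logistic link (binary). The dominance terms
#' make allelic effects non-linear; the dosage-product terms carry the
#' k = 2 interactions.
#'
#' @param n Sample size.
#' @param n_pcs Number of principal components (default 6).
#' @param af_logit Logit baseline allele frequency per variant.
#' @param pc_weights Matrix (variants x n_pcs) of genotype-model PC loadings
#'   (rows recycled from a vector); 0 removes genotype confounding.
#' @param beta Per-variant dosage (additive) effect on the outcome.
#' @param dominance Per-variant extra effect of the homozygous-alt genotype.
#' @param interactions List of `list(pair = c(j1, j2), gamma = g)` entries.
#' @param pc_out PC loadings in the outcome mean.
#' @param age_eff,sex_eff,intercept Covariate effects and intercept.
#' @param sigma Gaussian noise SD (continuous outcomes).
#' @param outcome `"continuous"` or `"binary"`.
#' @return A `confounded_scenario`.
#' @export
confounded_scenario <- function(n = 10000L, n_pcs = 6L,
                                af_logit = stats::qlogis(c(0.3, 0.3)),
                                pc_weights = 0.4,
                                beta = c(0.1, 0.1),
                                dominance = c(0, 0),
                                interactions = list(),
                                pc_out = rep(0.3, n_pcs),
                                age_eff = 0.2, sex_eff = 0.1,
                                intercept = 0, sigma = 1,
                                outcome = c("continuous", "binary")) {
  m <- length(af_logit)
  if (!is.matrix(pc_weights))
    pc_weights <- matrix(pc_weights, m, n_pcs)
  stopifnot(nrow(pc_weights) == m, ncol(pc_weights) == n_pcs,
            length(beta) == m, length(dominance) == m)
  structure(list(n = as.integer(n), n_pcs = as.integer(n_pcs),
                 af_logit = af_logit, pc_weights = pc_weights,
                 beta = beta, dominance = dominance,
                 interactions = interactions, pc_out = pc_out,
                 age_eff = age_eff, sex_eff = sex_eff,
                 intercept = intercept, sigma = sigma,
                 outcome = match.arg(outcome)),
            class = c("confounded_scenario", "scenario"))
}

draw_covariates <- function(n, n_pcs) {
  pcs <- matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  list(pcs = pcs, age = stats::rnorm(n), sex = stats::rbinom(n, 1L, 0.5))
}

scenario_mu <- function(sc, cov, dosages) {
  mu <- sc$intercept + as.vector(cov$pcs %*% sc$pc_out) +
    sc$age_eff * cov$age + sc$sex_eff * cov$sex
  for (j in seq_along(sc$beta))
    mu <- mu + sc$beta[j] * dosages[, j] +
      sc$dominance[j] * (dosages[, j] == 2)
  for (it in sc$interactions)
    mu <- mu + it$gamma * dosages[, it$pair[1L]] * dosages[, it$pair[2L]]
  if (any(!is.finite(mu))) stop("scenario error: non-finite mean function",
                                call. = FALSE)
  mu
}

#' Simulate a cohort from a scenario
#'
#' `simulate_cohort()` dispatches on the scenario class;
#' [simulate_null()] and [simulate_confounded()] are the two designs.
#' Identical seeds reproduce tables bit-identically.
#'
#' @param scenario A [null_scenario()] or [confounded_scenario()].
#' @param seed Integer seed.
#' @param n Optional sample-size override.
#' @return A data.frame with columns `y`, `A1..Am`, `PC1..PCq`, `age`,
#'   `sex`; genotype columns are factors with levels `0,1,2`.
#' @export
simulate_cohort <- function(scenario, seed = 1L, n = NULL)
  UseMethod("simulate_cohort")

#' @rdname simulate_cohort
#' @export
simulate_null <- function(scenario, seed = 1L, n = NULL)
  simulate_cohort.null_scenario(scenario, seed, n)

#' @rdname simulate_cohort
#' @export
simulate_confounded <- function(scenario, seed = 1L, n = NULL)
  simulate_cohort.confounded_scenario(scenario, seed, n)

#' @export
simulate_cohort.null_scenario <- function(scenario, seed = 1L, n = NULL) {
  if (is.null(n)) n <- scenario$n
  withr::with_seed(as.integer(seed), {
    cov <- draw_covariates(n, scenario$n_pcs)
    a <- vapply(scenario$mafs, function(maf) stats::rbinom(n, 2L, maf),
                integer(n))
    y <- if (scenario$outcome == "binary")
      stats::rbinom(n, 1L, scenario$case_fraction)
    else stats::rnorm(n)
    assemble_cohort_df(y, a, cov)
  })
}

#' @export
simulate_cohort.confounded_scenario <- function(scenario, seed = 1L,
                                                n = NULL) {
  if (is.null(n)) n <- scenario$n
  withr::with_seed(as.integer(seed), {
    cov <- draw_covariates(n, scenario$n_pcs)
    m <- length(scenario$af_logit)
    a <- vapply(seq_len(m), function(j) {
      p <- stats::plogis(scenario$af_logit[j] +
                           as.vector(cov$pcs %*% scenario$pc_weights[j, ]))
      stats::rbinom(n, 2L, p)
    }, integer(n))
    mu <- scenario_mu(scenario, cov, a)
    y <- if (scenario$outcome == "binary")
      stats::rbinom(n, 1L, stats::plogis(mu))
    else mu + stats::rnorm(n, sd = scenario$sigma)
    assemble_cohort_df(y, a, cov)
  })
}

assemble_cohort_df <- function(y, a, cov) {
  df <- data.frame(y = y)
  for (j in seq_len(ncol(a)))
    df[[paste0("A", j)]] <- factor(a[, j], levels = 0:2)
  df <- cbind(df, as.data.frame(cov$pcs))
  df$age <- cov$age
  df$sex <- cov$sex
  df
}

#' Default estimand columns for simulated cohorts
#'
#' Convenience: the ATE/AIE of the simulated variants on `y` adjusted for
#' the scenario's PCs, with age and sex as outcome-only covariates.
#'
#' @param scenario A scenario object.
#' @param treatments Which variant columns (default `A1`, and `A2` when
#'   `k = 2`).
#' @param baseline,target Level vectors (defaults `0 -> 1` per treatment).
#' @return An `estimand`.
#' @export
scenario_estimand <- function(scenario, treatments = "A1", baseline = NULL,
                              target = NULL) {
  k <- length(treatments)
  if (is.null(baseline)) baseline <- rep("0", k)
  if (is.null(target)) target <- rep("1", k)
  confounders <- paste0("PC", seq_len(scenario$n_pcs))
  if (k == 1L)
    ate("y", treatments, baseline, target, confounders, c("age", "sex"))
  else
    aie("y", treatments, baseline, target, confounders, c("age", "sex"))
}

#' Monte-Carlo ground truth of an estimand under a confounded scenario
#'
#' Draws `m_draws` covariate vectors, evaluates the scenario's true mean
#' function at every vertex level assignment, and returns the signed-sum
#' average with its Monte-Carlo standard error. Null scenarios have truth 0
#' by construction.
#'
#' @param scenario A [confounded_scenario()].
#' @param spec An `estimand` over the scenario's columns.
#' @param m_draws Number of Monte-Carlo covariate draws.
#' @param seed Integer seed.
#' @return List with `value` and `mc_se`.
#' @export
monte_carlo_truth <- function(scenario, spec, m_draws = 1e5, seed = 1L) {
  if (inherits(scenario, "null_scenario"))
    return(list(value = 0, mc_se = 0))
  vertices <- vertex_weights(spec)
  withr::with_seed(as.integer(seed), {
    cov <- draw_covariates(m_draws, scenario$n_pcs)
    per_draw <- numeric(m_draws)
    for (v in seq_len(nrow(vertices))) {
      dos <- matrix(0, m_draws, length(scenario$af_logit))
      for (tn in colnames(vertices$a)) {
        j <- as.integer(sub("^A", "", tn))
        dos[, j] <- as.numeric(vertices$a[v, tn])
      }
      mu <- scenario_mu(scenario, cov, dos)
      if (scenario$outcome == "binary") mu <- stats::plogis(mu)
      per_draw <- per_draw + vertices$sign[v] * mu
    }
    list(value = mean(per_draw), mc_se = stats::sd(per_draw) / sqrt(m_draws))
  })
}

#' Coverage / bias / variance / power evaluation harness
#'
#' Runs replicated simulate-estimate cycles over a grid of scenarios,
#' estimators and sample sizes; per replicate it records whether the Wald CI
#' covers the truth and whether the test rejects at `alpha`; cells aggregate
#' to empirical coverage (with normal-approximation binomial MC error),
#' rejection rate, bias, variance and MSE.
#'
#' @param scenarios Named list of scenario objects.
#' @param estimators Character vector of estimator names.
#' @param ns Sample sizes.
#' @param replicates Replicates per cell (default 300).
#' @param q_learner,g_learner Nuisance learners.
#' @param spec_fn Function `scenario -> estimand` (default
#'   [scenario_estimand()] on `A1`).
#' @param alpha Test level.
#' @param seed Base seed; replicate r of cell c uses `seed + 7919 c + r`.
#' @param truth_draws Monte-Carlo draws for the ground truth of confounded
#'   scenarios.
#' @return data.frame, one row per (scenario, estimator, n) cell.
#' @export
evaluate_grid <- function(scenarios, estimators = "wtmle", ns = 5000L,
                          replicates = 300L, q_learner = lrn_glm(),
                          g_learner = lrn_glm(),
                          spec_fn = scenario_estimand, alpha = 0.05,
                          seed = 1L, truth_draws = 2e5) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenario = scenarios)
  cells <- expand.grid(scenario = names(scenarios), estimator = estimators,
                       n = ns, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (c_i in seq_len(nrow(cells))) {
    sc <- scenarios[[cells$scenario[c_i]]]
    spec <- spec_fn(sc)
    truth <- monte_carlo_truth(sc, spec, m_draws = truth_draws,
                               seed = seed)$value
    est <- numeric(replicates); cover <- logical(replicates)
    reject <- logical(replicates)
    for (r in seq_len(replicates)) {
      rseed <- (seed + 7919L * c_i + r) %% .Machine$integer.max
      dat <- simulate_cohort(sc, seed = rseed, n = cells$n[c_i])
      rec <- estimate_effect(spec, dat, estimator = cells$estimator[c_i],
                             q_learner = q_learner, g_learner = g_learner,
                             seed = rseed, alpha = alpha)
      est[r] <- rec$psi
      cover[r] <- rec$ci[1L] <= truth && truth <= rec$ci[2L]
      reject[r] <- rec$p < alpha
    }
    cov_hat <- mean(cover)
    out[[c_i]] <- data.frame(
      scenario = cells$scenario[c_i], estimator = cells$estimator[c_i],
      n = cells$n[c_i], replicates = replicates, truth = truth,
      coverage = cov_hat,
      coverage_se = sqrt(cov_hat * (1 - cov_hat) / replicates),
      rejection = mean(reject), bias = mean(est) - truth,
      variance = stats::var(est),
      mse = mean((est - truth)^2))
  }
  do.call(rbind, out)
}
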