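test_that("constant learner returns the training mean / class frequencies", {
  df <- fixture_binary_w(n = 120)
  fits <- fit_nuisances(df, spec_binary_w(), q_learner = lrn_constant(),
                        g_learner = lrn_constant())
  expect_equal(unique(fits$qbar_obs), mean(df$y))
  p1 <- mean(df$A1 == "1")
  i1 <- which(fits$vertices$a[, 1] == "1")
  expect_equal(unique(fits$g_vertex[, i1]), p1)
  expect_equal(unique(fits$g_vertex[, -i1]), 1 - p1)
})

test_that("exactly-specified GLM recovers the generating surface at the vertices", {
  fx <- fixture_interaction(n = 10000, gamma = 0.5)
  sc <- fx$scenario
  fits <- fit_nuisances(fx$data, fx$spec,
                        q_learner = lrn_glm(interactions = TRUE))
  vw <- fits$vertices
  for (v in seq_len(nrow(vw))) {
    d1 <- as.numeric(vw$a[v, "A1"]); d2 <- as.numeric(vw$a[v, "A2"])
    truth <- sc$intercept + sc$beta[1] * d1 + sc$beta[2] * d2 +
      0.5 * d1 * d2 +
      as.vector(as.matrix(fx$data[, paste0("PC", 1:6)]) %*% sc$pc_out) +
      sc$age_eff * fx$data$age + sc$sex_eff * fx$data$sex
    expect_lt(mean(abs(fits$qbar_vertex[, v] - truth)), 0.1)
  }
})

test_that("product propensity factorizes and normalizes", {
  withr::with_seed(3, {
    n <- 2000
    df <- data.frame(y = rnorm(n),
                     A1 = factor(rbinom(n, 1, 0.5), levels = 0:1),
                     A2 = factor(rbinom(n, 1, 0.2), levels = 0:1),
                     W1 = rnorm(n))
  })
  spec <- aie("y", c("A1", "A2"), c("0", "0"), c("1", "1"), "W1")
  fits <- fit_nuisances(df, spec, g_learner = lrn_constant())
  v11 <- which(fits$vertices$a[, "A1"] == "1" & fits$vertices$a[, "A2"] == "1")
  p1 <- mean(df$A1 == "1"); p2 <- mean(df$A2 == "1")
  expect_equal(unique(fits$g_vertex[, v11]), p1 * p2)
  # normalization: per-treatment level probabilities sum to 1, so the four
  # joint vertex propensities of two binary treatments sum to 1 too
  expect_equal(unique(rowSums(fits$g_vertex)), 1, tolerance = 1e-12)
  # glm propensity also normalizes per individual
  fits_glm <- fit_nuisances(df, spec, g_learner = lrn_glm())
  expect_equal(rowSums(fits_glm$g_vertex), rep(1, n), tolerance = 1e-6)
})

test_that("HWE allele-count propensity recovers a logistic genotype model", {
  sc <- confounded_scenario(n = 10000, pc_weights = 0.4)
  dat <- simulate_confounded(sc, seed = 21)
  spec <- scenario_estimand(sc)
  fits <- fit_nuisances(dat, spec, g_learner = lrn_hwe_glm())
  pcs <- as.matrix(dat[, paste0("PC", 1:6)])
  p_true <- plogis(sc$af_logit[1] + as.vector(pcs %*% sc$pc_weights[1, ]))
  i1 <- which(fits$vertices$a[, 1] == "1")
  g_true <- 2 * p_true * (1 - p_true)
  expect_lt(mean(abs(fits$g_vertex[, i1] - g_true)), 0.01)
})

test_that("positivity violations and schema problems raise clear errors", {
  df <- fixture_binary_w(n = 60)
  spec_bad <- ate("y", "A1", "0", "2", "W1")
  expect_error(fit_nuisances(df, spec_bad), "positivity error.*2")
  df$A1 <- NULL
  expect_error(fit_nuisances(df, spec_binary_w()), "schema error")
})

test_that("cross-fit predictions come from out-of-fold models only", {
  df <- fixture_binary_w(n = 300, seed = 8)
  spec <- spec_binary_w()
  plan <- crossfit_plan(nrow(df), k_folds = 3, seed = 2)
  fits1 <- fit_nuisances(df, spec, plan = plan)
  # perturb the outcomes of fold-1 rows: fold-1 predictions are made by the
  # model trained on folds 2-3 and must not move; other folds' must
  df2 <- df
  df2$y[plan$folds == 1] <- df2$y[plan$folds == 1] + 10
  fits2 <- fit_nuisances(df2, spec, plan = plan)
  expect_equal(fits1$qbar_obs[plan$folds == 1],
               fits2$qbar_obs[plan$folds == 1])
  expect_false(any(fits1$qbar_obs[plan$folds != 1] ==
                     fits2$qbar_obs[plan$folds != 1]))
  expect_length(fits1$qbar_obs, nrow(df))
})

test_that("degenerate binary training folds are reported with the fold", {
  withr::with_seed(4, {
    df <- data.frame(y = c(rep(1L, 3), rep(0L, 297)),
                     A1 = factor(rbinom(300, 1, 0.5), levels = 0:1),
                     W1 = rnorm(300))
  })
  plan <- crossfit_plan(300, k_folds = 3, strata = df$y, seed = 1)
  # force all cases into one training split's complement
  # the single case sits in fold 2, so fold 2's training split has none
  df$y[1:3] <- 0L; df$y[which(plan$folds == 2)[1]] <- 1L
  expect_error(fit_nuisances(df, spec_binary_w(), plan = plan),
               "degenerate fit.*fold 2")
  expect_equal(adaptive_k_folds(c(rep(0, 500), rep(1, 57))), 5L)
  expect_equal(adaptive_k_folds(c(rep(0, 500), rep(1, 15))), 3L)
  expect_equal(adaptive_k_folds(rep(0:1, 500)), 20L)
})

test_that("stacked ensemble concentrates weight on the well-specified learner", {
  withr::with_seed(9, {
    n <- 10000
    w <- rnorm(n)
    df_y <- 1 + 2 * w + rnorm(n)
    x <- cbind(W1 = w)
  })
  plan <- crossfit_plan(n, k_folds = 3, seed = 7)
  ens <- stacked_ensemble_fit(list(lrn_constant(), lrn_glm()), x, df_y,
                              plan, "gaussian")
  expect_gt(ens$weights[2], 0.9)
  expect_lt(ens$cv_losses[2], ens$cv_losses[1])
  # discrete metalearner is the argmin of the CV losses
  disc <- stacked_ensemble_fit(list(lrn_constant(), lrn_glm()), x, df_y,
                               plan, "gaussian", meta = "discrete")
  expect_equal(disc$weights, c(0, 1))
  # duplicated learners tie in CV loss and any split predicts identically
  dup <- stacked_ensemble_fit(list(lrn_glm(), lrn_glm()), x, df_y,
                              plan, "gaussian")
  expect_equal(dup$cv_losses[1], dup$cv_losses[2])
  expect_error(stacked_ensemble_fit(list(lrn_glm()), x, df_y, plan,
                                    "gaussian"), "at least 2")
  expect_error(lrn_stack(lrn_glm()), "at least 2")
})

test_that("the HAL slot exists but is explicitly not implemented", {
  df <- fixture_binary_w(n = 50)
  expect_error(fit_nuisances(df, spec_binary_w(), q_learner = lrn_hal()),
               "not implemented")
})
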