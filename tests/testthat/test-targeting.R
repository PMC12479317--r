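# Minimal hand-built nuisance_fits for exact bias arithmetic.
toy_fits <- function(y, a, qbar, g) {
  spec <- ate("y", "A1", "0", "1", "W1")
  vw <- vertex_weights(spec)
  n <- length(y)
  i1 <- which(vw$a[, 1] == "1")
  match_vertex <- cbind(a == vw$a[1, 1], a == vw$a[2, 1])
  structure(list(spec = spec, y = y, family = "gaussian", vertices = vw,
                 qbar_obs = qbar, qbar_vertex = matrix(qbar, n, 2),
                 g_vertex = matrix(c(g, 1 - g)[c(2 - (i1 == 1), 1 + (i1 == 1))][1:2],
                                   n, 2, byrow = TRUE),
                 g_obs = rep(g, n),
                 match_vertex = match_vertex, folds = NULL),
            class = "nuisance_fits")
}

test_that("first_order_bias evaluates the IPW signed residual mean", {
  # interpolating Qbar: residuals vanish, bias is zero
  df <- fixture_binary_w(n = 80)
  fits <- fit_nuisances(df, spec_binary_w(),
                        q_learner = lrn_glm(interactions = TRUE))
  fits$qbar_obs <- df$y
  expect_equal(first_order_bias(fits), 0)
  # n = 4 toy, k = 1, g = 0.5, A = (1,0,1,0), residuals (+1,-1,+1,-1):
  # direct evaluation of the bias sum gives
  # (1/4) [ 2(+1) + 2(+1) + (-2)(-1) + (-2)(-1) ] = 2
  y <- c(1, -1, 1, -1)
  a <- c("1", "0", "1", "0")
  tf <- toy_fits(y, a, qbar = rep(0, 4), g = 0.5)
  expect_equal(first_order_bias(tf), 2)
})

test_that("OSE equals plug-in plus bias, and plug-in when the bias is zero", {
  df <- fixture_binary_w(n = 200)
  # saturated Qbar: within-cell residuals sum to zero, so B_n = 0 exactly
  fits <- fit_nuisances(df, spec_binary_w(),
                        q_learner = lrn_glm(interactions = TRUE))
  expect_lt(abs(first_order_bias(fits)), 1e-10)
  rec_plug <- estimate_effect(spec_binary_w(), df, "plugin",
                              q_learner = lrn_glm(interactions = TRUE))
  rec_ose <- estimate_effect(spec_binary_w(), df, "ose",
                             q_learner = lrn_glm(interactions = TRUE))
  expect_equal(rec_ose$psi, rec_plug$psi, tolerance = 1e-10)
  # with a misspecified Qbar the bias is added back
  rec_c <- estimate_effect(spec_binary_w(), df, "ose",
                           q_learner = lrn_constant())
  expect_equal(rec_c$psi, rec_c$plugin + rec_c$Bn)
})

test_that("the linear fluctuation solves the score exactly in one step", {
  df <- fixture_binary_w(n = 300, seed = 13)
  for (mode in c("canonical", "weighted")) {
    fits <- fit_nuisances(df, spec_binary_w(), q_learner = lrn_constant())
    tf <- tmle_fluctuate(fits, mode = mode)
    expect_lte(tf$iterations, 1L)
    expect_lt(abs(tf$Bn), 1e-10 * sd(df$y))
  }
  # already-solved score: epsilon-free, Qbar unchanged
  fits0 <- fit_nuisances(df, spec_binary_w(),
                         q_learner = lrn_glm(interactions = TRUE))
  tf0 <- tmle_fluctuate(fits0)
  expect_equal(tf0$iterations, 0L)
  expect_equal(tf0$qbar_vertex, fits0$qbar_vertex)
})

test_that("score-solving holds for binary outcomes and both TMLE modes", {
  withr::with_seed(17, {
    n <- 600
    w <- rnorm(n)
    a <- rbinom(n, 1, plogis(0.5 * w))
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * a + 0.6 * w))
    df <- data.frame(y = y, A1 = factor(a, levels = 0:1), W1 = w)
  })
  spec <- spec_binary_w()
  for (est in c("tmle", "wtmle")) {
    rec <- estimate_effect(spec, df, est, q_learner = lrn_glm())
    expect_lt(abs(mean(rec$eif)), 1e-8)
    expect_true(rec$converged)
    expect_true(rec$psi > -1 && rec$psi < 1)
  }
})

test_that("the EIF identity mean(D*) = B_n + plugin - psi is exact", {
  df <- fixture_binary_w(n = 150, seed = 29)
  for (ql in list(lrn_constant(), lrn_glm(), lrn_glm(interactions = TRUE))) {
    fits <- fit_nuisances(df, spec_binary_w(), q_learner = ql)
    psi_arbitrary <- 0.3
    lhs <- mean(eif_values(fits, psi_hat = psi_arbitrary))
    rhs <- first_order_bias(fits) +
      plugin_estimate(fits$vertices, fits$qbar_vertex) - psi_arbitrary
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("CV estimators coincide with canonical ones for constant learners", {
  df <- fixture_binary_w(n = 400, seed = 31)
  can <- estimate_effect(spec_binary_w(), df, "wtmle",
                         q_learner = lrn_constant(),
                         g_learner = lrn_constant())
  cv <- estimate_effect(spec_binary_w(), df, "cv_wtmle",
                        q_learner = lrn_constant(),
                        g_learner = lrn_constant(), folds = 3, seed = 2)
  # constant learners leave only fold-composition noise
  expect_equal(cv$psi, can$psi, tolerance = 0.25 * can$se)
  # pooled held-out score is solved
  expect_lt(abs(mean(cv$eif)), 1e-8 * sd(df$y))
})

test_that("empty vertex support is reported as a distinct condition", {
  # both marginal levels exist but no individual sits on any joint vertex
  df <- data.frame(y = rnorm(40),
                   A1 = factor(rep(c("0", "1", "2", "2"), 10), levels = 0:2),
                   A2 = factor(rep(c("2", "2", "0", "1"), 10), levels = 0:2),
                   W1 = rnorm(40))
  spec <- aie("y", c("A1", "A2"), c("0", "0"), c("1", "1"), "W1")
  expect_error(estimate_effect(spec, df, "wtmle",
                               q_learner = lrn_constant(),
                               g_learner = lrn_constant()),
               class = "genetmle_empty_support")
})

test_that("OSE and TMLE agree more closely as n grows", {
  sc <- confounded_scenario(n = 1000, beta = c(0.3, 0), pc_weights = 0.4)
  spec <- scenario_estimand(sc)
  gap <- vapply(c(1000, 8000), function(n) {
    dat <- simulate_confounded(sc, seed = 37, n = n)
    r_ose <- estimate_effect(spec, dat, "ose", g_learner = lrn_hwe_glm())
    r_tmle <- estimate_effect(spec, dat, "tmle", g_learner = lrn_hwe_glm())
    abs(r_ose$psi - r_tmle$psi)
  }, 0)
  expect_lt(gap[2], gap[1])
})

test_that("cross-fitting restores the EIF variance an overfit learner deflates", {
  # an aggressively overfit Qbar shrinks training residuals, so the
  # canonical EIF variance (hence CI width) is too small; scoring out-of-fold
  # removes the shrinkage -- the mechanism behind coverage restoration
  sc <- null_scenario(n = 600, mafs = 0.3)
  spec <- scenario_estimand(sc)
  boost <- lrn_boost(n_rounds = 150, eta = 0.5, min_obs = 2)
  gap <- vapply(1:3, function(r) {
    dat <- simulate_null(sc, seed = 400 + r)
    can <- estimate_effect(spec, dat, "wtmle", q_learner = boost)
    cv <- estimate_effect(spec, dat, "cv_wtmle", q_learner = boost, seed = r)
    cv$sigma2 - can$sigma2
  }, 0)
  expect_true(all(gap > 0))
})
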