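test_that("EIF variance matches the brute-force stratified oracle when saturated", {
  df <- fixture_binary_w(n = 200)
  oracle <- stratified_oracle(df)
  rec <- estimate_effect(spec_binary_w(), df, "tmle",
                         q_learner = lrn_glm(interactions = TRUE))
  expect_equal(rec$psi, oracle$psi, tolerance = 1e-8)
  expect_equal(rec$sigma2, oracle$variance, tolerance = 1e-6)
  expect_equal(rec$eif, oracle$eif, tolerance = 1e-6)
})

test_that("iid_variance is the mean squared EIF", {
  expect_equal(iid_variance(rep(3, 10)), 9)
  withr::with_seed(1, z <- rnorm(1e5))
  expect_equal(iid_variance(z), 1, tolerance = 3 * sqrt(2 / 1e5) + 1e-3)
})

test_that("wald_ci matches the closed form and handles degenerate cases", {
  w <- wald_ci(0.5, sigma2 = 4, n = 400, alpha = 0.05)
  expect_equal(w$ci, 0.5 + c(-1, 1) * qnorm(0.975) * 2 / 20)
  expect_equal(round(w$ci, 3), c(0.304, 0.696))
  expect_equal(w$p, 2 * pnorm(-0.5 / 0.1))
  w0 <- wald_ci(0.7, sigma2 = 0, n = 100)
  expect_true(w0$degenerate)
  expect_equal(w0$ci, c(0.7, 0.7))
  w1 <- wald_ci(0.5, sigma2 = 4, n = 400, alpha = 1)
  expect_equal(w1$ci, c(0.5, 0.5))
})

test_that("joint_test computes Hotelling t2 against the F reference", {
  n <- 100
  # orthonormal EIF columns: crossprod/n = identity
  d1 <- rep(c(1, -1), n / 2)
  d2 <- rep(c(1, 1, -1, -1), n / 4)
  recs <- list(fake_record(0.1, d1), fake_record(0.2, d2))
  jt <- joint_test(recs)
  expect_equal(jt$sigma, diag(2), ignore_attr = TRUE)
  expect_equal(jt$t2, n * (0.1^2 + 0.2^2))  # = 5
  expect_equal(jt$p_value,
               pf(jt$t2 * (n - 2) / (2 * (n - 1)), 2, n - 2,
                  lower.tail = FALSE))
  # zero estimate: t2 = 0, p-value 1
  jt0 <- joint_test(list(fake_record(0, d1), fake_record(0, d2)))
  expect_equal(jt0$t2, 0)
  expect_equal(jt0$p_value, 1)
  # p = 1 reduces to the squared Wald z up to the F/chi2 factor
  jt1 <- joint_test(list(fake_record(0.1, d1)))
  expect_equal(jt1$t2, (sqrt(n) * 0.1 / sqrt(mean(d1^2)))^2)
  # singular covariance falls back to a pseudo-inverse
  expect_warning(joint_test(list(fake_record(0.1, d1), fake_record(0.1, d1))),
                 "singular")
  # component ordering permutes Sigma but leaves t2 invariant
  jt_swap <- joint_test(rev(recs))
  expect_equal(jt_swap$t2, jt$t2)
})

test_that("delta_method propagates EIFs by the gradient", {
  n <- 400
  withr::with_seed(5, {
    z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  })
  # center and scale so Var = 1 exactly and Cov = 0.5 exactly
  z1 <- as.vector(scale(z1)) * sqrt(n / (n - 1))
  resid <- lm.fit(cbind(z1), z2)$residuals
  z2 <- 0.5 * z1 + resid / sqrt(mean(resid^2)) * sqrt(1 - 0.25)
  recs <- list(fake_record(0.2, z1), fake_record(0.9, z2))
  rec_d <- allelic_effect_difference(recs[[1]], recs[[2]])
  expect_equal(rec_d$psi, 0.7)
  # Var D1 - 2 Cov + Var D2 = 1 - 2(0.5) + 1 = 1
  expect_equal(rec_d$sigma2, 1, tolerance = 1e-10)
  # the delta variance is the exact quadratic form in the EIF covariance
  sig <- crossprod(cbind(z1, z2)) / n
  g <- c(-1, 1)
  expect_equal(rec_d$sigma2, as.numeric(t(g) %*% sig %*% g))
  # identity function leaves the record numerically unchanged
  rec_id <- delta_method(recs[1], f = function(x) x[1],
                         grad = function(x) 1)
  expect_equal(rec_id$psi, recs[[1]]$psi)
  expect_equal(rec_id$sigma2, recs[[1]]$sigma2)
  # numeric gradient agrees with the analytic one
  rec_num <- delta_method(recs, f = function(x) x[2] - x[1])
  expect_equal(rec_num$sigma2, rec_d$sigma2, tolerance = 1e-6)
})

test_that("positivity pruning drops exactly the under-threshold contrasts", {
  # genotype frequencies 0.81 / 0.18 / 0.01 built exactly
  df <- data.frame(y = rnorm(100),
                   A1 = factor(rep(c("0", "1", "2"), c(81, 18, 1)),
                               levels = 0:2),
                   W1 = rnorm(100))
  specs <- list(ate("y", "A1", "0", "1", "W1"),
                ate("y", "A1", "1", "2", "W1"))
  pr1 <- positivity_prune(df, specs, threshold = 0.01)
  expect_length(pr1$kept, 2)
  expect_length(pr1$dropped, 0)
  pr2 <- positivity_prune(df, specs, threshold = 0.02)
  expect_length(pr2$kept, 1)
  expect_identical(pr2$kept[[1]]$contrast[[1]][["target"]], "1")
  expect_identical(pr2$dropped[[1]]$contrast[[1]][["baseline"]], "1")
  pr0 <- positivity_prune(df, specs, threshold = 0)
  expect_length(pr0$dropped, 0)
  # per-treatment marginal mode agrees here (k = 1)
  prm <- positivity_prune(df, specs, threshold = 0.02, per_treatment = TRUE)
  expect_length(prm$kept, 1)
})

test_that("bh_adjust reproduces textbook step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_true(all(diff(sort(bh_adjust(c(0.001, 0.2, 0.04, 0.9)))) >= 0))
})
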