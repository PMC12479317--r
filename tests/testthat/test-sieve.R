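test_that("compute_grm reproduces the 2x2 hand-worked example", {
  dos <- rbind(ind1 = c(0, 2), ind2 = c(2, 0))
  g <- compute_grm(dos)
  expect_equal(g$p, c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(g$G[1, 2], -4)
  expect_equal(g$G[2, 1], -4)
  expect_equal(g$diag, c(4, 4), ignore_attr = TRUE)
})

test_that("GRM concentrates near 1 for duplicated individuals and is order-invariant", {
  withr::with_seed(2, {
    R <- 800
    p <- runif(R, 0.1, 0.9)
    dos <- t(replicate(30, rbinom(R, 2, p)))
  })
  dos <- rbind(dos, dos[1, ])  # duplicate individual 1
  g <- compute_grm(dos)
  n <- nrow(dos)
  expect_equal(g$G[1, n], 1, tolerance = 3 / sqrt(R) + 0.02)
  # unrelated pairs hover near 0
  expect_lt(max(abs(g$G[2:10, 11:20])), 4 / sqrt(R) + 0.05)
  # permuting variants leaves G unchanged
  withr::with_seed(3, perm <- sample(ncol(dos)))
  expect_equal(compute_grm(dos[, perm])$G, g$G)
  # monomorphic variants are excluded with a warning
  expect_warning(g2 <- compute_grm(cbind(dos, 0, 2)), "monomorphic")
  expect_equal(g2$R, ncol(dos))
})

test_that("sieve_curve recovers the iid estimator at tau = 0 and collapses at all pairs", {
  withr::with_seed(7, {
    n <- 120
    dos <- t(replicate(n, rbinom(300, 2, runif(300, 0.2, 0.8))))
    eif <- rnorm(n)
  })
  eif <- eif - mean(eif)  # TMLE-like: mean-zero EIF
  g <- compute_grm(dos)
  curve <- sieve_curve(eif, g, taus = c(0, 0.5, 1, 2))
  expect_equal(curve$sigma2[1], iid_variance(eif))
  # all pairs included: the double sum collapses to (sum D)^2 / n ~ 0
  expect_equal(curve$sigma2[4], sum(eif)^2 / n, tolerance = 1e-12)
  expect_lt(abs(curve$sigma2[4]), 1e-20)
  # chunking is an implementation detail, not a result
  expect_equal(sieve_curve(eif, g, taus = c(0, 0.5, 1, 2), chunk = 7L)$sigma2,
               curve$sigma2)
  expect_error(sieve_curve(eif, g, taus = numeric()), "empty tau grid")
  expect_error(sieve_curve(rnorm(10), g), "same individuals")
})

test_that("the curve steps exactly at the between-block dissimilarity", {
  # two blocks of identical genotypes: within-block d = 0, between d > 0
  b <- 4
  G <- matrix(0.2, 2 * b, 2 * b)
  G[1:b, 1:b] <- 1
  G[(b + 1):(2 * b), (b + 1):(2 * b)] <- 1
  eif <- c(rep(1, b), rep(-1, b))
  curve <- sieve_curve(eif, G, taus = c(0, 0.5, 0.79, 0.81, 1))
  n <- 2 * b
  # d = 0 within blocks: self-pairs plus all within-block cross-pairs
  within <- (n + 2 * b * (b - 1)) / n
  expect_equal(curve$sigma2[1], within)
  expect_equal(curve$sigma2[3], within)  # flat until d = 0.8
  # at tau >= 0.8 the (negative) between-block products enter
  expect_equal(curve$sigma2[4], (n + 2 * b * (b - 1) - 2 * b^2) / n)
})

test_that("block-exchangeable EIF correlation is recovered on the plateau", {
  m <- 1000; b <- 5; rho <- 0.5
  withr::with_seed(19, {
    z <- rep(rnorm(m), each = b)
    eif <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(m * b)
  })
  # within-block dissimilarity 0.1, between-block 1 (synthetic relatedness)
  G <- matrix(0, m * b, m * b)
  blocks <- rep(seq_len(m), each = b)
  for (bl in split(seq_len(m * b), blocks)) G[bl, bl] <- 0.9
  curve <- sieve_curve(eif, G, taus = c(0, 0.5))
  # sigma2 (1 + (b - 1) rho) = 3; the estimator is (1/n) sum_blocks S_b^2
  # with S_b ~ N(0, b(1+(b-1)rho)), so its 3-SE band is 3 sqrt(2/m) relative
  expect_equal(curve$sigma2[2], 1 + (b - 1) * rho,
               tolerance = 3 * sqrt(2 / m))
  expect_equal(curve$tau0, 0.5)
})

test_that("corrected_inference swaps in the plateau variance conservatively", {
  df <- fixture_binary_w(n = 150)
  rec <- estimate_effect(spec_binary_w(), df, "wtmle")
  # duplicated-individuals GRM: positively correlated EIFs within pairs
  n <- rec$n
  withr::with_seed(23, dos <- t(replicate(n, rbinom(400, 2, runif(400, .2, .8)))))
  g <- compute_grm(dos)
  curve <- sieve_curve(rec$eif, g, taus = seq(0, 1, length.out = 20))
  crec <- corrected_inference(rec, curve)
  expect_true(crec$svp)
  expect_gte(crec$sigma2, rec$sigma2)   # grid contains tau = 0
  expect_gte(crec$p, rec$p)
  # no correction: record inference unchanged
  flat <- curve; flat$sigma2_selected <- rec$sigma2; flat$tau0 <- 0
  crec0 <- corrected_inference(rec, flat)
  expect_equal(crec0$ci, rec$ci)
})

test_that("GRM round-trips through the text and binary dialects", {
  withr::with_seed(29, dos <- t(replicate(12, rbinom(50, 2, runif(50, .2, .8)))))
  g <- compute_grm(dos)
  prefix <- file.path(tempdir(), "toy")
  write_grm(g, prefix)
  g2 <- read_grm(prefix)
  expect_equal(g2$G, g$G, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(g2$R, g$R)
  # GCTA binary dialect (float32 lower triangle), built at run time
  n <- length(g$ids)
  lower <- which(lower.tri(g$G, diag = TRUE), arr.ind = TRUE)
  lower <- lower[order(lower[, 1], lower[, 2]), ]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(g$G[lower]), con, size = 4L, endian = "little")
  close(con)
  g3 <- read_grm(prefix)
  expect_equal(g3$G, g$G, ignore_attr = TRUE, tolerance = 1e-6)
  file.remove(paste0(prefix, c(".grm.gz", ".grm.id", ".grm.bin")))
})

test_that("hwe_filter drops gross Hardy-Weinberg violations", {
  withr::with_seed(31, {
    ok <- rbinom(500, 2, 0.4)
    bad <- rep(c(0, 2), 250)  # no heterozygotes at p = 0.5
    dos <- cbind(v1 = ok, v2 = bad, v3 = rbinom(500, 2, 0.2))
  })
  kept <- hwe_filter(dos, alpha = 1e-6)
  expect_equal(colnames(kept), c("v1", "v3"))
})
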