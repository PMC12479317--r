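# Deterministic in-code fixtures and independent oracles shared by the suite.

# Single binary confounder, binary treatment, continuous outcome with a
# treatment-by-confounder interaction; the discrete-W case where the exact
# nonparametric stratified estimator is computable by enumeration.
fixture_binary_w <- function(n = 200, seed = 11) {
  withr::with_seed(seed, {
    w <- stats::rbinom(n, 1, 0.5)
    a <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.8 * w))
    y <- 0.5 + w + 0.7 * a + 0.4 * a * w + stats::rnorm(n)
    data.frame(y = y, A1 = factor(a, levels = 0:1), W1 = w)
  })
}

spec_binary_w <- function() ate("y", "A1", "0", "1", "W1")

# Exact nonparametric stratified ATE and its influence-function values,
# by direct enumeration over the discrete confounder (the brute-force
# oracle the saturated estimators must match).
stratified_oracle <- function(df) {
  n <- nrow(df)
  psi <- 0
  parts <- data.frame(y1bar = numeric(n), y0bar = numeric(n),
                      g1 = numeric(n))
  for (w in unique(df$W1)) {
    idx <- df$W1 == w
    y1 <- df$y[idx & df$A1 == "1"]
    y0 <- df$y[idx & df$A1 == "0"]
    g1 <- length(y1) / sum(idx)
    psi <- psi + mean(idx) * (mean(y1) - mean(y0))
    parts$y1bar[idx] <- mean(y1)
    parts$y0bar[idx] <- mean(y0)
    parts$g1[idx] <- g1
  }
  a <- as.numeric(as.character(df$A1))
  eif <- a / parts$g1 * (df$y - parts$y1bar) -
    (1 - a) / (1 - parts$g1) * (df$y - parts$y0bar) +
    (parts$y1bar - parts$y0bar) - psi
  list(psi = psi, eif = eif, variance = mean(eif^2))
}

# Minimal estimate_record for inference-level tests.
fake_record <- function(psi, eif, alpha = 0.05) {
  structure(list(spec = ate("y", "A", "0", "1", "W"), estimator = "fake",
                 psi = psi, eif = eif, n = length(eif),
                 sigma2 = mean(eif^2), alpha = alpha, svp = FALSE),
            class = "estimate_record")
}

# Two-variant cohort with a pure dosage-product interaction and no
# confounding; the AIE truth is gamma exactly.
fixture_interaction <- function(n, gamma, seed = 5) {
  sc <- confounded_scenario(n = n, pc_weights = 0,
                            interactions = list(list(pair = c(1, 2),
                                                     gamma = gamma)))
  list(scenario = sc, data = simulate_confounded(sc, seed = seed),
       spec = scenario_estimand(sc, treatments = c("A1", "A2")))
}
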