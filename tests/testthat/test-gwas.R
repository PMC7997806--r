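test_that("the GRM matches a pencil-and-paper computation on a 3x2 table", {
  G <- matrix(c(0, 1, 2,
                1, 1, 0), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("v1", "v2")))
  K <- compute_grm(G)
  # oracle: explicit double loop over samples and variants
  p <- c(mean(G[, 1]) / 2, mean(G[, 2]) / 2)
  expected <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (m in 1:2)
      s <- s + (G[i, m] - 2 * p[m]) * (G[j, m] - 2 * p[m]) /
        (2 * p[m] * (1 - p[m]))
    expected[i, j] <- s / 2
  }
  expect_equal(matrix(K, 3, 3), expected, tolerance = 1e-12)
  expect_equal(attr(K, "n_variants"), 2)
  expect_lt(max(abs(K - t(K))), 1e-10)
})

test_that("identical genotype vectors give identical relatedness", {
  G <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0))
  K <- compute_grm(G)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
})

test_that("monomorphic variants are skipped; all-monomorphic errors", {
  G <- cbind(c(0, 1, 2), c(1, 1, 1))
  K <- compute_grm(G)
  expect_equal(attr(K, "n_skipped"), 1)
  expect_error(compute_grm(cbind(c(2, 2, 2))), "monomorphic")
})

test_that("unrelated samples have near-zero mean off-diagonal relatedness", {
  set.seed(22)
  G <- matrix(rbinom(300 * 10000, 2, runif(10000, 0.1, 0.9)[rep(1:10000, each = 300)]),
              300, 10000)
  K <- compute_grm(G)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.01)
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
})

test_that("principal components separate simulated populations and are orthogonal", {
  set.seed(23)
  cfg <- quiet_sim_config(n_patients = 200, n_variants = 2000,
                          ancestry_proportions = c(AA = 0.5, EA = 0.5),
                          fst = c(AA = 0.1, EA = 0.1))
  g <- simulate_genotypes(cfg)
  K <- compute_grm(g$genotypes)
  pcs <- compute_pcs(K, 10)
  r <- cor(pcs[, 1], as.numeric(g$ancestry == "EA"))
  expect_gt(abs(r), 0.9)
  cross <- crossprod(pcs)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-6)
  # deterministic sign: the largest-magnitude loading is positive
  expect_true(all(apply(pcs, 2, function(s) s[which.max(abs(s))] > 0)))
  expect_error(compute_pcs(K, 200), "smaller")
})

test_that("REML lands on the boundary and reduces to OLS without polygenic signal", {
  set.seed(24)
  n <- 150
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- as.numeric(X %*% c(2, 1, -1) + rnorm(n))
  K <- diag(n)   # isotropic relatedness: no identifiable polygenic component
  fit <- fit_lmm_null(y, X, K)
  expect_identical(fit$h2, 0)
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
})

test_that("the restricted likelihood at the optimum dominates a grid and a dense oracle agrees", {
  set.seed(25)
  fx <- polygenic_fixture(n = 120, m = 300, h2 = 0.5)
  fit <- fit_lmm_null(fx$y, fx$X, fx$K)
  for (h in c(0, 0.25, 0.5, 0.75))
    expect_gte(fit$logLik + 1e-6, dense_reml_loglik(fx$y, fx$X, fx$K, h))
  expect_equal(fit$logLik, dense_reml_loglik(fx$y, fx$X, fx$K, fit$h2),
               tolerance = 1e-6)
  expect_gte(fit$sigma2_g, 0)
  expect_gt(fit$sigma2_g + fit$sigma2_e, 0)
})

test_that("a non-PSD relatedness matrix and rank-deficient design are rejected", {
  K <- diag(3); K[1, 2] <- K[2, 1] <- 2       # eigenvalue below -1e-8
  expect_error(fit_lmm_null(rnorm(3), cbind(1, 1:3), K), "positive semi-definite")
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_lmm_null(rnorm(4), X, diag(4)), "rank deficient")
})

test_that("with sigma2_g = 0 the score test is OLS, to 1e-8", {
  set.seed(26)
  n <- 200
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- as.numeric(X %*% c(1, 2) + rnorm(n))
  fit <- fit_lmm_null(y, X, diag(n))
  expect_identical(fit$h2, 0)
  G <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  res <- score_test(fit, G)
  # dense OLS oracle: residual-maker algebra with the null-model variance
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  s2 <- sum((M %*% y)^2) / (n - ncol(X))
  for (j in 1:5) {
    g <- G[, j]
    beta_ols <- sum(g * (M %*% y)) / sum(g * (M %*% g))
    se_ols <- sqrt(s2 / sum(g * (M %*% g)))
    expect_equal(res$beta[j], beta_ols, tolerance = 1e-8)
    expect_equal(res$se[j], se_ols, tolerance = 1e-8)
    # and the coefficient equals lm() on the augmented design
    expect_equal(res$beta[j], unname(coef(lm(y ~ 0 + X + g))["g"]),
                 tolerance = 1e-8)
  }
})

test_that("an injected allele effect is recovered within 3 SE", {
  set.seed(27)
  fx <- polygenic_fixture(n = 600, m = 500, h2 = 0.3, sigma2 = 25)
  g <- rbinom(600, 2, 0.3)
  y <- fx$y + 8 * g
  fit <- fit_lmm_null(y, fx$X, fx$K)
  res <- score_test(fit, g)
  expect_lt(abs(res$beta - 8), 3 * res$se)
  expect_lt(res$p, 1e-6)
})

test_that("monomorphic candidates are skipped with a reason", {
  set.seed(28)
  n <- 80
  fit <- fit_lmm_null(rnorm(n), cbind(rep(1, n)), diag(n))
  res <- score_test(fit, cbind(mono = rep(2L, n), ok = rbinom(n, 2, 0.5)))
  expect_equal(res$skipped[1], "monomorphic")
  expect_true(is.na(res$p[1]))
  expect_false(is.na(res$p[2]))
})

test_that("genomic inflation behaves as a median chi-square ratio", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1)
  set.seed(29)
  p <- runif(1e5)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.02)
  # halving every chi-square halves lambda
  q <- qchisq(p, 1, lower.tail = FALSE)
  p_half <- pchisq(q / 2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_half), genomic_inflation(p) / 2,
               tolerance = 1e-10)
  expect_error(genomic_inflation(numeric(0)), "no p values")
})

test_that("a single-ancestry scan equals its own stratum and small strata are skipped", {
  cfg <- quiet_sim_config(n_patients = 120, n_variants = 150,
                          ancestry_proportions = c(EA = 1),
                          fst = c(EA = 0.05), noise_sd_mmHg = 2,
                          pd_amplitude_sd = 4, seed = 41L)
  b <- simulate_cohort(cfg)
  d <- suppressWarnings(derive_phenotypes(b, pipeline_config()))
  expect_warning(
    scan <- run_gwas(b, d$phenotypes, pipeline_config(n_pcs = 4),
                     strata = c("ALL", "EA", "AA")),
    "stratum AA skipped")
  expect_equal(scan$results$ALL$p, scan$results$EA$p)
  expect_equal(unname(scan$lambda_gc["ALL"]), unname(scan$lambda_gc["EA"]))
  expect_true(all(scan$results$ALL$maf <= 0.5, na.rm = TRUE))
})
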