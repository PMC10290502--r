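test_that("GRM closed forms hold for constructed genotypes", {
  # one variant, dosages (0, 2), p = 0.5 -> off-diagonal -2
  g <- compute_grm(matrix(c(0, 2), nrow = 1))
  expect_equal(g[1, 2], -2, ignore_attr = TRUE)
  expect_equal(g[1, 1], 2, ignore_attr = TRUE)
  # duplicated sample column: off-diagonal equals the diagonal entry
  set.seed(91)
  d <- matrix(rbinom(100 * 8, 2, 0.4), nrow = 100)
  d <- cbind(d, d[, 3])
  g2 <- compute_grm(d)
  expect_equal(g2[3, 9], g2[3, 3])
  # monomorphic variants are skipped with a warning
  expect_warning(compute_grm(rbind(matrix(rbinom(40, 2, .5), 2),
                                   rep(0, 20))), "monomorphic")
})

test_that("GRM equals the naive double-loop computation", {
  set.seed(92)
  d <- matrix(rbinom(200 * 30, 2, runif(200, 0.05, 0.5)), nrow = 200)
  d[sample(length(d), 50)] <- NA
  g <- compute_grm(d)
  expect_equal(unclass(g), naive_grm(d), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("null REML degenerates correctly and recovers heritability", {
  set.seed(93)
  n <- 120
  X <- cbind(1, rbinom(n, 1, .5), rnorm(n))
  # G = I: the variance split is unidentifiable but the total matches OLS
  y <- drop(X %*% c(1, .4, -.2)) + rnorm(n)
  f <- fit_null_lmm(y, X, diag(n))
  ols_s2 <- sum(lm.fit(X, y)$residuals^2) / (n - 3)
  expect_equal(f$sigma2_u + f$sigma2_e, ols_s2, tolerance = 1e-6)
  # exact linear phenotype: both variances collapse to ~0
  f0 <- fit_null_lmm(drop(X %*% c(2, 1, 3)), X, diag(n))
  expect_lt(f0$sigma2_u + f0$sigma2_e, 1e-10)
  # h2 = 0.5 recovery with a structured GRM, mean over 25 seeds
  cfg <- sim_config(n_samples = 300, n_variants = 1500, missing_rate = 0,
                    seed = 17)
  geno <- simulate_genotypes(cfg)
  G <- compute_grm(geno, exclude_chrom = character())
  eg <- eigen(G, symmetric = TRUE)
  Xc <- cbind(1, rbinom(300, 1, .5))
  h2 <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    u <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * 0.5) * rnorm(300)))
    y <- 1 + u + rnorm(300, 0, sqrt(0.5))
    ft <- fit_null_lmm(y, Xc, G, eig = eg)
    ft$sigma2_u / (ft$sigma2_u + ft$sigma2_e)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.1)
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  set.seed(94)
  n <- 60
  X <- cbind(1, rbinom(n, 1, .5))
  X <- cbind(X, X[, 2])  # aliased
  y <- rnorm(n)
  expect_warning(f <- fit_null_lmm(y, X, diag(n)), "aliased")
  expect_equal(length(f$fixed_effects), 2)
})

test_that("scan with identity GRM reduces exactly to OLS", {
  set.seed(95)
  n <- 90
  X <- cbind(1, rnorm(n), rbinom(n, 1, .5))
  y <- drop(X %*% c(1, .5, -.3)) + rnorm(n)
  fit <- fit_null_lmm(y, X, diag(n))
  d <- rbind(rbinom(n, 2, .3), rbinom(n, 2, .2))
  d[2, 5] <- NA  # exercise the pairwise-deletion path too
  vs <- variant_set(data.frame(chrom = "1", pos = c(10L, 20L),
                               vid = c("v1", "v2"), ref = "A", alt = "G"),
                    d)
  a <- scan_gene(fit, vs)
  o1 <- summary(lm(y ~ X[, -1] + d[1, ]))$coefficients[4, ]
  expect_equal(a$beta[1], unname(o1[1]), tolerance = 1e-8)
  expect_equal(a$se[1], unname(o1[2]), tolerance = 1e-8)
  ok <- !is.na(d[2, ])
  o2 <- summary(lm(y[ok] ~ X[ok, -1] + d[2, ok]))$coefficients[4, ]
  expect_equal(a$beta[2], unname(o2[1]), tolerance = 1e-8)
  expect_equal(a$se[2], unname(o2[2]), tolerance = 1e-8)
  expect_equal(a$n, c(n, n - 1L))
  # monomorphic variant within used samples: beta 0, p 1, flagged
  vs3 <- variant_set(data.frame(chrom = "1", pos = 30L, vid = "v3",
                                ref = "A", alt = "G"),
                     matrix(2, 1, n))
  a3 <- scan_gene(fit, vs3)
  expect_equal(a3$beta, 0)
  expect_equal(a3$p, 1)
  expect_equal(a3$flag, "monomorphic")
})

test_that("joint sample permutation leaves every statistic unchanged", {
  cfg <- sim_config(n_samples = 60, n_variants = 300, n_genes = 10,
                    chrom_length_bp = 3e6, missing_rate = 0.02, seed = 19)
  geno <- simulate_genotypes(cfg)
  # a 60-sample panel leaves a few monomorphic variants in the GRM
  expr <- suppressWarnings(simulate_expression(cfg, geno))
  y <- log2(expr$counts[1, ] + 1)
  X <- stats::model.matrix(~ sex + breed, expr$meta)
  G <- expr$grm
  f <- fit_null_lmm(y, X, G)
  a <- scan_gene(f, geno)
  perm <- sample(60)
  geno_p <- geno
  geno_p$dosages <- geno$dosages[, perm]
  f_p <- fit_null_lmm(y[perm], X[perm, ], G[perm, perm])
  a_p <- scan_gene(f_p, geno_p)
  expect_equal(a_p$beta, a$beta, tolerance = 1e-6)
  expect_equal(a_p$p, a$p, tolerance = 1e-6)
  expect_equal(c(f_p$sigma2_u, f_p$sigma2_e), c(f$sigma2_u, f$sigma2_e),
               tolerance = 1e-6)
})

test_that("Bonferroni adjustment clamps, scales, and shrinks with family size", {
  expect_equal(bonferroni_adjust(1e-9, 2.5e7), 0.025)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_error(bonferroni_adjust(0.5, 0), "family_size")
  set.seed(96)
  p <- runif(100)
  q1 <- bonferroni_adjust(p, 1000)
  q2 <- bonferroni_adjust(p, 5000)
  expect_true(all(q2 >= q1))          # significance shrinks as family grows
  expect_true(all(diff(q1[order(p)]) >= -1e-12))  # monotone in p
  expect_equal(q1, pmin(1, p * 1000))
})

test_that("test-count bookkeeping multiplies variants by summed genes", {
  expect_equal(count_tests(10, c(2, 3)), 50)
  expect_equal(count_tests(5, numeric(0)), 0)
})

test_that("planted cis variant lands in the top-5 p-values at n = 300", {
  cfg <- sim_config(n_samples = 300, n_variants = 4000, missing_rate = 0,
                    seed = 23)
  geno <- simulate_genotypes(cfg)
  G <- compute_grm(geno, exclude_chrom = character())
  eg <- eigen(G, symmetric = TRUE)
  af <- rowMeans(geno$dosages) / 2
  cand <- which(pmin(af, 1 - af) >= 0.2)
  X <- cbind(1, rbinom(300, 1, .5))
  hits <- vapply(1:10, function(s) {
    set.seed(2000 + s)
    causal <- sample(cand, 1)
    u <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * 0.3) * rnorm(300)))
    y <- 2 + geno$dosages[causal, ] * 1.0 + u + rnorm(300, 0, sqrt(0.7))
    f <- fit_null_lmm(y, X, G, eig = eg)
    a <- scan_gene(f, geno)
    causal %in% order(a$p)[1:5]
  }, logical(1))
  expect_gte(sum(hits), 9)
})
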