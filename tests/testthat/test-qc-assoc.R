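test_that("HWE chi-square matches hand-computed oracles", {
  # exact HWE proportions: statistic 0
  expect_equal(hwe_test(25, 50, 25), 1)
  # complete heterozygote deficit: statistic equals n
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_equal(qchisq(hwe_test(50, 0, 50), 1, lower.tail = FALSE), 100,
               tolerance = 1e-6)
  # hand oracle at (30, 40, 30): q = 0.5, expected (25, 50, 25),
  # chi = 25/25 + 100/50 + 25/25 = 4
  expect_equal(hwe_test(30, 40, 30), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # monomorphic SNP: defined as 1
  expect_equal(hwe_test(0, 0, 40), 1)
  expect_equal(hwe_test(40, 0, 0), 1)
  expect_error(hwe_test(0, 0, 0), "at least one")
})

test_that("marker filters apply strict thresholds with ordered reasons", {
  n <- 50L
  # 10-SNP toy panel with constructed metrics
  base <- withr::with_seed(1, matrix(rbinom(n * 10, 2, 0.4), nrow = n))
  d <- base
  d[1, 1] <- NA          # call rate 49/50 = 0.98 exactly -> excluded (strict)
  d[, 2] <- rep(0L, n); d[seq_len(5), 2] <- 1L  # maf 0.05 -> kept
  d[, 3] <- c(1L, rep(0L, n - 1L))              # maf 0.01 exactly -> excluded
  d[, 4] <- rep(c(0L, 2L), n / 2)               # het deficit -> hwe fail
  d[, 5] <- rep(0L, n)                          # monomorphic -> maf fail
  d[1:2, 6] <- NA                               # call rate 0.96 and hwe-violating
  d[, 6] <- c(NA, NA, rep(c(0L, 2L), 24))
  g <- make_geno(d)
  log <- filter_snps(g, qc_thresholds())
  expect_identical(log$keep,
                   c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                     rep(TRUE, 4)))
  expect_identical(log$reason[c(1, 3, 4, 5, 6)],
                   c("call_rate", "maf", "hwe", "maf", "call_rate"))
  # retained set equals the marginal conjunction regardless of rule order
  m <- snp_qc(g)
  expect_identical(log$keep, m$call_rate > 0.98 & m$hwe_p > 0.001 & m$maf > 0.01)
})

test_that("sample call-rate boundary at 0.95 is retained", {
  d <- matrix(rep(1L, 20 * 5), nrow = 5)
  d[1, 1] <- NA               # 19/20 = 0.95 exactly -> retained
  d[2, 1:2] <- NA             # 18/20 = 0.90 -> removed
  g <- make_geno(d)
  log <- filter_samples(g)
  expect_identical(log$keep, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  # no-missing case retains everyone
  expect_true(all(filter_samples(make_geno(matrix(1L, 4, 6)))$keep))
})

test_that("genotype PCs separate discrete subpopulations", {
  n <- 200L; s <- 300L
  pop <- rep(0:1, each = n / 2)
  d <- withr::with_seed(2, {
    f1 <- runif(s, 0.1, 0.5)
    delta <- sample(c(-0.25, 0.25), s, replace = TRUE)
    f2 <- pmin(pmax(f1 + delta, 0.05), 0.95)
    t(vapply(pop, function(p) rbinom(s, 2L, if (p == 0) f1 else f2), integer(s)))
  })
  pcs <- genotype_pcs(make_geno(d), k = 2)
  expect_gt(abs(cor(pcs$PC1, pop)), 0.9)
})

test_that("genotype PCs recover a rank-1 structure up to sign", {
  u <- rep(c(0L, 1L, 2L), length.out = 30L)
  d <- matrix(u, nrow = 30L, ncol = 10L)
  d <- d + withr::with_seed(3, matrix(rbinom(300, 1, 0.02), 30)) # break exact ties
  d[d > 2L] <- 2L
  pcs <- genotype_pcs(make_geno(d), k = 1)
  expect_gt(abs(cor(pcs$PC1, u)), 0.98)
  expect_error(genotype_pcs(make_geno(d), k = 10), "smaller")
})

test_that("single-SNP OLS matches a hand solve on six individuals", {
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 0.9, 2.2, -0.2, 1.1, 1.8)
  g <- make_geno(matrix(as.integer(x), ncol = 1))
  a <- run_gwas(g, y)
  X <- cbind(1, x)
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  se <- sqrt(sum(r^2) / (6 - 2) * solve(crossprod(X))[2, 2])
  expect_equal(a$beta, b[2], tolerance = 1e-10)
  expect_equal(a$se, se, tolerance = 1e-10)
  expect_equal(a$p, 2 * pt(-abs(b[2] / se), 4), tolerance = 1e-10)
})

test_that("a perfect fit hits the p-value floor and beta 1", {
  x <- as.integer(c(0, 1, 2, 1, 0, 2, 1, 0))
  g <- make_geno(matrix(x, ncol = 1))
  a <- run_gwas(g, as.numeric(x))
  expect_equal(a$beta, 1, tolerance = 1e-12)
  expect_equal(a$p, 1e-300)
})

test_that("missing dosages fall back to per-SNP regression consistently", {
  d <- withr::with_seed(4, matrix(rbinom(400, 2, 0.3), nrow = 100))
  y <- withr::with_seed(5, rnorm(100))
  cov <- withr::with_seed(6, matrix(rnorm(200), ncol = 2))
  d2 <- d
  d2[1, 2] <- NA
  a <- run_gwas(make_geno(d2), y, covariates = cov)
  # oracle via lm on the complete observations
  obs <- !is.na(d2[, 2])
  fit <- summary(lm(y[obs] ~ d2[obs, 2] + cov[obs, 1] + cov[obs, 2]))$coefficients
  expect_equal(a$beta[a$snp == "s2"], fit[2, 1], tolerance = 1e-10)
  expect_equal(a$se[a$snp == "s2"], fit[2, 2], tolerance = 1e-10)
  expect_equal(a$n[a$snp == "s2"], 99)
  # fast path agrees with lm too
  fit1 <- summary(lm(y ~ d[, 1] + cov))$coefficients
  expect_equal(a$beta[a$snp == "s1"], fit1[2, 1], tolerance = 1e-10)
  expect_equal(a$p[a$snp == "s1"], fit1[2, 4], tolerance = 1e-10)
})

test_that("zero-variance SNPs are skipped with a log entry", {
  d <- cbind(rep(1L, 20), rbinom(20, 2, 0.5))
  a <- run_gwas(make_geno(d), rnorm(20))
  expect_identical(attr(a, "skipped"), "s1")
  expect_identical(nrow(a), 1L)
})

test_that("location shifts of the phenotype do not change the scan", {
  d <- withr::with_seed(7, matrix(rbinom(600, 2, 0.3), nrow = 60))
  y <- withr::with_seed(8, rnorm(60))
  a1 <- run_gwas(make_geno(d), y)
  a2 <- run_gwas(make_geno(d), y + 100)
  expect_equal(a1$beta, a2$beta, tolerance = 1e-10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
})

test_that("null scan is calibrated: type-I rate, lambda, uniformity", {
  cfg <- tiny_config(n_individuals = 2000L, n_chromosomes = 5L,
                     snps_per_chromosome = 1000L, within_block_rho = 0,
                     seed = 101L)
  g <- simulate_genotypes(cfg)
  ph <- derive_general_factor(simulate_phenotypes(g, cfg))
  a <- run_gwas(g, ph$g, covariates = genotype_pcs(g, 4))
  expect_true(abs(mean(a$p < 0.05) - 0.05) < 0.01)
  lam <- inflation_lambda(a$p)
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
})

test_that("single-marker p-values are uniform under the null across seeds", {
  ks_p <- vapply(1:10, function(s) {
    cfg <- tiny_config(n_individuals = 400L, n_chromosomes = 2L,
                       snps_per_chromosome = 400L, within_block_rho = 0.3,
                       seed = 200L + s)
    g <- simulate_genotypes(cfg)
    ph <- derive_general_factor(simulate_phenotypes(g, cfg))
    a <- run_gwas(g, ph$g)
    suppressWarnings(stats::ks.test(a$p, "punif")$p.value)
  }, numeric(1))
  expect_gte(sum(ks_p > 0.01), 9L)
})

test_that("Bonferroni thresholds reproduce the printed alpha levels", {
  expect_equal(bonferroni_alpha(6956), 7.188039e-06, tolerance = 1e-7)
  expect_equal(bonferroni_alpha(40), 0.00125)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_error(bonferroni_alpha(0), "integer")
})

test_that("qq_data pairs sorted observed quantiles with uniform expectations", {
  p <- c(0.5, 0.1, 0.9, 0.3)
  qq <- qq_data(p)
  expect_equal(qq$observed, -log10(sort(p)))
  expect_equal(qq$expected, -log10((1:4 - 0.5) / 4))
})
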