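# Box-Cox transformation and lambda selection, the Gaussian IRLS fitter
# against independent oracles, and the gene-trait scan.

test_that("Box-Cox transform matches its closed form", {
  expect_equal(boxcoxTransform(5, 1), 4)
  expect_equal(boxcoxTransform(exp(1), 0), 1)
  expect_equal(boxcoxTransform(3, 2), 4)
  expect_equal(boxcoxTransform(c(1, 4), 0.5), c(0, 2))
  expect_error(boxcoxTransform(c(2, -1, 3), 1), "positive")
  expect_error(boxcoxTransform(c(2, 0), 0), "positive")
})

test_that("transform is continuous at lambda = 0 and monotone in y", {
  y <- c(0.2, 1, 3, 10, 100)
  expect_equal(boxcoxTransform(y, 1e-6), log(y), tolerance = 1e-4)
  expect_equal(boxcoxTransform(y, -1e-6), log(y), tolerance = 1e-4)
  for (lam in seq(-2, 2, by = 0.5)) {
    z <- boxcoxTransform(sort(y), lam)
    expect_true(all(diff(z) > 0), info = paste("lambda =", lam))
  }
})

test_that("the default lambda grid spans [-2, 2] in nine steps", {
  set.seed(1)
  X <- cbind(sex = rbinom(50, 1, 0.5), age = rnorm(50, 50, 10))
  y <- exp(rnorm(50, 4, 0.3))
  sel <- selectLambda(y, X)
  expect_equal(sel$grid, seq(-2, 2, by = 0.5))
  expect_length(sel$logLik, 9L)
  expect_equal(sel$logLik[sel$grid == sel$lambda], max(sel$logLik))
})

test_that("profile log-likelihood agrees with the MASS::boxcox oracle", {
  set.seed(2)
  n <- 300
  x <- rnorm(n)
  y <- exp(1 + 0.3 * x + rnorm(n, 0, 0.4))
  grid <- seq(-2, 2, by = 0.5)
  sel <- selectLambda(y, cbind(x = x), grid = grid)
  d <- data.frame(x = x, y = y)
  or <- MASS::boxcox(y ~ x, data = d, lambda = grid, plotit = FALSE)
  # same curve up to an additive constant, hence the same argmax
  expect_equal(grid[which.max(or$y)], sel$lambda)
  d <- sel$logLik - or$y
  expect_lt(diff(range(d)), 1e-6)
})

test_that("IRLS equals the normal-equations solution on random designs", {
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(20:60, 1)
    p <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    fit <- fitIRLS(y, X)
    expect_equal(unname(fit$coefficients), normalEquations(y, X),
                 tolerance = 1e-8)
  }
})

test_that("IRLS matches stats::glm coefficients, SEs and p-values", {
  set.seed(4)
  n <- 200
  d <- data.frame(g = rbinom(n, 1, 0.05), sex = rbinom(n, 1, 0.5),
                  age = rnorm(n, 50, 10))
  d$y <- 2 - 3 * d$g + 0.5 * d$sex + 0.1 * d$age + rnorm(n)
  X <- cbind(`(Intercept)` = 1, g = d$g, sex = d$sex, age = d$age)
  fit <- fitIRLS(d$y, X)
  gfit <- stats::glm(y ~ g + sex + age, data = d, family = gaussian())
  sm <- summary(gfit)$coefficients
  expect_equal(unname(fit$coefficients), unname(sm[, "Estimate"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sm[, "Std. Error"]),
               tolerance = 1e-10)
  # glm reports z-like t with dispersion df; compare via lm's t test
  lsm <- summary(stats::lm(y ~ g + sex + age, data = d))$coefficients
  expect_equal(unname(fit$pvalue), unname(lsm[, "Pr(>|t|)"]),
               tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- cbind(`(Intercept)` = 1, gene = 0, age = rnorm(30))
  expect_error(fitIRLS(rnorm(30), X), "gene")
  X2 <- cbind(`(Intercept)` = 1, a = 1:30, b = 2 * (1:30))
  expect_error(fitIRLS(rnorm(30), X2), "rank deficient")
})

test_that("a planted carrier effect is recovered within 3 SE", {
  set.seed(5)
  n <- 2000
  g <- c(rep(1, 30), rep(0, n - 30))
  X <- cbind(`(Intercept)` = 1, gene = g, sex = rbinom(n, 1, 0.5),
             age = rnorm(n, 50, 10))
  y <- 100 - 20 * g + 0.1 * X[, "age"] + rnorm(n, 0, 10)
  fit <- fitIRLS(y, X)
  expect_lt(abs(fit$coefficients["gene"] + 20), 3 * fit$se["gene"])
})

test_that("lambda selection recovers the generative transform", {
  # data generated on the transformed scale and inverted at known lambda
  set.seed(6)
  n <- 2000
  for (lam in c(0, 1)) {
    hits <- 0L
    for (rep in 1:10) {
      X <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
      z <- 5 + 0.3 * X[, "sex"] + 0.2 * X[, "age"] + rnorm(n, 0, 0.8)
      y <- if (lam == 0) exp(z) else (lam * z + 1)^(1 / lam)
      sel <- selectLambda(y, X)
      hits <- hits + (sel$lambda == lam)
    }
    expect_gte(hits, 9L)
  }
})

test_that("gene scan enforces the minimum-carrier rule", {
  sim <- simulateStudy(smallConfig(seed = 30))
  cfg <- simConfigOf(sim)
  qc <- traitQC(sim@measurements, sim@medications, cfg@traits,
                cfg@medicationEffects)
  hc <- hardCallGenotypes(sim@genotypes$carrier, sim@genotypes$probability)
  gcs <- collapseToGenes(sim@variants[, c("variant_key", "gene_id")],
                         hc$carrier, sim@cohort$subject_id)
  scan <- runGeneTraitScan(gcs, qc, sim@cohort)
  expect_true(all(scan$associations$n_carriers >= 3L))
  # a two-carrier gene must not appear
  few <- names(Filter(function(x) length(x) < 3, gcs@carriersByGene))
  expect_false(any(scan$associations$gene %in% few))
  expect_true(all(scan$associations$p_value > 0 &
                    scan$associations$p_value <= 1))
})

test_that("gene p-value is invariant to affine covariate rescaling", {
  sim <- simulateStudy(smallConfig(seed = 31))
  cfg <- simConfigOf(sim)
  qc <- traitQC(sim@measurements, sim@medications, cfg@traits,
                cfg@medicationEffects)
  hc <- hardCallGenotypes(sim@genotypes$carrier, sim@genotypes$probability)
  gcs <- collapseToGenes(sim@variants[, c("variant_key", "gene_id")],
                         hc$carrier, sim@cohort$subject_id)
  cov2 <- sim@cohort
  cov2$age <- (cov2$age - 50) / 10
  cov2$PC1 <- 100 * cov2$PC1 + 5
  s1 <- runGeneTraitScan(gcs, qc, sim@cohort)
  s2 <- runGeneTraitScan(gcs, qc, cov2)
  expect_equal(s1$associations$p_value, s2$associations$p_value,
               tolerance = 1e-8)
})

test_that("null gene p-values are approximately uniform", {
  set.seed(8)
  n <- 400
  X0 <- cbind(`(Intercept)` = 1, sex = rbinom(n, 1, 0.5), age = rnorm(n))
  ps <- vapply(1:200, function(i) {
    g <- as.numeric(seq_len(n) %in% sample.int(n, 8))
    y <- 1 + 0.2 * X0[, "sex"] + rnorm(n)
    fit <- fitIRLS(y, cbind(X0[, 1, drop = FALSE], gene = g,
                            X0[, -1, drop = FALSE]))
    unname(fit$pvalue["gene"])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
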