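random_beta <- function(n_cpg, n_s, seed = 1) {
  set.seed(seed)
  matrix(runif(n_cpg * n_s), n_cpg, n_s,
         dimnames = list(sprintf("cg%04d", seq_len(n_cpg)),
                         sprintf("S%03d", seq_len(n_s))))
}

test_that("scaled PCA reproduces a reference eigendecomposition", {
  beta <- random_beta(50, 20, seed = 101)
  res <- pca_scaled(beta)
  # oracle: eigendecomposition of the covariance of the scaled data
  xs <- t(scale(t(beta)))  # CpGs centred/scaled
  m <- t(xs)
  ev <- eigen(crossprod(m), symmetric = TRUE)
  k <- ncol(res$scores)
  for (j in 1:10) {
    sc_oracle <- m %*% ev$vectors[, j]
    # compare up to sign
    d <- min(sum((res$scores[, j] - sc_oracle)^2),
             sum((res$scores[, j] + sc_oracle)^2))
    expect_lt(d, 1e-8)
  }
  expect_equal(res$variance_fraction,
               ev$values[seq_len(k)] / sum(pmax(ev$values, 0)),
               tolerance = 1e-8)
  # variance fractions nonincreasing and sum to 1 over all components
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  # orthogonal scores (Gram matrix diagonal)
  g <- crossprod(res$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6)
})

test_that("PCA handles two samples and rank-1 structure", {
  beta <- random_beta(30, 2, seed = 5)
  res <- pca_scaled(beta)
  expect_equal(res$variance_fraction[1], 1.0, tolerance = 1e-10)
  # rank-1 outer product
  set.seed(6)
  u <- runif(40); v <- rnorm(12)
  b1 <- outer(u, v)
  b1 <- (b1 - min(b1)) / diff(range(b1))
  dimnames(b1) <- list(sprintf("cg%02d", 1:40), sprintf("S%02d", 1:12))
  r1 <- pca_scaled(b1)
  expect_equal(r1$variance_fraction[1], 1.0, tolerance = 1e-10)
})

test_that("PCA sign convention and standardized scores are deterministic", {
  beta <- random_beta(30, 10, seed = 7)
  r1 <- pca_scaled(beta)
  r2 <- pca_scaled(beta)
  expect_identical(r1$scores, r2$scores)
  for (j in 1:5) {
    expect_gt(r1$loadings[which.max(abs(r1$loadings[, j])), j], 0)
  }
  informative <- which(r1$variance_fraction > 1e-12)
  expect_equal(unname(colMeans(r1$standardized_scores[, informative])),
               rep(0, length(informative)), tolerance = 1e-12)
  expect_equal(unname(apply(r1$standardized_scores[, informative], 2, sd)),
               rep(1, length(informative)), tolerance = 1e-12)
})

test_that("PC-variable associations recover R^2 and match point-biserial", {
  beta <- random_beta(40, 30, seed = 8)
  res <- pca_scaled(beta)
  samples <- data.frame(sample_id = colnames(beta),
                        self = res$scores[, 1],
                        grp = rep(c("a", "b"), 15),
                        konst = 1)
  assoc <- suppressMessages(
    pc_association(res, samples, c("self", "grp", "konst"),
                   n_components = 3))
  expect_equal(assoc$r_squared[assoc$variable == "self" &
                                 assoc$component == 1], 1.0,
               tolerance = 1e-12)
  # two-level factor R^2 equals squared point-biserial correlation
  pb <- cor(res$scores[, 2], as.numeric(factor(samples$grp)))^2
  expect_equal(assoc$r_squared[assoc$variable == "grp" &
                                 assoc$component == 2], pb,
               tolerance = 1e-12)
  expect_true("konst" %in% attr(assoc, "skipped"))
})

test_that("null PC associations are controlled at the FDR level", {
  set.seed(9)
  hits <- 0L; tests <- 0L
  for (rep in 1:30) {
    beta <- random_beta(30, 40, seed = 1000 + rep)
    res <- pca_scaled(beta)
    samples <- data.frame(sample_id = colnames(beta),
                          noise = rnorm(40))
    assoc <- pc_association(res, samples, "noise", n_components = 5)
    hits <- hits + sum(assoc$significant)
    tests <- tests + nrow(assoc)
  }
  expect_lte(hits / tests, 0.05)
})

test_that("PC-PR2 equals direct per-component partial R^2 regressions", {
  set.seed(10)
  n <- 20; p <- 50
  cov1 <- rnorm(n); cov2 <- runif(n)
  beta <- random_beta(p, n, seed = 11)
  covs <- data.frame(c1 = cov1, c2 = cov2)
  res <- pcpr2(beta, covs, variance_threshold = 0.9)
  # oracle: redo the decomposition and regressions from scratch
  xs <- t(scale(t(beta)))
  sv <- svd(t(xs))
  lambda <- sv$d^2
  q <- which(cumsum(lambda / sum(lambda)) >= 0.9)[1]
  pr2 <- matrix(NA_real_, q, 2)
  for (j in seq_len(q)) {
    y <- sv$u[, j] * sv$d[j]
    rss_full <- sum(resid(lm(y ~ cov1 + cov2))^2)
    pr2[j, 1] <- (sum(resid(lm(y ~ cov2))^2) - rss_full) /
      sum(resid(lm(y ~ cov2))^2)
    pr2[j, 2] <- (sum(resid(lm(y ~ cov1))^2) - rss_full) /
      sum(resid(lm(y ~ cov1))^2)
  }
  w <- lambda[1:q] / sum(lambda[1:q])
  want <- 100 * colSums(pr2 * w)
  expect_equal(unname(res$partial_r2_pct), unname(want), tolerance = 1e-8)
  expect_equal(res$n_components_used, q)
})

test_that("PC-PR2 attributes structure to the generating covariate", {
  set.seed(12)
  n <- 24
  driver <- rnorm(n)
  noisecov <- rnorm(n)
  beta <- matrix(0, 60, n, dimnames = list(sprintf("cg%02d", 1:60),
                                           sprintf("S%02d", 1:n)))
  for (i in 1:60) beta[i, ] <- 0.5 + 0.08 * runif(1, 0.5, 1) * driver +
    rnorm(n, 0, 0.01)
  beta <- pmin(pmax(beta, 0), 1)
  res <- pcpr2(beta, data.frame(driver = driver, noisecov = noisecov))
  expect_gt(res$partial_r2_pct["driver"], 10 * res$partial_r2_pct["noisecov"])
  expect_lt(res$partial_r2_pct["noisecov"], 5)
  # invariance to affine rescaling of a covariate
  res2 <- pcpr2(beta, data.frame(driver = 10 * driver + 3,
                                 noisecov = noisecov))
  expect_equal(res$partial_r2_pct, res2$partial_r2_pct, tolerance = 1e-8)
  # threshold 1.0 uses all informative components (CpG-centred data has
  # rank n - 1; the last eigenvalue is numerically zero)
  res3 <- pcpr2(beta, data.frame(driver = driver, noisecov = noisecov),
                variance_threshold = 1.0)
  expect_gte(res3$n_components_used, n - 1L)
  # collinear covariates are rejected with the pair named
  expect_error(pcpr2(beta, data.frame(a = driver, b = 2 * driver)),
               "collinear")
})

test_that("per-CpG linear models recover slopes and respect the gate", {
  set.seed(13)
  n <- 50
  ga <- runif(n, 8, 42)
  samples <- data.frame(sample_id = sprintf("S%03d", 1:n),
                        gestational_age = ga)
  # parameter recovery: slope 0.01 per week, tiny noise
  beta <- matrix(NA_real_, 20, n,
                 dimnames = list(sprintf("cg%02d", 1:20), samples$sample_id))
  for (i in 1:20) beta[i, ] <- 0.2 + 0.01 * ga + rnorm(n, 0, 0.001)
  fit <- cpg_linear_model(beta, samples)
  expect_true(all(abs(fit$slope - 0.01) < 0.002))
  # constant beta: slope 0
  bc <- matrix(0.4, 5, n, dimnames = list(paste0("k", 1:5),
                                          samples$sample_id))
  fc <- cpg_linear_model(bc, samples)
  expect_equal(fc$slope, rep(0, 5), tolerance = 1e-14)
  # missing values: complete-case fit equals lm on the same rows
  bm <- beta
  bm[1, 1:5] <- NA
  fm <- cpg_linear_model(bm, samples)
  ref <- lm(bm[1, -(1:5)] ~ ga[-(1:5)])
  expect_equal(fm$slope[1], unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fm$p_value[1], summary(ref)$coefficients[2, 4],
               tolerance = 1e-10)
  # fast path agrees with lm per CpG
  ref2 <- lm(beta[2, ] ~ ga)
  expect_equal(fit$slope[2], unname(coef(ref2)[2]), tolerance = 1e-10)
  expect_equal(fit$p_value[2], summary(ref2)$coefficients[2, 4],
               tolerance = 1e-10)
  # rank-deficient adjustment is rejected with the aliased column named
  samples$dup <- samples$gestational_age
  expect_error(cpg_linear_model(beta, samples, adjustment = "dup"),
               "aliased")
})

test_that("slope estimates are unbiased on synthetic data", {
  set.seed(14)
  n <- 100; true_slope <- 0.005
  ga <- runif(n, 8, 42)
  samples <- data.frame(sample_id = sprintf("S%03d", 1:n),
                        gestational_age = ga)
  est <- replicate(100, {
    b <- matrix(0.3 + true_slope * ga + rnorm(n, 0, 0.02), 1, n,
                dimnames = list("cg1", samples$sample_id))
    cpg_linear_model(b, samples)$slope
  })
  expect_lt(abs(mean(est) - true_slope), 0.1 * true_slope)
})

test_that("group comparison matches exact enumeration and maps stars", {
  a <- c(1.2, 3.4, 5.6)
  b <- c(2.1, 7.7, 9.9)
  res <- group_compare(c(a, b), rep(c("ref", "g1"), each = 3), "ref")
  expect_equal(res$p_value, oracle_ranksum_exact_p(a, b), tolerance = 1e-12)
  # strongly shifted groups reach four stars
  set.seed(15)
  v1 <- rnorm(12, 0.5, 0.02); v2 <- rnorm(12, 0.6, 0.02)
  res2 <- group_compare(c(v1, v2), rep(c("ref", "g1"), each = 12), "ref")
  expect_lt(res2$fdr, 1e-4)
  expect_equal(res2$stars, "****")
  # null: identical distributions rarely significant
  pvals <- replicate(50, {
    v <- rnorm(24)
    group_compare(v, rep(c("ref", "g1"), each = 12), "ref")$p_value
  })
  expect_gte(mean(pvals >= 0.05), 0.9)
  # singleton groups skipped with a note; remaining groups still tested
  expect_message(
    res3 <- group_compare(c(1, 2, 3, 4, 5, 6, 9),
                          c("ref", "ref", "ref", "g1", "g1", "g1", "g2"),
                          "ref"), "skipped")
  expect_equal(res3$group, "g1")
  expect_equal(attr(res3, "skipped"), "g2")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(16)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # monotone: sorted inputs give sorted outputs
    expect_true(all(diff(bh_fdr(sort(p))) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
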