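test_that("qc_genotypes removes low-MAF and low-call-rate markers", {
  dos <- cbind(
    common = c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1),
    rare   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),  # MAF 0.05 >= 0.01: kept
    mono   = rep(0, 10),                        # MAF 0: removed
    holey  = c(NA, NA, 1, 1, 0, 2, 1, 0, 1, 2)  # call rate 0.8: removed
  )
  G <- make_genotypes(dos)
  Gq <- qc_genotypes(G, maf_min = 0.01, call_rate_min = 0.95)
  expect_setequal(colnames(Gq$dosages), c("common", "rare"))
  rep <- attr(Gq, "qc_report")
  expect_equal(rep$n_kept, 2L)
  expect_equal(rep$removed_maf, 1L)
  expect_equal(rep$removed_call_rate, 1L)
})

test_that("impute_dosages fills missing entries with the marker mean", {
  dos <- cbind(a = c(0, 2, NA, 2), b = c(1, 1, 1, NA))
  out <- pleionet:::impute_dosages(dos)
  expect_equal(unname(out[3, "a"]), mean(c(0, 2, 2)))
  expect_equal(unname(out[4, "b"]), 1)
  expect_false(anyNA(out))
})

test_that("compute_grm matches the hand-computed standardized form", {
  dos <- cbind(m1 = c(0, 1, 2, 1), m2 = c(2, 2, 1, 1))
  G <- make_genotypes(dos)
  A <- compute_grm(G)
  p <- colMeans(dos) / 2
  W <- sweep(dos, 2, 2 * p)
  expected <- matrix(0, 4, 4)
  for (j in 1:2) {
    expected <- expected + tcrossprod(W[, j]) / (2 * p[j] * (1 - p[j]))
  }
  expected <- expected / 2
  expect_equal(unname(A), unname(expected))
  expect_true(isSymmetric(A))
})

test_that("reml_mixed recovers a planted heritability", {
  set.seed(31)
  n <- 300
  Z <- matrix(rnorm(n * 100), n, 100)
  K <- tcrossprod(Z) / 100
  K <- K / mean(diag(K))
  sg2 <- 2; se2 <- 2  # h2 = 0.5
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0))) %*% t(ek$vectors)
  y <- drop(L %*% rnorm(n)) * sqrt(sg2) + rnorm(n, sd = sqrt(se2))
  fit <- pleionet:::reml_mixed(y, matrix(1, n, 1), K)
  h2 <- fit$lambda / (fit$lambda + 1)
  expect_lt(abs(h2 - 0.5), 0.15)
})

test_that("mlma_loco reduces to OLS when the GRM is diagonal", {
  dos <- cbind(m1 = c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2))
  y <- 0.5 * dos[, 1] + c(0.01, -0.02, 0.03, 0, -0.01, 0.02, -0.03, 0.01, 0, -0.01)
  G <- make_genotypes(dos)
  panel <- pleionet:::new_trait_panel(
    matrix(y, ncol = 1, dimnames = list(rownames(G$dosages), "y")))
  st <- mlma_loco(G, panel, grm = diag(10))
  ols <- lm(y ~ dos[, 1])
  expect_equal(unname(st$beta[1, 1]), unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(unname(st$se[1, 1]), unname(summary(ols)$coef[2, 2]),
               tolerance = 1e-8)
})

test_that("mlma_loco matches the full-matrix GLS oracle under kinship", {
  set.seed(2)
  n <- 80
  Z <- matrix(rnorm(n * 30), n, 30)
  K <- tcrossprod(Z) / 30
  K <- K / mean(diag(K))
  dos <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
                dimnames = list(paste0("s", 1:n), paste0("m", 1:5)))
  ek <- eigen(K + diag(n) * 0.5, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0))) %*% t(ek$vectors)
  y <- drop(L %*% rnorm(n)) + 0.4 * dos[, 3]
  G <- make_genotypes(dos)
  panel <- pleionet:::new_trait_panel(
    matrix(y, ncol = 1, dimnames = list(paste0("s", 1:n), "y")))
  st <- suppressWarnings(mlma_loco(G, panel, grm = K))
  fit <- pleionet:::reml_mixed(y, matrix(1, n, 1), K)
  Vi <- solve(fit$lambda * K + diag(n))
  for (j in 1:5) {
    X <- cbind(1, dos[, j])
    XtVi <- t(X) %*% Vi
    cf <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% cf
    s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
    seb <- sqrt(s2 * solve(XtVi %*% X)[2, 2])
    expect_equal(unname(st$beta[j, 1]), unname(cf[2]), tolerance = 1e-6)
    expect_equal(unname(st$se[j, 1]), unname(seb), tolerance = 1e-6)
  }
})

test_that("LOCO excludes the test chromosome from the GRM", {
  b <- small_bundle()
  G <- qc_genotypes(b$genotypes)
  st <- mlma_loco(G, b$panel)
  expect_s3_class(st, "marker_stats")
  expect_equal(dim(st$t), c(ncol(G$dosages), 3))
  expect_true(all(st$p >= 0 & st$p <= 1, na.rm = TRUE))
})

test_that("trait_correlation_matrix is a valid correlation matrix", {
  b <- small_bundle()
  G <- qc_genotypes(b$genotypes)
  st <- mlma_loco(G, b$panel)
  V <- trait_correlation_matrix(st)
  expect_true(isSymmetric(V))
  expect_equal(unname(diag(V)), rep(1, 3))
  expect_true(all(eigen(V, only.values = TRUE)$values > 0))
})

test_that("pleiotropy chi-square equals the sum of squared t when V = I", {
  b <- small_bundle()
  G <- qc_genotypes(b$genotypes)
  st <- mlma_loco(G, b$panel)
  V <- diag(3)
  dimnames(V) <- list(st$traits, st$traits)
  pl <- pleiotropy_statistic(st, V)
  complete <- rowSums(!is.finite(st$t)) == 0
  expect_equal(pl$chi2, unname(rowSums(st$t[complete, ]^2)))
  expect_equal(pl$df[1], 3)
  expect_equal(pl$p, pchisq(pl$chi2, 3, lower.tail = FALSE))
})

test_that("adjust_phenotype removes a covariate effect", {
  set.seed(8)
  n <- 100
  K <- diag(n)
  sex <- rep(0:1, length.out = n)
  y <- 2 * sex + rnorm(n)
  adj <- adjust_phenotype(y, covariates = cbind(sex = sex), grm = K)
  expect_lt(abs(cor(as.numeric(adj), sex)), 0.1)
})
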