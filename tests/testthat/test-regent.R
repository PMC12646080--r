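test_that("shared percentage follows the union convention", {
  out <- shared_stats_counts(153, 149, 38)
  expect_equal(out$shared_pct, 14.4)
  expect_equal(out$n_shared, 38)
  s <- shared_stats(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(s$n_shared, 2)
  expect_equal(s$shared_pct, 50)
  expect_error(shared_stats_counts(3, 3, 5), "exceeds")
})

test_that("null mixture EM recovers planted parameters", {
  set.seed(40)
  n <- 5000
  z <- rbinom(n, 1, 0.3)
  p <- ifelse(z == 1, rbeta(n, 0.15, 1), runif(n))
  fit <- fit_null_mixture(p)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - 0.3), 0.05)
  expect_lt(abs(fit$a - 0.15), 0.05)
  expect_true(all(diff(fit$loglik) >= -1e-8))
})

test_that("soft-label LDA recovers a planted discriminant direction", {
  set.seed(17)
  n <- 200
  z <- rbinom(n, 1, 0.5)
  x <- cbind(z * 2 + rnorm(n), rnorm(n), rnorm(n))
  rownames(x) <- paste0("g", 1:n)
  # soft labels: noisy truth
  w <- pmin(pmax(z * 0.8 + 0.1 + rnorm(n, sd = 0.02), 0), 1)
  f <- lda_reduce(x, w)
  expect_equal(names(f), rownames(x))
  # the feature separates the classes and is oriented upward for class 1
  expect_gt(mean(f[z == 1]) - mean(f[z == 0]), 0)
  expect_gt(pleionet:::auc_rank(f, z), 0.85)
  d <- attr(f, "direction")
  expect_gt(abs(d[1]) / sqrt(sum(d^2)), 0.8)
})

test_that("assemble_features z-scores and zero-fills missing genes", {
  r1 <- setNames(c(1, 2, 3), c("a", "b", "c"))
  r2 <- setNames(c(5, 9), c("a", "b"))
  X <- assemble_features(list(n1 = r1, n2 = r2), c("a", "b", "c", "d"))
  expect_equal(dim(X), c(4L, 2L))
  expect_equal(unname(X["d", ]), c(0, 0))
  expect_equal(mean(X[c("a", "b", "c"), "n1"]), 0)
  expect_equal(sd(X[c("a", "b", "c"), "n1"]), 1)
  expect_equal(unname(X["c", "n2"]), 0)
})

test_that("hierarchical EM log-likelihood never decreases", {
  set.seed(23)
  n <- 800
  z <- rbinom(n, 1, 0.15)
  p <- ifelse(z == 1, rbeta(n, 0.25, 1), runif(n))
  x <- matrix(z + rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
  fit <- em_hierarchical(p, x)
  expect_s3_class(fit, "ppa_fit")
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_true(fit$converged)
})

test_that("a covariate-free hierarchical fit nests the null mixture", {
  set.seed(29)
  n <- 600
  p <- ifelse(rbinom(n, 1, 0.12) == 1, rbeta(n, 0.2, 1), runif(n))
  x0 <- matrix(1, n, 1, dimnames = list(NULL, "const"))  # zero variance
  fit <- suppressWarnings(em_hierarchical(p, x0))
  nul <- fit_null_mixture(p)
  expect_lt(abs(fit$a - nul$a), 0.01)
  expect_lt(abs(plogis(fit$beta0) - nul$pi), 0.01)
  expect_equal(unname(fit$beta["const"]), 0)
})

test_that("an informative feature earns a positive coefficient and lifts AUC", {
  set.seed(37)
  n <- 1500
  z <- rbinom(n, 1, 0.1)
  p <- ifelse(z == 1, rbeta(n, 0.2, 1), runif(n))
  x <- matrix(z + rnorm(n), ncol = 1, dimnames = list(NULL, "net"))
  fit <- em_hierarchical(p, x)
  expect_gt(unname(fit$beta["net"]), 0)
  nul <- fit_null_mixture(p)
  expect_gte(pleionet:::auc_rank(fit$ppa, z),
             pleionet:::auc_rank(nul$ppa, z) - 0.005)
})

test_that("ppa_fit S3 surface behaves like a classic fitted model", {
  set.seed(41)
  n <- 300
  p <- ifelse(rbinom(n, 1, 0.2) == 1, rbeta(n, 0.3, 1), runif(n))
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(paste0("g", 1:n), "f"))
  fit <- em_hierarchical(setNames(p, paste0("g", 1:n)), x)
  expect_output(print(fit), "Hierarchical PPA model")
  cf <- coef(fit)
  expect_true(all(c("(Intercept)", "f", "a") %in% names(cf)))
  expect_equal(fitted(fit), fit$ppa)
  expect_named(fitted(fit))
})

test_that("prioritize keeps the top fraction with deterministic ties", {
  p <- setNames(c(0.001, 0.002, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.2, 0.3),
                paste0("g", 1:10))
  x <- matrix(rnorm(10), ncol = 1, dimnames = list(names(p), "f"))
  fit <- suppressWarnings(em_hierarchical(
    c(p, setNames(runif(90), paste0("h", 1:90))),
    rbind(x, matrix(rnorm(90), ncol = 1,
                    dimnames = list(paste0("h", 1:90), "f")))))
  scores <- structure(
    data.frame(gene = names(fit$ppa), p = unname(fit$p),
               stringsAsFactors = FALSE),
    class = c("gene_score_table", "data.frame"))
  out <- prioritize(fit, scores, top_frac = 0.05, alpha = 0.05)
  expect_equal(length(out$prioritized), 5L)  # ceiling(0.05 * 100)
  expect_true(all(out$prioritized_significant %in% out$prioritized))
  sig <- setNames(out$table$significant, out$table$gene)
  expect_true(all(sig[out$prioritized_significant]))
  # the retained set is exactly the top-5 rows of the sorted table
  expect_equal(sort(out$table$gene[1:5]), sort(out$prioritized))
  # BH flag is never more liberal than nominal
  out_bh <- prioritize(fit, scores, top_frac = 0.05, method = "BH")
  expect_lte(sum(out_bh$table$significant), sum(out$table$significant))
})
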