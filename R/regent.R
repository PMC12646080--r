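## Representation learning and the hierarchical mixture model: soft labels
## from a null Beta/Uniform mixture, soft-label LDA reduction of node
## embeddings to one feature per network, and an EM-fitted hierarchical model
## whose E-step posterior is the per-gene posterior probability of
## association (PPA).

mixture_density <- function(p, a) a * p^(a - 1)

#' Fit the null two-component p-value mixture
#'
#' `pi * Beta(a, 1) + (1 - pi) * Uniform(0, 1)` fitted by EM without
#' covariates. The per-gene posterior of membership in the Beta component is
#' the initial PPA ("soft label") used by the representation-learning stage.
#'
#' @param p gene-level p-values in (0, 1]; values of 0 are floored at 1e-300.
#' @param max_iter maximal EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return list: `pi` (mixing weight, clamped to `[1e-6, 1 - 1e-6]`), `a`
#'   (Beta shape in (0, 1]), `ppa` (per-gene posterior), `loglik` (trace),
#'   `converged`, `iterations`.
#' @export
fit_null_mixture <- function(p, max_iter = 1000, tol = 1e-8) {
  assert_that(length(p) >= 50, "need at least 50 p-values")
  assert_that(all(p <= 1) && all(p >= 0), "p-values must lie in [0, 1]")
  if (any(p <= 0)) {
    warning("p-value(s) of 0 floored at 1e-300")
    p <- pmax(p, 1e-300)
  }
  pi_ <- 0.1; a <- 0.5
  lp <- log(p)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- mixture_density(p, a)
    num <- pi_ * f1
    w <- num / (num + (1 - pi_))
    ll <- sum(log(num + (1 - pi_)))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
        tol * (abs(ll_trace[it - 1]) + 1)) {
      converged <- TRUE
      break
    }
    pi_ <- min(max(mean(w), 1e-6), 1 - 1e-6)
    sw <- sum(w)
    a <- if (sw > 0) sw / (-sum(w * lp)) else a
    a <- min(max(a, 1e-3), 1)
  }
  if (!converged) {
    stop("null mixture EM did not converge in ", max_iter,
         " iterations; last log-likelihoods: ",
         paste(round(tail(ll_trace, 3), 4), collapse = ", "))
  }
  f1 <- mixture_density(p, a)
  ppa <- pi_ * f1 / (pi_ * f1 + (1 - pi_))
  list(pi = pi_, a = a, ppa = ppa, loglik = ll_trace,
       converged = converged, iterations = length(ll_trace))
}

#' Soft-label linear discriminant reduction
#'
#' Two-class LDA whose class memberships are the soft labels `w` (class 1)
#' and `1 - w` (class 0): class means and within/between scatter are computed
#' with those weights, and the leading discriminant direction
#' (the top eigenvector of `W^-1 B`, obtained in closed form for two classes
#' as `W^-1 (m1 - m0)` with a ridge-regularized `W`) projects the embedding
#' to one dimension. The sign is oriented so the high-label class mean maps
#' higher.
#'
#' @param embedding nodes x dims numeric matrix with rownames.
#' @param labels soft labels in `[0, 1]` aligned with the embedding rows.
#' @param ridge ridge added to the within-scatter diagonal.
#' @return named numeric vector (one feature per node) with the projection
#'   vector in the `direction` attribute.
#' @export
lda_reduce <- function(embedding, labels, ridge = 1e-6) {
  embedding <- as.matrix(embedding)
  assert_that(length(labels) == nrow(embedding),
              "labels must align with embedding rows")
  assert_that(all(labels >= 0 & labels <= 1), "labels must lie in [0, 1]")
  assert_that(var(labels) > 0, "all labels are equal")
  w <- labels
  n1 <- sum(w); n0 <- sum(1 - w)
  m1 <- colSums(embedding * w) / n1
  m0 <- colSums(embedding * (1 - w)) / n0
  dm <- m1 - m0
  if (sqrt(sum(dm^2)) < 1e-12) stop("identical class means: no discriminant")
  c1 <- sweep(embedding, 2, m1)
  c0 <- sweep(embedding, 2, m0)
  W <- crossprod(c1 * sqrt(w)) + crossprod(c0 * sqrt(1 - w))
  Wr <- W + diag(ridge, ncol(W))
  v <- tryCatch(solve(Wr, dm), error = function(e) {
    solve(W + diag(1e-3 * max(diag(W)), ncol(W)), dm)
  })
  v <- v / sqrt(sum(v^2))
  if (sum(dm * v) < 0) v <- -v
  feat <- drop(embedding %*% v)
  names(feat) <- rownames(embedding)
  attr(feat, "direction") <- v
  feat
}

#' Assemble the per-network feature matrix
#'
#' Each network's one-dimensional reduction becomes one column, centered and
#' unit-scaled over the genes present in that network; genes absent from a
#' network receive 0 in its column (the column mean) and are flagged in the
#' `missing` indicator attribute.
#'
#' @param reductions named list of named numeric vectors (per network).
#' @param gene_universe character vector of all genes to score.
#' @return genes x networks matrix with attribute `missing` (logical matrix).
#' @export
assemble_features <- function(reductions, gene_universe) {
  assert_that(length(reductions) >= 1, "need at least one network reduction")
  assert_that(length(gene_universe) > 0, "empty gene universe")
  X <- matrix(0, length(gene_universe), length(reductions),
              dimnames = list(gene_universe, names(reductions)))
  miss <- matrix(TRUE, length(gene_universe), length(reductions),
                 dimnames = dimnames(X))
  for (j in seq_along(reductions)) {
    r <- reductions[[j]]
    present <- intersect(names(r), gene_universe)
    if (length(present) == 0) next
    v <- r[present]
    s <- sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    X[present, j] <- z
    miss[present, j] <- FALSE
  }
  attr(X, "missing") <- miss
  X
}

hier_loglik <- function(p, eta, a) {
  pi_g <- stats::plogis(eta)
  sum(log(pi_g * mixture_density(p, a) + (1 - pi_g)))
}

#' Hierarchical EM model for the posterior probability of association
#'
#' Per gene, a latent association indicator `Z_g ~ Bernoulli(sigma(b0 +
#' b' x_g))` with network features `x_g`; `p_g | Z = 1 ~ Beta(a, 1)` and
#' `p_g | Z = 0 ~ Uniform(0, 1)`. The E-step posterior `P(Z_g = 1 | p, x)` is
#' the PPA; the M-step updates the Beta shape in closed form and the prior
#' coefficients by weighted logistic regression on the soft responsibilities,
#' with step-halving if a step ever lowers the observed-data log-likelihood.
#'
#' @param p gene-level p-values in (0, 1] (0 floored at 1e-300), named by
#'   gene when available.
#' @param features genes x networks feature matrix from
#'   [assemble_features()]; zero-variance columns are dropped from the prior
#'   regression (their coefficient is fixed at 0).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximal EM iterations.
#' @return object of class `ppa_fit`: shape `a`, prior coefficients `beta0`
#'   and `beta` (one per feature column), per-gene `ppa`, log-likelihood
#'   trace, `converged`, `iterations`.
#' @export
em_hierarchical <- function(p, features, tol = 1e-6, max_iter = 500) {
  features <- as.matrix(features)
  assert_that(length(p) == nrow(features),
              "p-values and features must align")
  genes <- names(p) %||% rownames(features) %||% as.character(seq_along(p))
  if (any(p <= 0)) {
    warning("p-value(s) of 0 floored at 1e-300")
    p <- pmax(p, 1e-300)
  }
  lp <- log(p)
  active <- apply(features, 2, function(x) var(x) > 0)
  Xa <- features[, active, drop = FALSE]
  ## initialize from the covariate-free null mixture
  init <- fit_null_mixture(p, max_iter = max_iter * 2, tol = 1e-8)
  a <- init$a
  beta0 <- stats::qlogis(min(max(init$pi, 1e-6), 1 - 1e-6))
  beta <- rep(0, ncol(Xa))
  eta <- rep(beta0, length(p)) + if (ncol(Xa)) drop(Xa %*% beta) else 0
  ll_trace <- hier_loglik(p, eta, a)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi_g <- stats::plogis(eta)
    f1 <- mixture_density(p, a)
    w <- pi_g * f1 / (pi_g * f1 + (1 - pi_g))
    w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
    ## closed-form Beta(a, 1) weighted MLE
    a_new <- min(max(sum(w) / (-sum(w * lp)), 1e-3), 1)
    ## weighted logistic regression on the soft responsibilities
    if (ncol(Xa)) {
      fit_glm <- suppressWarnings(
        glm(w ~ Xa, family = binomial())
      )
      coefs <- coef(fit_glm)
      beta0_new <- coefs[1]
      beta_new <- coefs[-1]
      beta_new[is.na(beta_new)] <- 0
    } else {
      mw <- min(max(mean(w), 1e-6), 1 - 1e-6)
      beta0_new <- stats::qlogis(mw)
      beta_new <- beta
    }
    ## step-halving guard: the observed-data log-likelihood must not drop
    step <- 1
    repeat {
      a_try <- a + step * (a_new - a)
      b0_try <- beta0 + step * (beta0_new - beta0)
      b_try <- beta + step * (beta_new - beta)
      eta_try <- rep(b0_try, length(p)) +
        if (ncol(Xa)) drop(Xa %*% b_try) else 0
      ll_try <- hier_loglik(p, eta_try, a_try)
      if (is.finite(ll_try) && ll_try >= ll_trace[length(ll_trace)] - 1e-10) break
      step <- step / 2
      if (step < 1e-6) {
        stop("EM step failed to increase the log-likelihood even after ",
             "step-halving; trace tail: ",
             paste(round(tail(ll_trace, 3), 4), collapse = ", "))
      }
    }
    a <- a_try; beta0 <- unname(b0_try); beta <- b_try; eta <- eta_try
    ll_trace <- c(ll_trace, ll_try)
    n_ll <- length(ll_trace)
    if (abs(ll_trace[n_ll] - ll_trace[n_ll - 1]) <=
        tol * (abs(ll_trace[n_ll - 1]) + 1)) {
      converged <- TRUE
      break
    }
  }
  pi_g <- stats::plogis(eta)
  f1 <- mixture_density(p, a)
  ppa <- pi_g * f1 / (pi_g * f1 + (1 - pi_g))
  beta_full <- setNames(rep(0, ncol(features)), colnames(features))
  beta_full[active] <- unname(beta)
  structure(list(a = a, beta0 = beta0, beta = beta_full,
                 ppa = setNames(ppa, genes), p = setNames(p, genes),
                 loglik = ll_trace, converged = converged,
                 iterations = length(ll_trace) - 1L,
                 n_genes = length(p), features = features),
            class = "ppa_fit")
}

#' @export
print.ppa_fit <- function(x, ...) {
  cat("Hierarchical PPA model\n")
  cat(sprintf("  genes: %d, features: %d\n", x$n_genes, length(x$beta)))
  cat(sprintf("  Beta shape a = %.4f\n", x$a))
  cat(sprintf("  prior intercept = %.4f (baseline prior %.4f)\n",
              x$beta0, stats::plogis(x$beta0)))
  cat(sprintf("  EM iterations: %d (%s), log-likelihood %.4f\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              tail(x$loglik, 1)))
  invisible(x)
}

#' @export
summary.ppa_fit <- function(object, ...) {
  print(object)
  cat("  feature coefficients:\n")
  print(round(object$beta, 4))
  cat("  PPA quantiles:\n")
  print(round(quantile(object$ppa, c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)), 4))
  invisible(object)
}

#' @export
coef.ppa_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta, a = object$a)
}

#' @export
fitted.ppa_fit <- function(object, ...) object$ppa

#' @export
plot.ppa_fit <- function(x, ...) {
  plot(seq_along(x$loglik) - 1, x$loglik, type = "b",
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "Hierarchical model EM trace", ...)
  invisible(x)
}

#' Prioritize candidate genes from a fitted PPA model
#'
#' Retains the top `ceiling(top_frac * N)` genes by PPA (ties broken by
#' smaller gene p-value, then gene id) and flags the subset that is also
#' significant at the gene level.
#'
#' @param fit a `ppa_fit`.
#' @param scores a `gene_score_table` over the same genes (source of the
#'   gene p-values for the significance flag).
#' @param top_frac fraction of genes retained.
#' @param alpha significance level for the gene-level flag.
#' @param method "nominal" compares p to alpha directly; "BH" applies
#'   Benjamini-Hochberg across genes first.
#' @return list: `table` (gene, ppa, p, prioritized, significant),
#'   `prioritized` (gene ids) and `prioritized_significant` (the
#'   intersection list).
#' @export
prioritize <- function(fit, scores, top_frac = 0.01, alpha = 0.05,
                       method = c("nominal", "BH")) {
  stopifnot(inherits(fit, "ppa_fit"))
  method <- match.arg(method)
  genes <- names(fit$ppa)
  assert_that(length(genes) > 0, "no genes in the fit")
  p <- setNames(scores$p, scores$gene)[genes]
  assert_that(!anyNA(p), "fit and score table gene universes differ")
  k <- ceiling(top_frac * length(genes))
  ord <- order(-fit$ppa, p, genes)
  top <- genes[ord[seq_len(k)]]
  sig_p <- if (method == "BH") p.adjust(p, "BH") else p
  significant <- sig_p <= alpha
  tab <- data.frame(
    gene = genes, ppa = unname(fit$ppa), p = unname(p),
    prioritized = genes %in% top,
    significant = unname(significant),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$ppa, tab$p, tab$gene), ]
  rownames(tab) <- NULL
  list(table = tab, prioritized = top,
       prioritized_significant = top[significant[top]])
}

#' Overlap summary of two gene lists
#'
#' Reports both set sizes, the intersection size, and the shared percentage
#' `100 * |A intersect B| / |A union B|` rounded to one decimal.
#'
#' @param list_a,list_b character vectors (or set sizes via
#'   [shared_stats_counts()]).
#' @return list: `n_a`, `n_b`, `n_shared`, `shared_pct`.
#' @export
shared_stats <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  shared <- length(intersect(a, b))
  shared_stats_counts(length(a), length(b), shared)
}

#' Overlap summary from counts
#'
#' @param n_a,n_b set sizes.
#' @param n_shared intersection size.
#' @return list: `n_a`, `n_b`, `n_shared`, `shared_pct` (percentage of the
#'   union, one decimal).
#' @export
shared_stats_counts <- function(n_a, n_b, n_shared) {
  assert_that(n_shared <= min(n_a, n_b), "intersection exceeds a set size")
  union_n <- n_a + n_b - n_shared
  pct <- if (union_n == 0) 0 else round(100 * n_shared / union_n, 1)
  list(n_a = n_a, n_b = n_b, n_shared = n_shared, shared_pct = pct)
}
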