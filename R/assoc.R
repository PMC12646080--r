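## Genotype QC, leave-one-chromosome-out mixed-model association and the
## multi-trait pleiotropy chi-square statistic.

#' Marker quality control
#'
#' Removes markers with minor allele frequency below `maf_min` or a call rate
#' below `call_rate_min`. Both boundaries are strict: a marker exactly at the
#' threshold is retained.
#'
#' @param G a `pleio_genotypes` object.
#' @param maf_min minimum minor allele frequency (strict `<` removes).
#' @param call_rate_min minimum fraction of non-missing calls (strict `<`).
#' @return filtered `pleio_genotypes` with a `qc_report` attribute giving the
#'   number of markers removed per filter.
#' @export
qc_genotypes <- function(G, maf_min = 0.01, call_rate_min = 0.95) {
  stopifnot(inherits(G, "pleio_genotypes"))
  assert_that(ncol(G$dosages) > 0, "no markers to filter")
  dos <- G$dosages
  call_rate <- colMeans(!is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  drop_maf <- maf < maf_min
  drop_cr <- call_rate < call_rate_min
  keep <- !(drop_maf | drop_cr)
  if (!any(keep)) {
    stop("quality control removed every marker (",
         sum(drop_maf), " by MAF, ", sum(drop_cr), " by call rate)")
  }
  out <- new_genotypes(dos[, keep, drop = FALSE],
                       G$markers[keep, , drop = FALSE], G$samples)
  attr(out, "qc_report") <- list(
    n_input = ncol(dos), n_kept = sum(keep),
    removed_maf = sum(drop_maf), removed_call_rate = sum(drop_cr)
  )
  out
}

## Mean-impute missing dosages column-wise (upstream data are assumed
## imputed; this only covers stray missing calls that survive QC).
impute_dosages <- function(dos) {
  if (!anyNA(dos)) return(dos)
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2]]
  dos
}

#' Genomic relationship matrix
#'
#' Allele-frequency standardized GRM:
#' `A = (1/m) * sum_i (x_i - 2 p_i)(x_i - 2 p_i)' / (2 p_i (1 - p_i))`.
#' Monomorphic markers carry no information and are excluded with a warning.
#'
#' @param G a `pleio_genotypes` object (post-QC).
#' @param exclude_chrom optional chromosome id excluded from the sum
#'   (the leave-one-chromosome-out background).
#' @return symmetric samples x samples matrix.
#' @export
compute_grm <- function(G, exclude_chrom = NULL) {
  stopifnot(inherits(G, "pleio_genotypes"))
  keep <- rep(TRUE, ncol(G$dosages))
  if (!is.null(exclude_chrom)) keep <- !(G$markers$chrom %in% exclude_chrom)
  assert_that(sum(keep) >= 1, "no markers remain after chromosome exclusion")
  X <- impute_dosages(G$dosages[, keep, drop = FALSE])
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from the GRM")
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  assert_that(length(p) >= 1, "no polymorphic markers for the GRM")
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  dimnames(A) <- list(rownames(X), rownames(X))
  A
}

## EMMA-style REML for y = X b + g + e with g ~ N(0, sg2 K), e ~ N(0, se2 I).
## Works in the eigenbasis of K; profiles the likelihood over
## lambda = sg2/se2. Returns variance components and the rotated data needed
## for downstream GLS marker tests.
reml_mixed <- function(y, X, K, lower = -10, upper = 10, eig = NULL) {
  n <- length(y)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  q <- ncol(X)
  reml_nll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    bhat <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(bhat)) return(1e10)
    r <- ys - Xs %*% bhat
    rss <- sum(w * r^2)
    se2 <- rss / (n - q)
    0.5 * ((n - q) * log(se2) + sum(log(v)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - q))
  }
  opt <- optimize(reml_nll, c(lower, upper))
  lam <- exp(opt$minimum)
  v <- lam * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  bhat <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% bhat
  se2 <- sum(w * r^2) / (n - q)
  sg2 <- lam * se2
  list(sg2 = sg2, se2 = se2, lambda = lam, beta = drop(bhat),
       U = U, d = d, weights = w / se2, ys = ys, Xs = Xs,
       h2 = sg2 * mean(d) / (sg2 * mean(d) + se2))
}

#' Pre-adjust a phenotype for fixed covariates and polygenic background
#'
#' Fits the null mixed model (covariates as fixed effects, polygenic random
#' effect with covariance proportional to the GRM, REML variance components)
#' and returns its marginal residuals: the adjusted phenotype subsequently
#' used for marker testing.
#'
#' @param y numeric phenotype vector.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is added).
#' @param grm samples x samples relationship matrix.
#' @return numeric vector of adjusted phenotypes (mean approximately 0), with
#'   the REML fit in the `fit` attribute.
#' @export
adjust_phenotype <- function(y, covariates = NULL, grm) {
  n <- length(y)
  X <- cbind(intercept = rep(1, n), covariates)
  assert_that(qr(X)$rank == ncol(X), "covariate design is rank-deficient")
  fit <- reml_mixed(y, X, grm)
  adj <- drop(y - X %*% fit$beta)
  attr(adj, "fit") <- fit
  adj
}

#' Leave-one-chromosome-out mixed-model association scan
#'
#' For each trait and chromosome, the polygenic covariance is built from all
#' markers except those on the tested chromosome; REML variance components
#' are estimated once under the null for that (trait, chromosome) pair and
#' reused in a generalized-least-squares Wald test of every marker on the
#' chromosome (the standard fast approximation to per-marker REML).
#' With a single chromosome the scan falls back to a plain mixed model using
#' the genome-wide GRM, with a warning.
#'
#' @param G post-QC `pleio_genotypes`.
#' @param panel a `trait_panel`; when it carries covariates each trait is
#'   pre-adjusted with [adjust_phenotype()] before the scan, mirroring the
#'   phenotype-adjustment route; EBV-like panels without covariates enter the
#'   model directly.
#' @param grm optional precomputed relationship matrix used for every
#'   chromosome (disables the leave-one-chromosome-out background; useful
#'   with pedigree relationships or known covariance structures).
#' @return a `marker_stats` object: list of matrices `beta`, `se`, `t`, `p`
#'   (markers x traits) plus the marker table.
#' @export
mlma_loco <- function(G, panel, grm = NULL) {
  stopifnot(inherits(G, "pleio_genotypes"), inherits(panel, "trait_panel"))
  assert_that(nrow(panel$traits) == nrow(G$dosages),
              "panel rows must match genotype samples")
  dos <- impute_dosages(G$dosages)
  chroms <- unique(G$markers$chrom)
  loco <- is.null(grm) && length(chroms) >= 2
  if (!loco && is.null(grm)) {
    warning("single chromosome: falling back to a plain mixed model ",
            "with the genome-wide GRM")
  }
  traits <- panel$traits
  if (!is.null(panel$covariates)) {
    grm_all <- grm %||% compute_grm(G)
    traits <- apply(traits, 2, function(y)
      as.numeric(adjust_phenotype(y, panel$covariates, grm_all)))
    dimnames(traits) <- dimnames(panel$traits)
  }
  m <- ncol(dos); t <- ncol(traits)
  beta <- se <- matrix(NA_real_, m, t,
                       dimnames = list(G$markers$id, colnames(traits)))
  n <- nrow(dos)
  for (ch in chroms) {
    idx <- which(G$markers$chrom == ch)
    K <- if (!is.null(grm)) grm
         else if (loco) compute_grm(G, exclude_chrom = ch)
         else compute_grm(G)
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors
    d <- pmax(eig$values, 0)
    Gs <- crossprod(U, dos[, idx, drop = FALSE])
    ones <- drop(crossprod(U, rep(1, n)))  # rotated intercept column
    for (k in seq_len(t)) {
      ys <- drop(crossprod(U, traits[, k]))
      fit <- reml_mixed(traits[, k], matrix(1, n, 1), K, eig = eig)
      w <- 1 / (fit$lambda * d + 1)  # precision up to 1/se2
      ## GLS of y on (intercept, x) with weights w, vectorized over markers;
      ## the intercept must be rotated along with y and x
      scc <- sum(w * ones^2)
      scy <- sum(w * ones * ys)
      scx <- drop(crossprod(Gs, w * ones))
      sxy <- drop(crossprod(Gs, w * ys))
      sxx <- drop(crossprod(Gs^2, w))
      det_ <- scc * sxx - scx^2
      b <- (scc * sxy - scx * scy) / det_
      a <- (scy - b * scx) / scc
      ## residual variance re-estimated per marker (n - 2 df)
      rss <- vapply(seq_along(idx), function(j) {
        r <- ys - a[j] * ones - b[j] * Gs[, j]
        sum(w * r^2)
      }, numeric(1))
      s2 <- rss / (n - 2)
      seb <- sqrt(s2 * scc / det_)
      bad <- !is.finite(b) | det_ <= 0
      b[bad] <- NA_real_; seb[bad] <- NA_real_
      beta[idx, k] <- b
      se[idx, k] <- seb
    }
  }
  tt <- beta / se
  p <- 2 * pnorm(-abs(tt))
  structure(list(beta = beta, se = se, t = tt, p = p, markers = G$markers,
                 traits = colnames(traits)),
            class = "marker_stats")
}

#' Correlation matrix of the traits' signed t-values
#'
#' Pearson correlation of the per-trait signed t columns across all markers;
#' this is the matrix inverted in the multi-trait pleiotropy statistic.
#'
#' @param stats a `marker_stats` object.
#' @param ridge optional ridge added to the diagonal when the matrix is
#'   near-singular (`NULL`, the default, errors instead).
#' @return symmetric unit-diagonal traits x traits matrix.
#' @export
trait_correlation_matrix <- function(stats, ridge = NULL) {
  stopifnot(inherits(stats, "marker_stats"))
  tmat <- stats$t
  ok <- rowSums(!is.finite(tmat)) == 0
  tmat <- tmat[ok, , drop = FALSE]
  assert_that(ncol(tmat) >= 2, "need at least two traits")
  assert_that(nrow(tmat) >= 3, "need at least three markers")
  V <- cor(tmat)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8) {
    if (is.null(ridge)) {
      stop("trait t-value correlation matrix is near-singular ",
           "(condition number > 1e8); consider the ridge option")
    }
    V <- V + diag(ridge, ncol(V))
    V <- stats::cov2cor(V)
    message("applied ridge ", ridge, " to the trait correlation matrix")
  }
  V
}

#' Multi-trait pleiotropy statistic
#'
#' Per marker, `chi2 = t' V^-1 t` where `t` is the vector of signed t-values
#' across traits and `V` their correlation matrix; the p-value is the upper
#' tail of a chi-square with degrees of freedom equal to the number of
#' traits.
#'
#' @param stats a `marker_stats` object.
#' @param V trait correlation matrix from [trait_correlation_matrix()].
#' @return a `pleio_table`: data.frame (id, chrom, pos, chi2, df, p) with the
#'   matrix `V` attached as an attribute. Markers with non-finite t in any
#'   trait are excluded with a warning.
#' @export
pleiotropy_statistic <- function(stats, V) {
  stopifnot(inherits(stats, "marker_stats"))
  tmat <- stats$t
  ok <- rowSums(!is.finite(tmat)) == 0
  if (!all(ok)) {
    warning(sum(!ok), " marker(s) with non-finite t excluded")
  }
  tmat <- tmat[ok, , drop = FALSE]
  Vinv <- solve(V)
  chi2 <- rowSums((tmat %*% Vinv) * tmat)
  chi2 <- pmax(chi2, 0)
  df <- ncol(tmat)
  out <- data.frame(
    id = stats$markers$id[ok],
    chrom = stats$markers$chrom[ok],
    pos = stats$markers$pos[ok],
    chi2 = chi2, df = df,
    p = pchisq(chi2, df = df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  attr(out, "V") <- V
  class(out) <- c("pleio_table", "data.frame")
  out
}
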