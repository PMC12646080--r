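## Signed weighted gene co-expression networks: FPKM normalization,
## low-expression filtering, soft-threshold selection, signed adjacency,
## topological overlap, and module detection with k-means reallocation.

#' FPKM normalization of a count matrix
#'
#' `FPKM_gs = count_gs * 1e9 / (length_g * libsize_s)`.
#'
#' @param counts genes x samples count matrix with a `gene_lengths`
#'   attribute (bp) or `gene_lengths` supplied explicitly.
#' @param gene_lengths optional named vector of gene lengths in bp.
#' @return FPKM matrix with the same dimnames, `unit` attribute "FPKM".
#' @export
fpkm_normalize <- function(counts, gene_lengths = attr(counts, "gene_lengths")) {
  assert_that(!is.null(gene_lengths), "gene lengths are required for FPKM")
  len <- gene_lengths[rownames(counts)]
  assert_that(!anyNA(len), "gene length missing for some genes")
  if (any(len <= 0)) stop("zero or negative gene length(s)")
  lib <- colSums(counts)
  assert_that(all(lib > 0), "library sizes must be positive")
  fpkm <- counts * 1e9 / outer(as.numeric(len), as.numeric(lib))
  dimnames(fpkm) <- dimnames(counts)
  attr(fpkm, "gene_lengths") <- gene_lengths
  attr(fpkm, "unit") <- "FPKM"
  fpkm
}

#' Remove weakly expressed genes
#'
#' Genes whose mean FPKM across samples falls strictly below `min_fpkm` are
#' dropped (a gene exactly at the threshold is retained). A per-sample rule
#' (`criterion = "all"`: drop when every sample is below) is also available.
#'
#' @param expr FPKM-scale genes x samples matrix.
#' @param min_fpkm expression floor.
#' @param criterion "mean" (default) or "all".
#' @return filtered matrix with a `filter_report` attribute.
#' @export
filter_low_expression <- function(expr, min_fpkm = 0.2,
                                  criterion = c("mean", "all")) {
  criterion <- match.arg(criterion)
  keep <- if (criterion == "mean") {
    rowMeans(expr) >= min_fpkm
  } else {
    apply(expr, 1, function(r) any(r >= min_fpkm))
  }
  if (!any(keep)) stop("every gene fell below the expression filter")
  gl <- attr(expr, "gene_lengths")
  out <- expr[keep, , drop = FALSE]
  attr(out, "gene_lengths") <- gl[rownames(out)]
  attr(out, "unit") <- attr(expr, "unit")
  attr(out, "filter_report") <- list(n_input = nrow(expr),
                                     n_removed = sum(!keep))
  out
}

## log2(FPKM + 1) working scale for all correlation computations.
log_expr <- function(expr) log2(expr + 1)

#' Select the soft-threshold power
#'
#' For each candidate power the signed adjacency is formed and the scale-free
#' topology fit index (R-squared of the log-log regression of the binned
#' connectivity distribution, signed by the slope) is computed; the smallest
#' power reaching `target_fit` is returned. If none reaches it, the usual
#' signed-network default power (`fallback_power`, 12 by default) is returned
#' with a warning: on strongly modular expression data the connectivity
#' distribution is not scale-free at any power, and a low maximal-fit power
#' would leave within- and between-module adjacencies insufficiently
#' contrasted for clustering.
#'
#' @param expr FPKM genes x samples matrix (log2(FPKM+1) is taken internally).
#' @param powers candidate powers.
#' @param target_fit required fit index.
#' @param n_bins connectivity histogram bins.
#' @param fallback_power power used when no candidate reaches `target_fit`.
#' @return integer power with the fit curve in the `fit_indices` attribute.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_fit = 0.8,
                                n_bins = 10, fallback_power = 12L) {
  lx <- log_expr(expr)
  v <- apply(lx, 1, var)
  if (any(v == 0)) stop("constant expression profile(s): ",
                        paste(head(rownames(lx)[v == 0], 3), collapse = ", "))
  assert_that(nrow(lx) >= 20, "need at least 20 genes")
  cc <- cor(t(lx))
  base <- (1 + cc) / 2
  diag(base) <- 0
  fits <- vapply(powers, function(b) {
    k <- rowSums(base^b)
    scale_free_fit(k, n_bins)
  }, numeric(1))
  ok <- which(fits >= target_fit)
  if (length(ok)) {
    beta <- powers[ok[1]]
  } else {
    beta <- as.integer(fallback_power)
    warning("no power reached the target fit (best ",
            round(max(fits), 3), "); using the signed-network default power ",
            fallback_power)
  }
  attr(beta, "fit_indices") <- data.frame(power = powers, fit = fits)
  beta
}

## Scale-free topology fit: regress log10 frequency on log10 mean
## connectivity over connectivity bins; signed R^2 (negative slope expected).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  ## equal-width connectivity bins: with quantile bins the per-bin frequency
  ## would be constant by construction and the regression meaningless
  bin <- cut(k, n_bins, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Signed weighted adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with Pearson correlation of
#' log2(FPKM+1) profiles; anticorrelated genes get weight near 0. The
#' diagonal is zeroed (self-edges are meaningless for density and embedding).
#'
#' @param expr FPKM genes x samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric genes x genes matrix in `[0, 1]` with attribute `beta`.
#' @export
signed_adjacency <- function(expr, beta) {
  assert_that(is.numeric(beta) && beta >= 1, "beta must be >= 1")
  lx <- log_expr(expr)
  v <- apply(lx, 1, var)
  if (any(v == 0)) stop("constant expression profile(s): ",
                        paste(head(rownames(lx)[v == 0], 3), collapse = ", "))
  a <- ((1 + cor(t(lx))) / 2)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`; measures shared network neighborhoods and is the clustering
#' similarity for module detection.
#'
#' @param adj adjacency matrix in `[0, 1]` with zero diagonal.
#' @return symmetric TOM matrix in `[0, 1]`.
#' @export
compute_tom <- function(adj) {
  assert_that(all(adj >= 0 & adj <= 1), "adjacency must lie in [0, 1]")
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

## First principal component of the module's standardized log-expression,
## oriented to correlate positively with the module mean profile.
module_eigengene <- function(lx_scaled, members) {
  sub <- lx_scaled[members, , drop = FALSE]
  if (length(members) == 1L) return(drop(sub))
  sv <- svd(sub, nu = 0, nv = 1)
  eg <- drop(sv$v[, 1])
  if (cor(eg, colMeans(sub)) < 0) eg <- -eg
  eg
}

#' Detect co-expression modules with k-means reallocation
#'
#' Average-linkage hierarchical clustering of `1 - TOM` cut at a fixed
#' height gives initial modules (clusters below `min_module_size` go to the
#' unassigned pool); up to `kmeans_iters` reallocation rounds then move each
#' gene to the module whose eigengene its profile correlates with most,
#' recomputing eigengenes after every round. The reallocation objective
#' (sum over genes of the correlation with the assigned eigengene, evaluated
#' at the eigengenes used for the assignment) never decreases and is
#' recorded for auditing.
#'
#' @param adj signed adjacency (used for consistency checks only).
#' @param tom TOM from [compute_tom()].
#' @param expr FPKM matrix (same genes).
#' @param min_module_size smallest retained initial cluster.
#' @param kmeans_iters maximal reallocation rounds (0 = hierarchical cut
#'   only).
#' @param cut_height tree cut height on the `1 - TOM` dissimilarity.
#' @param seed seed (reallocation is deterministic; kept for interface
#'   stability).
#' @return a `module_assignment`: list with `labels` (named integer vector;
#'   0 only before reallocation), `eigengenes` (samples x modules),
#'   `objective_trace` (per-round audit) and `initial_labels`.
#' @export
detect_modules <- function(adj, tom, expr, min_module_size = 30,
                           kmeans_iters = 20, cut_height = 0.9, seed = 1L) {
  assert_that(all(rownames(tom) == rownames(expr)),
              "TOM and expression gene order differ")
  n <- nrow(tom)
  lx <- log_expr(expr)
  lx_scaled <- t(scale(t(lx)))
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: a single module is returned")
    labels <- setNames(rep(1L, n), rownames(tom))
    eg <- matrix(module_eigengene(lx_scaled, names(labels)),
                 ncol = 1, dimnames = list(colnames(expr), "1"))
    return(structure(list(labels = labels, eigengenes = eg,
                          objective_trace = numeric(0),
                          initial_labels = labels),
                     class = "module_assignment"))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep_mods <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(n)
  for (i in seq_along(keep_mods)) labels[raw == keep_mods[i]] <- i
  names(labels) <- rownames(tom)
  if (!any(labels > 0)) {
    ## no cluster met the size floor: keep the largest as one module
    big <- as.integer(names(sizes)[which.max(sizes)])
    labels[raw == big] <- 1L
    warning("no initial cluster reached min_module_size; ",
            "largest cluster retained")
  }
  initial <- labels
  mods <- sort(unique(labels[labels > 0]))
  trace <- numeric(0)
  if (kmeans_iters > 0) {
    if (any(labels == 0)) {
      ## seed unassigned genes at their nearest eigengene so every
      ## reallocation round starts from a full partition
      eg0 <- vapply(mods, function(m)
        module_eigengene(lx_scaled, names(labels)[labels == m]),
        numeric(ncol(lx)))
      cors0 <- cor(t(lx_scaled), eg0)
      grey <- which(labels == 0)
      labels[grey] <- mods[max.col(cors0[grey, , drop = FALSE],
                                   ties.method = "first")]
    }
    for (it in seq_len(kmeans_iters)) {
      eg <- vapply(mods, function(m)
        module_eigengene(lx_scaled, names(labels)[labels == m]),
        numeric(ncol(lx)))
      cors <- cor(t(lx_scaled), eg)  # genes x modules
      ## objective before reassignment, under the current eigengenes
      obj_before <- sum(vapply(seq_len(n), function(g)
        if (labels[g] > 0) cors[g, labels[g]] else 0, numeric(1)))
      new_labels <- mods[max.col(cors, ties.method = "first")]
      names(new_labels) <- names(labels)
      obj_after <- sum(cors[cbind(seq_len(n), match(new_labels, mods))])
      trace <- c(trace, obj_before, obj_after)
      if (all(new_labels == labels)) { labels <- new_labels; break }
      labels <- new_labels
    }
  }
  mods <- sort(unique(labels[labels > 0]))
  eg <- vapply(mods, function(m)
    module_eigengene(lx_scaled, names(labels)[labels == m]),
    numeric(ncol(lx)))
  colnames(eg) <- as.character(mods)
  rownames(eg) <- colnames(expr)
  structure(list(labels = labels, eigengenes = eg,
                 objective_trace = trace, initial_labels = initial),
            class = "module_assignment")
}

#' Per-module adjacency submatrices
#'
#' @param adj full signed adjacency.
#' @param assignment a `module_assignment`.
#' @return named list of adjacency matrices, one per module label.
#' @export
module_adjacencies <- function(adj, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  labs <- assignment$labels
  mods <- sort(unique(labs[labs > 0]))
  out <- lapply(mods, function(m) {
    g <- names(labs)[labs == m]
    adj[g, g, drop = FALSE]
  })
  names(out) <- paste0("module", mods)
  out
}
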