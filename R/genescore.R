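## Gene-level pleiotropy p-values: marker-to-gene mapping, local LD
## eigenvalues and the Liu moment-matching tail approximation for the
## weighted chi-square sum.

#' Map markers to gene bodies
#'
#' A marker is assigned to every gene whose interval
#' `[start - window_bp, end + window_bp]` (1-based, inclusive at both ends)
#' contains its position; overlapping genes receive the marker multiple
#' times. Genes without markers are omitted.
#'
#' @param markers marker table (id, chrom, pos).
#' @param genes gene-model data.frame (gene, chrom, start, end).
#' @param window_bp symmetric window added around each gene body.
#' @return named list: gene id -> character vector of marker ids.
#' @export
map_snps_to_genes <- function(markers, genes, window_bp = 0) {
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    lo <- genes$start[i] - window_bp
    hi <- genes$end[i] + window_bp
    hit <- markers$chrom == genes$chrom[i] &
      markers$pos >= lo & markers$pos <= hi
    out[[i]] <- markers$id[hit]
  }
  out[lengths(out) > 0]
}

#' Local LD matrix of a marker set
#'
#' Signed Pearson correlation (r, not r-squared) of the dosage columns.
#'
#' @param G `pleio_genotypes`.
#' @param marker_ids markers to correlate (must be columns of `G`).
#' @return symmetric unit-diagonal correlation matrix.
#' @export
ld_matrix <- function(G, marker_ids) {
  stopifnot(inherits(G, "pleio_genotypes"))
  assert_that(length(marker_ids) >= 1, "need at least one marker")
  missing <- setdiff(marker_ids, colnames(G$dosages))
  assert_that(length(missing) == 0,
              "markers absent from genotypes: ",
              paste(head(missing, 3), collapse = ", "))
  X <- impute_dosages(G$dosages[, marker_ids, drop = FALSE])
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    stop("zero-variance marker(s): ",
         paste(head(marker_ids[v == 0], 3), collapse = ", "))
  }
  R <- cor(X)
  dimnames(R) <- list(marker_ids, marker_ids)
  R
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Liu-style moment matching: the first four cumulants of
#' `Q = sum_j lambda_j * chisq_1` are matched to a (possibly noncentral)
#' chi-square, whose tail supplies the p-value. When the skewness condition
#' `s1^2 > s2` fails, the kurtosis-matched central approximation is used.
#'
#' @param T observed statistic (>= 0).
#' @param eigenvalues weights `lambda_j >= 0`; small negative values arising
#'   from numerical error are clipped to zero with a warning.
#' @return p-value in (0, 1].
#' @export
liu_pvalue <- function(T, eigenvalues) {
  assert_that(is.numeric(T) && length(T) == 1L && T >= 0,
              "T must be a non-negative scalar")
  lam <- as.numeric(eigenvalues)
  if (any(lam < 0)) {
    if (any(lam < -1e-8)) {
      warning("negative eigenvalue(s) clipped to zero")
    }
    lam <- pmax(lam, 0)
  }
  lam <- lam[lam > 0]
  assert_that(length(lam) > 0, "all eigenvalues are zero")
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  tstar <- (T - muQ) / sigmaQ
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  muX <- l + delta
  sigmaX <- sqrt(2 * (l + 2 * delta))
  q <- tstar * sigmaX + muX
  p <- pchisq(q, df = l, ncp = delta, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Gene-level pleiotropy p-values
#'
#' Per gene, each mapped marker p-value is transformed to an upper-tail
#' chi-square(1) quantile (the squared normal quantile of `1 - p/2`); their
#' sum `T_g` is referred to the null distribution of a weighted chi-square
#' sum whose weights are the eigenvalues of the gene's signed LD matrix,
#' evaluated with [liu_pvalue()]. Genes with a single marker return the
#' marker p-value unchanged.
#'
#' @param pleio a `pleio_table` from [pleiotropy_statistic()].
#' @param mapping gene -> marker ids list from [map_snps_to_genes()].
#' @param G `pleio_genotypes` (source of the local LD matrices).
#' @param genes optional gene-model data.frame used to annotate the output
#'   with symbol and coordinates.
#' @return a `gene_score_table`: data.frame (gene, symbol, chrom, n_snps,
#'   statistic, p) with the per-gene eigenvalues in the `eigenvalues`
#'   attribute.
#' @export
gene_level_pvalues <- function(pleio, mapping, G, genes = NULL) {
  stopifnot(inherits(pleio, "pleio_table"))
  pv <- setNames(pleio$p, pleio$id)
  rows <- vector("list", length(mapping))
  eig_list <- vector("list", length(mapping))
  names(eig_list) <- names(mapping)
  for (i in seq_along(mapping)) {
    gid <- names(mapping)[i]
    ids <- intersect(mapping[[i]], names(pv))
    if (length(ids) == 0) next
    p <- pv[ids]
    if (any(p <= 0)) {
      warning("marker p-value(s) of 0 floored at 1e-300 in gene ", gid)
      p <- pmax(p, 1e-300)
    }
    if (length(ids) == 1L) {
      stat <- qchisq(p, df = 1, lower.tail = FALSE)
      gp <- unname(p)
      lam <- 1
    } else {
      z2 <- qchisq(p, df = 1, lower.tail = FALSE)
      stat <- sum(z2)
      R <- ld_matrix(G, ids)
      lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      gp <- liu_pvalue(stat, lam)
    }
    eig_list[[gid]] <- lam
    rows[[i]] <- data.frame(gene = gid, n_snps = length(ids),
                            statistic = unname(sum(stat)), p = gp,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  assert_that(!is.null(out) && nrow(out) > 0, "no gene received any marker p")
  if (!is.null(genes)) {
    idx <- match(out$gene, genes$gene)
    out$symbol <- genes$symbol[idx]
    out$chrom <- genes$chrom[idx]
    out <- out[, c("gene", "symbol", "chrom", "n_snps", "statistic", "p")]
  }
  rownames(out) <- NULL
  attr(out, "eigenvalues") <- eig_list[out$gene]
  class(out) <- c("gene_score_table", "data.frame")
  out
}
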