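## Over-representation analysis: hypergeometric gene-set enrichment from GMT
## collections, QTL-window annotation and enrichment, BH-FDR control, and
## gene x term incidence matrices for network embedding.

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test per term: with `N` background genes,
#' `K` term members in the background, `n` query genes and `k` of them in the
#' term, `p = P(X >= k)` for hypergeometric `X`; Benjamini-Hochberg q-values
#' control the FDR across terms.
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param terms a term collection: list with `sets` (term -> gene vector) and
#'   optional `descriptions`; a bare named list of gene vectors also works.
#' @param background character vector defining the gene universe.
#' @param fdr FDR level for the `enriched` flag.
#' @return data.frame (term, description, k, K, n, N, p, q, enriched) sorted
#'   by p.
#' @export
hypergeom_enrich <- function(query, terms, background, fdr = 0.05) {
  sets <- if (is.list(terms) && !is.null(terms$sets)) terms$sets else terms
  desc <- if (is.list(terms) && !is.null(terms$descriptions))
    terms$descriptions else setNames(rep("", length(sets)), names(sets))
  query <- toupper(unique(query))
  background <- toupper(unique(background))
  assert_that(length(query) > 0, "empty query gene set")
  assert_that(length(background) > 0, "empty background gene set")
  extra <- setdiff(query, background)
  assert_that(length(extra) == 0,
              "query genes outside the background: ",
              paste(head(extra, 3), collapse = ", "))
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(tm) {
    members <- intersect(toupper(sets[[tm]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, description = unname(desc[tm]),
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  assert_that(!is.null(out), "no term overlaps the background")
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= fdr
  out[order(out$p), , drop = FALSE]
}

#' Annotate genes with overlapping QTL intervals
#'
#' Emits a (gene, QTL) pair whenever the QTL interval intersects the gene
#' body extended by `window_bp` on each side (same chromosome; 1-based
#' inclusive coordinates; the window is clamped at position 1).
#'
#' @param genes gene-model data.frame (gene, chrom, start, end).
#' @param qtls QTL data.frame (qtl_id, trait, trait_class, chrom, start, end).
#' @param window_bp symmetric window around the gene (default 100 kb).
#' @return data.frame of annotated pairs (possibly zero rows).
#' @export
annotate_qtls <- function(genes, qtls, window_bp = 100000) {
  out <- list(); k <- 0L
  for (i in seq_len(nrow(genes))) {
    lo <- max(1, genes$start[i] - window_bp)
    hi <- genes$end[i] + window_bp
    hit <- which(qtls$chrom == genes$chrom[i] &
                 qtls$end >= lo & qtls$start <= hi)
    if (length(hit)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = genes$gene[i],
        qtl_id = qtls$qtl_id[hit], trait = qtls$trait[hit],
        trait_class = qtls$trait_class[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    return(data.frame(gene = character(0), qtl_id = character(0),
                      trait = character(0), trait_class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' QTL-trait enrichment
#'
#' Per QTL trait, a hypergeometric test of how often the query genes are
#' annotated to the trait relative to the background annotation (computed
#' over the full gene universe with the same window).
#'
#' @param annotated (gene, trait) pairs for the query genes, from
#'   [annotate_qtls()] restricted to the query.
#' @param background_annotated (gene, trait) pairs over the full universe.
#' @param background_genes character vector: the full gene universe.
#' @param query_genes character vector of query genes.
#' @param fdr FDR level.
#' @return data.frame (trait, trait_class, k, K, n, N, p, q, enriched).
#' @export
qtl_enrich <- function(annotated, background_annotated, background_genes,
                       query_genes, fdr = 0.05) {
  if (nrow(annotated) == 0) {
    return(data.frame(trait = character(0), trait_class = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  }
  N <- length(unique(background_genes))
  n <- length(unique(query_genes))
  traits <- unique(annotated$trait)
  rows <- lapply(traits, function(tr) {
    bg <- unique(background_annotated$gene[background_annotated$trait == tr])
    if (length(bg) == 0) {
      warning("trait absent from the background annotation: ", tr)
      return(NULL)
    }
    K <- length(bg)
    k <- length(unique(annotated$gene[annotated$trait == tr]))
    cls <- annotated$trait_class[annotated$trait == tr][1]
    data.frame(trait = tr, trait_class = cls, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(qtl_enrich(annotated[0, ], background_annotated,
                                      background_genes, query_genes, fdr))
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= fdr
  out[order(out$p), , drop = FALSE]
}

#' Gene x enriched-term incidence matrix
#'
#' Binary matrix whose entry is 1 iff the gene is annotated to the enriched
#' term; genes with no membership in any enriched term are excluded from the
#' rows and recorded in the `excluded_genes` attribute.
#'
#' @param genes gene universe (character vector of symbols/ids matching the
#'   term sets).
#' @param enriched_sets named list: enriched term -> member genes.
#' @return binary matrix (genes x terms) with attribute `excluded_genes`.
#' @export
build_incidence <- function(genes, enriched_sets) {
  assert_that(length(enriched_sets) > 0, "no enriched terms")
  genes <- unique(toupper(genes))
  M <- vapply(enriched_sets,
              function(s) as.integer(genes %in% toupper(s)),
              integer(length(genes)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(genes))
  dimnames(M) <- list(genes, names(enriched_sets))
  M <- M[, colSums(M) > 0, drop = FALSE]
  keep <- rowSums(M) > 0
  out <- M[keep, , drop = FALSE]
  attr(out, "excluded_genes") <- genes[!keep]
  out
}
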