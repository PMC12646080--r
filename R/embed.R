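## Network embedding: biased (node2vec-style) random walks over weighted
## gene-gene and bipartite gene-term graphs, skip-gram embeddings, and the
## top-K weighted edge density / mean betweenness diagnostic curves.

#' Random-walk configuration
#'
#' Defaults follow the usual node2vec setup for gene networks: 10 walks per
#' node of maximal length 80, return weight (1/p) 0.25 so walks rarely
#' backtrack, in-out weight (1/q) 1.
#'
#' @param n_walks walks started per node.
#' @param walk_length maximal walk length (nodes).
#' @param return_weight bias multiplier for stepping back to the previous
#'   node (the 1/p factor).
#' @param inout_weight bias multiplier for stepping to a node not adjacent to
#'   the previous one (the 1/q factor).
#' @param seed integer seed for the walk sampler.
#' @return list of class `walk_config`.
#' @export
walk_config <- function(n_walks = 10, walk_length = 80,
                        return_weight = 0.25, inout_weight = 1, seed = 1L) {
  assert_that(is_count(n_walks), "n_walks must be a positive integer")
  assert_that(is_count(walk_length), "walk_length must be a positive integer")
  assert_that(return_weight > 0 && inout_weight > 0,
              "walk bias weights must be positive")
  structure(list(n_walks = as.integer(n_walks),
                 walk_length = as.integer(walk_length),
                 return_weight = return_weight, inout_weight = inout_weight,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Build the walk graph from an adjacency or incidence matrix
#'
#' Square symmetric matrices are treated as weighted undirected gene-gene
#' graphs (diagonal ignored); rectangular binary matrices are expanded to a
#' bipartite gene-term graph with unit edge weights. Zero-weight edges are
#' dropped; isolated nodes are retained.
#'
#' @param m adjacency (genes x genes) or incidence (genes x terms) matrix
#'   with dimnames.
#' @param type "auto" (default), "adjacency" or "incidence".
#' @return an igraph undirected weighted graph with a logical vertex
#'   attribute `is_gene`.
#' @export
build_walk_graph <- function(m, type = c("auto", "adjacency", "incidence")) {
  type <- match.arg(type)
  assert_that(length(m) > 0 && !is.null(rownames(m)),
              "matrix with dimnames required")
  if (type == "auto") {
    sq <- nrow(m) == ncol(m) && !is.null(colnames(m)) &&
      all(rownames(m) == colnames(m))
    type <- if (sq) "adjacency" else "incidence"
  }
  if (type == "adjacency") {
    a <- m
    diag(a) <- 0
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$is_gene <- TRUE
  } else {
    genes <- rownames(m); terms <- colnames(m)
    assert_that(length(intersect(genes, terms)) == 0,
                "gene and term names must not collide")
    idx <- which(m != 0, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(genes) + length(terms),
                              name = c(genes, terms),
                              is_gene = rep(c(TRUE, FALSE),
                                            c(length(genes), length(terms))))
    if (nrow(idx)) {
      ends <- rbind(genes[idx[, 1]], terms[idx[, 2]])
      g <- igraph::add_edges(g, as.vector(ends),
                             weight = as.numeric(m[idx]))
    }
  }
  assert_that(igraph::vcount(g) > 0, "empty graph")
  g
}

#' Biased random walks on a weighted graph
#'
#' Second-order walks: the step from `v` (arrived from `u`) samples neighbor
#' `x` with unnormalized weight `w(v, x) * alpha`, where `alpha` is
#' `return_weight` if `x == u`, 1 if `x` is adjacent to `u`, and
#' `inout_weight` otherwise. Walks truncate at dead ends; `n_walks` walks
#' start at every node. Deterministic given `cfg$seed`.
#'
#' @param graph igraph undirected weighted graph.
#' @param cfg a [walk_config()].
#' @return list of character vectors of node names, with the graph's vertex
#'   names in the `vertex_names` attribute.
#' @export
biased_random_walks <- function(graph, cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"))
  assert_that(igraph::vcount(graph) > 0, "empty graph")
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  keep <- w > 0
  el <- el[keep, , drop = FALSE]; w <- w[keep]
  nbr <- vector("list", n); wts <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  if (nrow(el)) {
    for (side in 1:2) {
      a <- el[, side]; b <- el[, 3 - side]
      o <- order(a, b)
      sp <- split(seq_along(a)[o], a[o])
      for (nm in names(sp)) {
        i <- as.integer(nm)
        nbr[[i]] <- c(nbr[[i]], b[sp[[nm]]])
        wts[[i]] <- c(wts[[i]], w[sp[[nm]]])
      }
    }
    for (i in seq_len(n)) {
      o <- order(nbr[[i]])
      nbr[[i]] <- as.integer(nbr[[i]][o] - 1L)  # 0-based sorted for C++
      wts[[i]] <- wts[[i]][o]
    }
  }
  walks <- .biased_walks_cpp(nbr, wts, cfg$n_walks, cfg$walk_length,
                             cfg$return_weight, cfg$inout_weight,
                             as.double(cfg$seed))
  nms <- igraph::V(graph)$name %||% as.character(seq_len(n))
  out <- lapply(walks, function(v) nms[v])
  attr(out, "vertex_names") <- nms
  out
}

#' Skip-gram embedding of walk corpora
#'
#' Trains skip-gram with negative sampling over the node walks (single
#' deterministic worker) and returns one `dims`-length vector per node.
#' Nodes that never occur with a context (e.g. isolated nodes whose walks
#' have length 1) receive a zero vector with a warning.
#'
#' @param walks list of walks from [biased_random_walks()].
#' @param dims embedding dimensionality.
#' @param window maximal distance between target and context node within a
#'   walk (the actual window per token is sampled uniformly in 1..window).
#' @param epochs training epochs over the corpus.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate (linear decay).
#' @param seed integer seed.
#' @return numeric matrix nodes x dims with rownames.
#' @export
skipgram_embed <- function(walks, dims = 32, window = 32, epochs = 20,
                           negative = 5, alpha = 0.025, seed = 1L) {
  nms <- attr(walks, "vertex_names")
  if (is.null(nms)) nms <- sort(unique(unlist(walks)))
  idx_walks <- lapply(walks, function(v) match(v, nms))
  emb <- .sgns_train_cpp(idx_walks, length(nms), as.integer(dims),
                         as.integer(window), as.integer(epochs),
                         as.integer(negative), alpha, as.double(seed))
  trained <- attr(emb, "trained")
  if (!all(trained)) {
    warning(sum(!trained), " node(s) without any context pair; ",
            "zero vectors returned for them")
  }
  rownames(emb) <- nms
  emb
}

#' Weighted edge density of the top-K genes
#'
#' `WED_K = sum_{i<j<=K} w_ij / (K (K - 1) / 2)`: the mean pairwise edge
#' weight among the K genes ranked most significant.
#'
#' @param adj symmetric weighted adjacency with zero diagonal.
#' @param ranking character vector of genes ordered most significant first
#'   (ascending p); must be a subset of the adjacency nodes.
#' @param k_grid K values (default 100 to 5000 by 100); values exceeding the
#'   available genes are capped.
#' @return data.frame (K, wed) of class `topk_curve`.
#' @export
wed_topk <- function(adj, ranking, k_grid = seq(100, 5000, by = 100)) {
  assert_that(length(k_grid) > 0, "empty K grid")
  missing <- setdiff(ranking, rownames(adj))
  assert_that(length(missing) == 0, "ranked genes absent from the adjacency")
  n <- length(ranking)
  ks <- sort(unique(pmin(k_grid, n)))
  ks <- ks[ks >= 2]
  assert_that(length(ks) > 0, "K grid has no usable value (need K >= 2)")
  wed <- vapply(ks, function(k) {
    top <- ranking[seq_len(k)]
    sum(adj[top, top]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  structure(data.frame(K = ks, value = wed), class = c("topk_curve",
                                                       "data.frame"))
}

#' Exact betweenness centrality
#'
#' Unweighted shortest-path betweenness, each unordered pair counted once;
#' disconnected pairs contribute nothing.
#'
#' @param graph igraph graph.
#' @return named numeric vector of node scores.
#' @export
betweenness_scores <- function(graph) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  if (is.null(names(b))) names(b) <- as.character(seq_along(b))
  b
}

#' Mean betweenness of the top-K genes
#'
#' @param scores named betweenness scores (from [betweenness_scores()]).
#' @param ranking genes ordered most significant first; only genes present in
#'   `scores` enter the means (term nodes are excluded by passing a
#'   gene-only ranking).
#' @param k_grid K values; capped at the available genes.
#' @return data.frame (K, value) of class `topk_curve`.
#' @export
mean_betweenness_topk <- function(scores, ranking,
                                  k_grid = seq(100, 5000, by = 100)) {
  assert_that(length(k_grid) > 0, "empty K grid")
  ranking <- ranking[ranking %in% names(scores)]
  assert_that(length(ranking) > 0,
              "no ranked gene carries a betweenness score")
  n <- length(ranking)
  ks <- sort(unique(pmin(k_grid, n)))
  val <- vapply(ks, function(k) mean(scores[ranking[seq_len(k)]]),
                numeric(1))
  structure(data.frame(K = ks, value = val), class = c("topk_curve",
                                                       "data.frame"))
}
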