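# Shared fixtures and small oracles used across test files. Everything is
# generated programmatically from fixed seeds; nothing is read from disk.

# Small genotype/trait bundle reused by assoc and genescore tests.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 120, n_markers = 300, n_chrom = 3,
                        n_traits = 3, n_causal = 10, seed = 7L)
      cache <<- simulate_bundle(cfg, module_spec = c(M1 = 20, M2 = 20),
                                n_expr_samples = 20, n_terms = 10,
                                n_qtls = 8)
    }
    cache
  }
})

# Minimal single-chromosome genotype object from a dosage matrix.
make_genotypes <- function(dos) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("s", seq_len(n))
  if (is.null(colnames(dos))) colnames(dos) <- paste0("m", seq_len(m))
  markers <- data.frame(id = colnames(dos), chrom = "chr1",
                        pos = seq_len(m) * 1000, ref = "A", alt = "B",
                        stringsAsFactors = FALSE)
  pleionet:::new_genotypes(dos, markers, rownames(dos))
}

# Brute-force betweenness: enumerate all shortest paths between every
# unordered pair by breadth-first search with predecessor lists, then count
# path memberships for interior vertices. Unweighted, undirected.
brute_betweenness <- function(adj_list, n) {
  btw <- numeric(n)
  all_paths <- function(pred, s, v) {
    if (v == s) return(list(s))
    out <- list()
    for (u in pred[[v]]) {
      for (pp in all_paths(pred, s, u)) out[[length(out) + 1L]] <- c(pp, v)
    }
    out
  }
  for (s in seq_len(n - 1L)) {
    dist <- rep(Inf, n); dist[s] <- 0
    pred <- vector("list", n)
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj_list[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          pred[[v]] <- u
          queue <- c(queue, v)
        } else if (dist[v] == dist[u] + 1) {
          pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    for (t in (s + 1L):n) {
      if (is.infinite(dist[t])) next
      paths <- all_paths(pred, s, t)
      npath <- length(paths)
      for (pp in paths) {
        interior <- setdiff(pp, c(s, t))
        btw[interior] <- btw[interior] + 1 / npath
      }
    }
  }
  btw
}

# Random connected-ish undirected graph as an adjacency matrix.
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

adj_to_list <- function(a) {
  lapply(seq_len(nrow(a)), function(i) which(a[i, ] > 0))
}
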