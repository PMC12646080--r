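two_clique_graph <- function(k = 8) {
  a <- matrix(0, 2 * k + 1, 2 * k + 1)
  nms <- c(paste0("a", 1:k), paste0("b", 1:k), "bridge")
  dimnames(a) <- list(nms, nms)
  a[1:k, 1:k] <- 1
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(a) <- 0
  a["a1", "bridge"] <- a["bridge", "a1"] <- 1
  a["b1", "bridge"] <- a["bridge", "b1"] <- 1
  a
}

test_that("walks are deterministic by seed and respect the graph", {
  adj <- two_clique_graph()
  g <- build_walk_graph(adj)
  cfg <- walk_config(n_walks = 3, walk_length = 20, seed = 5L)
  w1 <- biased_random_walks(g, cfg)
  w2 <- biased_random_walks(g, cfg)
  expect_identical(w1, w2)
  w3 <- biased_random_walks(g, walk_config(n_walks = 3, walk_length = 20,
                                           seed = 6L))
  expect_false(identical(w1, w3))
  expect_equal(length(w1), 3 * igraph::vcount(g))
  # every consecutive pair is an edge
  for (wk in w1[1:10]) {
    for (i in seq_len(length(wk) - 1)) {
      expect_true(adj[wk[i], wk[i + 1]] > 0)
    }
  }
})

test_that("second-order walk bias matches the hand-computed transition law", {
  # u - v, v - w, v - x, u - w: from v with previous u, the unnormalized
  # weights are return_weight for u, 1 for w (adjacent to u), inout for x
  adj <- matrix(0, 4, 4, dimnames = list(c("u", "v", "w", "x"),
                                         c("u", "v", "w", "x")))
  adj["u", "v"] <- adj["v", "u"] <- 1
  adj["v", "w"] <- adj["w", "v"] <- 1
  adj["v", "x"] <- adj["x", "v"] <- 1
  adj["u", "w"] <- adj["w", "u"] <- 1
  g <- build_walk_graph(adj)
  cfg <- walk_config(n_walks = 4000, walk_length = 5,
                     return_weight = 2, inout_weight = 0.5, seed = 11L)
  walks <- biased_random_walks(g, cfg)
  nxt <- character(0)
  for (wk in walks) {
    hit <- which(wk[-length(wk)] == "v" &
                   c("", wk[-length(wk)])[seq_len(length(wk) - 1)] == "u")
    if (length(hit)) nxt <- c(nxt, wk[hit + 1])
  }
  freq <- table(factor(nxt, levels = c("u", "w", "x"))) / length(nxt)
  expected <- c(u = 2, w = 1, x = 0.5) / 3.5
  expect_true(all(abs(freq - expected) < 0.03))
})

test_that("skip-gram embeddings are deterministic and separate cliques", {
  adj <- two_clique_graph()
  g <- build_walk_graph(adj)
  walks <- biased_random_walks(g, walk_config(seed = 2L))
  e1 <- skipgram_embed(walks, dims = 16, epochs = 5, seed = 3L)
  e2 <- skipgram_embed(walks, dims = 16, epochs = 5, seed = 3L)
  expect_identical(e1, e2)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  aa <- combn(paste0("a", 1:8), 2)
  within <- mean(apply(aa, 2, function(p) cosine(e1[p[1], ], e1[p[2], ])))
  ab <- expand.grid(paste0("a", 1:8), paste0("b", 1:8))
  across <- mean(apply(ab, 1, function(p) cosine(e1[p[1], ], e1[p[2], ])))
  expect_gt(within, across)
})

test_that("bipartite incidence graphs expand with term nodes flagged", {
  inc <- matrix(c(1, 0, 1, 1), 2, 2,
                dimnames = list(c("G1", "G2"), c("T1", "T2")))
  g <- build_walk_graph(inc)
  expect_setequal(igraph::V(g)$name, c("G1", "G2", "T1", "T2"))
  expect_equal(sum(igraph::V(g)$is_gene), 2)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 3)
})

test_that("WED equals the direct pairwise mean on random graphs", {
  for (i in 1:5) {
    set.seed(100 + i)
    n <- 30
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    rk <- sample(rownames(a))
    out <- wed_topk(a, rk, k_grid = c(5, 10, 20))
    for (j in seq_len(nrow(out))) {
      k <- out$K[j]
      top <- rk[1:k]
      direct <- sum(a[top, top][upper.tri(diag(k))]) / (k * (k - 1) / 2)
      expect_equal(out$value[j], direct)
    }
  }
})

test_that("WED of a complete unit-weight graph is 1 at every K", {
  n <- 40
  a <- matrix(1, n, n); diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  out <- wed_topk(a, rownames(a), k_grid = c(10, 20, 40))
  expect_equal(out$value, rep(1, 3))
})

test_that("betweenness matches closed forms for star and path", {
  # star with 4 leaves: center lies on all choose(4,2) = 6 leaf pairs
  star <- matrix(0, 5, 5, dimnames = list(c("c", paste0("l", 1:4)),
                                          c("c", paste0("l", 1:4))))
  star["c", paste0("l", 1:4)] <- 1
  star[paste0("l", 1:4), "c"] <- 1
  b <- betweenness_scores(build_walk_graph(star))
  expect_equal(unname(b["c"]), 6)
  expect_equal(unname(b[paste0("l", 1:4)]), rep(0, 4))
  # path of 3: middle node on exactly 1 pair
  path <- matrix(0, 3, 3, dimnames = list(c("a", "m", "b"),
                                          c("a", "m", "b")))
  path["a", "m"] <- path["m", "a"] <- 1
  path["m", "b"] <- path["b", "m"] <- 1
  bp <- betweenness_scores(build_walk_graph(path))
  expect_equal(unname(bp["m"]), 1)
})

test_that("betweenness equals the exhaustive oracle on random graphs", {
  for (i in 1:10) {
    a <- random_graph(9, 0.35, seed = 500 + i)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    b <- betweenness_scores(g)
    oracle <- brute_betweenness(adj_to_list(a), nrow(a))
    expect_equal(unname(b), oracle, tolerance = 1e-10)
  }
})

test_that("mean betweenness top-K averages only ranked scored genes", {
  scores <- c(g1 = 4, g2 = 2, g3 = 0, T1 = 99)
  out <- mean_betweenness_topk(scores, c("g1", "g2", "g3"),
                               k_grid = c(2, 3))
  expect_equal(out$value, c(3, 2))
})
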