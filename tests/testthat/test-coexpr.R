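test_that("fpkm_normalize matches the hand formula", {
  counts <- matrix(c(10, 90, 20, 80), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  attr(counts, "gene_lengths") <- c(g1 = 1000, g2 = 2000)
  f <- fpkm_normalize(counts)
  lib <- colSums(counts)
  expect_equal(f["g1", "s1"], 10 * 1e9 / (1000 * lib[1]), ignore_attr = TRUE)
  expect_equal(f["g2", "s2"], 80 * 1e9 / (2000 * lib[2]), ignore_attr = TRUE)
})

test_that("filter_low_expression drops genes below the mean-FPKM floor", {
  x <- rbind(hi = rep(5, 4), lo = rep(0.1, 4), edge = rep(0.2, 4))
  colnames(x) <- paste0("s", 1:4)
  out <- filter_low_expression(x, min_fpkm = 0.2)
  expect_setequal(rownames(out), c("hi", "edge"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed, 1L)
})

test_that("signed adjacency maps correlation through ((1+r)/2)^beta", {
  set.seed(10)
  x <- matrix(runif(5 * 20, 0, 8), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  adj <- signed_adjacency(x, beta = 6)
  r <- cor(t(log2(x + 1)))
  expect_equal(adj[1, 2], ((1 + r[1, 2]) / 2)^6)
  expect_equal(unname(diag(adj)), rep(0, 5))
  expect_true(all(adj >= 0 & adj <= 1))
})

test_that("TOM matches the closed form on a 3-node toy", {
  # adjacency: a12 = a13 = a23 = 0.5
  adj <- matrix(0.5, 3, 3); diag(adj) <- 0
  dimnames(adj) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- compute_tom(adj)
  # l_12 = a13 * a32 = 0.25; k = 1; TOM = (0.25 + 0.5)/(1 + 1 - 0.5) = 0.5
  expect_equal(tom[1, 2], 0.5)
  expect_equal(unname(diag(tom)), rep(1, 3))
})

test_that("scale-free fit is high on a power-law degree sequence", {
  set.seed(77)
  k <- 1 / runif(3000)^(1 / 1.5)  # Pareto-tailed connectivity
  expect_gt(pleionet:::scale_free_fit(k, n_bins = 10), 0.8)
})

test_that("module detection recovers planted modules exactly", {
  genes <- data.frame(gene = sprintf("G%03d", 1:150),
                      symbol = sprintf("G%03d", 1:150),
                      chrom = "chr1", start = 1:150 * 1000,
                      end = 1:150 * 1000 + 500, strand = "+",
                      stringsAsFactors = FALSE)
  ex <- simulate_expression(genes, c(A = 50, B = 50, C = 50),
                            n_samples = 30, within_cor = 0.9, seed = 11L)
  expr <- filter_low_expression(ex$expr)
  beta <- suppressWarnings(pick_soft_threshold(expr))
  adj <- signed_adjacency(expr, as.numeric(beta))
  tom <- compute_tom(adj)
  mods <- detect_modules(adj, tom, expr, seed = 7L)
  lab <- mods$labels
  truth <- as.integer(factor(ex$truth$module_labels[names(lab)]))
  expect_equal(length(unique(lab[lab > 0])), 3L)
  expect_gte(pleionet:::adjusted_rand_index(lab, truth), 0.9)
})

test_that("k-means reallocation objective never decreases within a round", {
  b <- small_bundle()
  expr <- filter_low_expression(b$expr)
  adj <- signed_adjacency(expr, 12)
  tom <- compute_tom(adj)
  mods <- detect_modules(adj, tom, expr, min_module_size = 15, seed = 3L)
  tr <- mods$objective_trace
  expect_true(length(tr) >= 2)
  before <- tr[seq(1, length(tr), by = 2)]
  after <- tr[seq(2, length(tr), by = 2)]
  expect_true(all(after >= before - 1e-10))
})

test_that("module eigengene is the leading expression component", {
  set.seed(21)
  base <- rnorm(15)
  x <- t(vapply(1:10, function(i) base + rnorm(15, sd = 0.1),
                numeric(15)))
  rownames(x) <- paste0("g", 1:10); colnames(x) <- paste0("s", 1:15)
  eg <- pleionet:::module_eigengene(x, rownames(x))
  expect_gt(abs(cor(eg, base)), 0.95)
  # sign convention: positively oriented to the module mean profile
  expect_gt(cor(eg, colMeans(x)), 0)
})
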