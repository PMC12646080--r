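test_that("map_snps_to_genes respects the inclusive window", {
  markers <- data.frame(id = c("s1", "s2", "s3"), chrom = "chr1",
                        pos = c(100, 250, 900), stringsAsFactors = FALSE)
  genes <- data.frame(gene = "g1", chrom = "chr1", start = 200, end = 300,
                      stringsAsFactors = FALSE)
  expect_equal(map_snps_to_genes(markers, genes, 0)$g1, "s2")
  expect_setequal(map_snps_to_genes(markers, genes, 100)$g1, c("s1", "s2"))
  expect_setequal(map_snps_to_genes(markers, genes, 600)$g1,
                  c("s1", "s2", "s3"))
})

test_that("ld_matrix is the signed Pearson r of dosages", {
  dos <- cbind(a = c(0, 1, 2, 1, 0), b = c(2, 1, 0, 1, 2),
               c = c(0, 1, 2, 2, 0))
  G <- make_genotypes(dos)
  R <- ld_matrix(G, c("a", "b", "c"))
  expect_equal(R["a", "b"], -1)
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R["a", "c"], cor(dos[, "a"], dos[, "c"]))
})

test_that("liu_pvalue is exact for chi-square weight vectors", {
  # single unit eigenvalue: T ~ chisq(1)
  for (T in c(0.5, 2, 5, 10)) {
    expect_equal(liu_pvalue(T, 1),
                 pchisq(T, df = 1, lower.tail = FALSE), tolerance = 1e-10)
  }
  # two unit eigenvalues: T ~ chisq(2)
  for (T in c(1, 3, 8)) {
    expect_equal(liu_pvalue(T, c(1, 1)),
                 pchisq(T, df = 2, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("liu_pvalue is monotone decreasing in T and bounded", {
  lam <- c(2, 1, 0.5)
  p <- vapply(c(1, 2, 4, 8, 16), liu_pvalue, numeric(1),
              eigenvalues = lam)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("single-marker genes pass the marker p through unchanged", {
  b <- small_bundle()
  G <- qc_genotypes(b$genotypes)
  st <- mlma_loco(G, b$panel)
  V <- trait_correlation_matrix(st)
  pl <- pleiotropy_statistic(st, V)
  # build a mapping with one single-marker gene and one multi-marker gene
  ids <- pl$id[1:4]
  mapping <- list(gsolo = ids[1], gmulti = ids[2:4])
  sc <- gene_level_pvalues(pl, mapping, G)
  expect_equal(sc$p[sc$gene == "gsolo"], pl$p[pl$id == ids[1]])
  expect_equal(sc$n_snps[sc$gene == "gmulti"], 3L)
})

test_that("gene p-values under perfect LD equal the single-marker p", {
  # duplicate a marker: eigenvalues (2, 0), T = 2 q and
  # P(2 chisq1 > 2 q) = P(chisq1 > q) = p
  dos0 <- c(0, 1, 2, 1, 0, 2, 1, 1)
  dos <- cbind(a = dos0, b = dos0, c = rev(dos0))
  G <- make_genotypes(dos)
  p_marker <- 0.03
  pl <- structure(
    data.frame(id = c("a", "b"), chrom = "chr1", pos = c(1000, 2000),
               chi2 = 1, df = 1, p = p_marker, stringsAsFactors = FALSE),
    class = c("pleio_table", "data.frame"))
  sc <- gene_level_pvalues(pl, list(g = c("a", "b")), G)
  expect_equal(sc$p, p_marker, tolerance = 1e-6)
})

test_that("independent markers give the Fisher-style chi-square combination", {
  set.seed(5)
  n <- 4000
  dos <- cbind(a = rbinom(n, 2, 0.5), b = rbinom(n, 2, 0.5))
  G <- make_genotypes(dos)
  p1 <- 0.04; p2 <- 0.2
  pl <- structure(
    data.frame(id = c("a", "b"), chrom = "chr1", pos = c(1000, 2000),
               chi2 = 1, df = 1, p = c(p1, p2), stringsAsFactors = FALSE),
    class = c("pleio_table", "data.frame"))
  sc <- gene_level_pvalues(pl, list(g = c("a", "b")), G)
  T <- qchisq(p1, 1, lower.tail = FALSE) + qchisq(p2, 1, lower.tail = FALSE)
  # eigenvalues ~ (1, 1) up to sampling noise: T ~ chisq(2)
  expect_equal(sc$p, pchisq(T, 2, lower.tail = FALSE), tolerance = 0.01)
})
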