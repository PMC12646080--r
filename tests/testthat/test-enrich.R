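test_that("hypergeometric enrichment matches phyper by hand", {
  background <- paste0("G", 1:100)
  query <- paste0("G", 1:10)
  terms <- list(sets = list(T1 = paste0("G", 1:20),    # 8 of 10 hits? no: all 10
                            T2 = paste0("G", 51:70)),  # 0 hits
                descriptions = c(T1 = "planted", T2 = "cold"))
  out <- hypergeom_enrich(query, terms, background, fdr = 0.05)
  r1 <- out[out$term == "T1", ]
  expect_equal(r1$k, 10L)
  expect_equal(r1$K, 20L)
  expect_equal(r1$p, phyper(9, 20, 80, 10, lower.tail = FALSE))
  r2 <- out[out$term == "T2", ]
  expect_equal(r2$k, 0L)
  expect_equal(r2$p, 1)
  expect_equal(out$q, p.adjust(out$p, "BH"), ignore_attr = TRUE)
  expect_true(r1$enriched)
  expect_false(r2$enriched)
})

test_that("query genes outside the background are rejected", {
  expect_error(
    hypergeom_enrich(c("A", "ZZZ"), list(sets = list(T = "A")), c("A", "B")),
    "outside the background")
})

test_that("annotate_qtls applies the symmetric 100-kb window", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = c("chr1", "chr1"),
                      start = c(500000, 2000000), end = c(510000, 2010000),
                      stringsAsFactors = FALSE)
  qtls <- data.frame(qtl_id = "q1", trait = "milk", trait_class = "Production",
                     chrom = "chr1", start = 350000, end = 450000,
                     stringsAsFactors = FALSE)
  # g1 window [400000, 610000] overlaps q1; g2 window does not
  ann <- annotate_qtls(genes, qtls, window_bp = 100000)
  expect_equal(ann$gene, "g1")
  # shrink the window: no overlap at all
  expect_equal(nrow(annotate_qtls(genes, qtls, window_bp = 1000)), 0L)
})

test_that("qtl_enrich reproduces the hypergeometric by hand", {
  bg_genes <- paste0("g", 1:50)
  bg_ann <- data.frame(gene = paste0("g", 1:20), qtl_id = "q", trait = "milk",
                       trait_class = "Production", stringsAsFactors = FALSE)
  q_genes <- paste0("g", 1:10)
  q_ann <- bg_ann[bg_ann$gene %in% q_genes, ]
  out <- qtl_enrich(q_ann, bg_ann, bg_genes, q_genes)
  expect_equal(out$k, 10L)
  expect_equal(out$K, 20L)
  expect_equal(out$p, phyper(9, 20, 30, 10, lower.tail = FALSE))
})

test_that("build_incidence drops memberless genes and empty terms", {
  genes <- c("a", "b", "c")
  sets <- list(T1 = c("A", "B"), T2 = "ZZ")
  M <- build_incidence(genes, sets)
  expect_equal(dim(M), c(2L, 1L))
  expect_setequal(rownames(M), c("A", "B"))
  expect_equal(attr(M, "excluded_genes"), "C")
  expect_true(all(M %in% 0:1))
})
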