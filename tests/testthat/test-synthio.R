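test_that("sim_config validates its fields", {
  cfg <- sim_config(seed = 1L)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(n_samples = -5), "n_samples")
  expect_error(sim_config(maf_range = c(0.6, 0.4)), "maf_range")
  expect_error(sim_config(frac_pleiotropic = 2), "frac_pleiotropic")
})

test_that("simulated genotypes are reproducible and respect LD blocks", {
  cfg <- sim_config(n_samples = 200, n_markers = 100, n_chrom = 2,
                    ld_block_size = 10, ld_rho = 0.95, seed = 5L)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  expect_equal(dim(g1$dosages), c(200, 100))
  # within-block LD exceeds between-block LD
  r <- suppressWarnings(cor(g1$dosages))
  within <- mean(abs(r[1:10, 1:10][upper.tri(diag(10))]), na.rm = TRUE)
  between <- mean(abs(r[1:10, 21:30]), na.rm = TRUE)
  expect_gt(within, between + 0.2)
})

test_that("trait simulation plants pleiotropic markers with the stated h2", {
  cfg <- sim_config(n_samples = 400, n_markers = 400, n_chrom = 2,
                    n_traits = 3, n_causal = 20, frac_pleiotropic = 0.5,
                    h2 = 0.4, seed = 9L)
  G <- simulate_genotypes(cfg)
  tr <- simulate_traits(G, cfg)
  expect_equal(ncol(tr$panel$traits), 3)
  expect_equal(length(tr$truth$pleiotropic_markers), 10)
  # realized heritability of the genetic values close to target
  gv <- tr$truth$genetic_values
  h2_real <- apply(gv, 2, var) /
    apply(tr$panel$traits, 2, var)
  expect_true(all(abs(h2_real - 0.4) < 0.15))
})

test_that("expression generator plants recoverable correlated modules", {
  genes <- data.frame(gene = sprintf("G%03d", 1:60),
                      symbol = sprintf("G%03d", 1:60),
                      chrom = "chr1", start = 1:60 * 1000,
                      end = 1:60 * 1000 + 500, strand = "+",
                      stringsAsFactors = FALSE)
  ex <- simulate_expression(genes, c(A = 30, B = 30), n_samples = 25,
                            within_cor = 0.9, seed = 3L)
  expect_true(all(ex$expr >= 0))
  cc <- cor(t(log2(ex$expr + 1)))
  lab <- ex$truth$module_labels
  same <- outer(lab, lab, "==") & upper.tri(cc)
  diff <- !outer(lab, lab, "==") & upper.tri(cc)
  expect_gt(mean(cc[same]), 0.7)
  expect_lt(mean(abs(cc[diff])), 0.3)
})

test_that("annotation generator biases terms toward pleiotropic symbols", {
  b <- small_bundle()
  sets <- b$terms$sets
  expect_true(length(sets) > 0)
  pleio_sym <- b$genes$symbol[match(b$truth$pleiotropic_genes, b$genes$gene)]
  frac_in_sets <- mean(unlist(sets) %in% toupper(pleio_sym))
  frac_overall <- length(pleio_sym) / nrow(b$genes)
  expect_gt(frac_in_sets, frac_overall)
})

test_that("the full bundle is self-consistent", {
  b <- small_bundle()
  expect_setequal(names(b), c("genotypes", "genes", "panel", "expr",
                              "terms", "qtls", "truth", "cfg"))
  expect_true(all(b$truth$pleiotropic_genes %in% b$genes$gene))
  expect_equal(nrow(b$panel$traits), nrow(b$genotypes$dosages))
  expect_true(all(b$qtls$chrom %in% b$genes$chrom))
})
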