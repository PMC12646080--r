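## Synthetic data generation: LD-blocked genotypes, pleiotropic trait
## architectures, modular expression matrices and enriched annotation
## tracks, with ground-truth labels for recovery testing.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic genotype/trait
#' generator. All downstream generators consume this object, so one config
#' plus one seed fully determines a fixture bundle.
#'
#' @param n_samples number of diploid individuals.
#' @param n_markers total number of biallelic markers.
#' @param n_chrom number of chromosomes the markers are spread over.
#' @param n_traits number of (correlated) quantitative traits, at least 2.
#' @param maf_range length-2 interval in (0, 0.5] from which per-marker minor
#'   allele frequencies are drawn uniformly.
#' @param ld_block_size number of consecutive markers forming one LD block;
#'   markers in different blocks are generated independently.
#' @param ld_rho lag-1 autocorrelation of the latent AR(1) haplotype process
#'   within a block; controls how fast pairwise r2 decays with distance.
#' @param h2 per-trait narrow-sense heritability in [0, 1); recycled across
#'   traits when scalar.
#' @param trait_cor traits x traits residual correlation matrix (symmetric
#'   positive definite, unit diagonal), or a scalar exchangeable correlation.
#' @param n_causal number of causal markers underlying the traits.
#' @param frac_pleiotropic fraction of causal markers whose effect is shared
#'   across all traits (the pleiotropic loci); the remainder affect a single
#'   trait each.
#' @param missing_rate per-entry probability of a missing genotype call
#'   (default 0: complete data).
#' @param seed integer seed; every generator derives its stream from it.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_markers = 2000, n_chrom = 4,
                       n_traits = 4, maf_range = c(0.05, 0.5),
                       ld_block_size = 25, ld_rho = 0.95,
                       h2 = 0.4, trait_cor = 0.3, n_causal = 30,
                       frac_pleiotropic = 0.6, missing_rate = 0,
                       seed = 1L) {
  assert_that(is_count(n_samples), "n_samples must be a positive integer")
  assert_that(is_count(n_markers), "n_markers must be a positive integer")
  assert_that(is_count(n_chrom) && n_chrom <= n_markers,
              "n_chrom must be a positive integer <= n_markers")
  assert_that(is_count(n_traits) && n_traits >= 2, "n_traits must be >= 2")
  assert_that(length(maf_range) == 2 && all(maf_range > 0) &&
              all(maf_range <= 0.5) && maf_range[1] <= maf_range[2],
              "maf_range must lie in (0, 0.5]")
  assert_that(is_count(ld_block_size), "ld_block_size must be positive")
  assert_that(is.numeric(ld_rho) && ld_rho >= 0 && ld_rho < 1,
              "ld_rho must be in [0, 1)")
  h2 <- rep_len(h2, n_traits)
  assert_that(all(h2 >= 0 & h2 < 1), "h2 must be in [0, 1)")
  if (is.matrix(trait_cor)) {
    assert_that(nrow(trait_cor) == n_traits && ncol(trait_cor) == n_traits,
                "trait_cor must be n_traits x n_traits")
  } else {
    assert_that(is.numeric(trait_cor) && length(trait_cor) == 1L,
                "trait_cor must be a matrix or scalar")
    trait_cor <- matrix(trait_cor, n_traits, n_traits)
    diag(trait_cor) <- 1
  }
  assert_that(all(abs(diag(trait_cor) - 1) < 1e-12),
              "trait_cor must have unit diagonal")
  assert_that(is_spd(trait_cor), "trait_cor must be symmetric positive-definite")
  assert_that(is_count(n_causal) && n_causal <= n_markers,
              "n_causal must be a positive integer <= n_markers")
  assert_that(frac_pleiotropic >= 0 && frac_pleiotropic <= 1,
              "frac_pleiotropic must be in [0, 1]")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
    n_chrom = as.integer(n_chrom), n_traits = as.integer(n_traits),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    h2 = h2, trait_cor = trait_cor, n_causal = as.integer(n_causal),
    frac_pleiotropic = frac_pleiotropic, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## One AR(1) latent haplotype block, thresholded to allele indicators.
ar1_haplotype_block <- function(n, maf, rho) {
  b <- length(maf)
  z <- matrix(0, n, b)
  z[, 1] <- rnorm(n)
  if (b > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (j in 2:b) z[, j] <- rho * z[, j - 1] + innov_sd * rnorm(n)
  }
  thresh <- qnorm(1 - maf)
  sweep(z, 2, thresh, ">") * 1L
}

#' Simulate LD-blocked diploid genotypes
#'
#' Dosages in `{0, 1, 2}` are produced by thresholding two independent latent
#' AR(1) Gaussian haplotype processes per LD block (a Gaussian-copula LD
#' model), so within-block pairwise r2 decays with marker distance while
#' blocks are mutually independent.
#'
#' @param cfg a [sim_config()].
#' @return a `pleio_genotypes` object: list with `dosages` (samples x markers
#'   integer matrix, possibly with NA when `missing_rate > 0`), `markers`
#'   (data.frame with id, chrom, pos, ref, alt) and `samples`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 101L), {
    n <- cfg$n_samples; m <- cfg$n_markers
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    chrom_of <- rep(seq_len(cfg$n_chrom), length.out = m)
    chrom_of <- sort(chrom_of)
    dos <- matrix(0L, n, m)
    for (ch in seq_len(cfg$n_chrom)) {
      idx <- which(chrom_of == ch)
      starts <- seq(1L, length(idx), by = cfg$ld_block_size)
      for (s in starts) {
        blk <- idx[s:min(s + cfg$ld_block_size - 1L, length(idx))]
        h1 <- ar1_haplotype_block(n, maf[blk], cfg$ld_rho)
        h2 <- ar1_haplotype_block(n, maf[blk], cfg$ld_rho)
        dos[, blk] <- h1 + h2
      }
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n * m) < cfg$missing_rate, n, m)
      dos[miss] <- NA_integer_
    }
    pos <- integer(m)
    for (ch in seq_len(cfg$n_chrom)) {
      idx <- which(chrom_of == ch)
      pos[idx] <- seq_along(idx) * 1000L
    }
    markers <- data.frame(
      id = sprintf("snp%05d", seq_len(m)),
      chrom = paste0("chr", chrom_of),
      pos = pos,
      ref = "A", alt = "B",
      stringsAsFactors = FALSE
    )
    samples <- sprintf("ind%04d", seq_len(n))
    dimnames(dos) <- list(samples, markers$id)
    new_genotypes(dos, markers, samples)
  })
}

new_genotypes <- function(dosages, markers, samples) {
  assert_that(all(markers$id == colnames(dosages)),
              "marker table out of step with dosage columns")
  assert_that(!anyDuplicated(markers$id), "marker ids must be unique")
  structure(list(dosages = dosages, markers = markers, samples = samples),
            class = "pleio_genotypes")
}

#' @export
print.pleio_genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$markers$chrom))))
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat(sprintf("  %d missing calls\n", nmiss))
  invisible(x)
}

#' Tile gene models over simulated markers
#'
#' Groups consecutive markers on each chromosome into non-overlapping gene
#' bodies so that every gene carries a known set of markers; used to anchor
#' the gene-level statistics and the annotation generator.
#'
#' @param markers marker table (id, chrom, pos) as in a `pleio_genotypes`.
#' @param markers_per_gene number of consecutive markers per gene body.
#' @param pad bp added on each side of the outermost markers.
#' @return data.frame of gene models: gene, symbol, chrom, start, end, strand.
#' @export
simulate_gene_models <- function(markers, markers_per_gene = 5, pad = 100) {
  assert_that(is_count(markers_per_gene), "markers_per_gene must be positive")
  out <- list(); k <- 0L
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    starts <- seq(1L, length(idx), by = markers_per_gene)
    for (s in starts) {
      grp <- idx[s:min(s + markers_per_gene - 1L, length(idx))]
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = sprintf("GENE%04d", k), symbol = sprintf("SYM%04d", k),
        chrom = ch,
        start = max(1L, min(markers$pos[grp]) - as.integer(pad)),
        end = max(markers$pos[grp]) + as.integer(pad),
        strand = "+", stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate correlated pleiotropic traits
#'
#' Genetic values are built from randomly chosen causal markers; a fraction
#' of them (the pleiotropic loci) carry effects on every trait, the rest on a
#' single trait each. Correlated Gaussian noise is added and scaled per trait
#' so the realized heritability matches `cfg$h2`.
#'
#' @param G a `pleio_genotypes` object.
#' @param cfg the [sim_config()] used to generate `G`.
#' @param genes optional gene-model data.frame; when given, the truth lists
#'   the genes harboring the shared-effect markers.
#' @return list with `panel` (a `trait_panel`: traits matrix, covariates,
#'   trait names) and `truth` (causal marker table, pleiotropic marker ids,
#'   pleiotropic gene ids).
#' @export
simulate_traits <- function(G, cfg, genes = NULL) {
  stopifnot(inherits(G, "pleio_genotypes"), inherits(cfg, "sim_config"))
  assert_that(ncol(G$dosages) > 0 && nrow(G$dosages) > 0, "empty genotypes")
  with_seed(derive_seed(cfg$seed, 202L), {
    n <- nrow(G$dosages); m <- ncol(G$dosages); t <- cfg$n_traits
    causal <- sort(sample.int(m, cfg$n_causal))
    n_shared <- round(cfg$frac_pleiotropic * cfg$n_causal)
    shared <- causal[seq_len(n_shared)]
    specific <- setdiff(causal, shared)
    beta <- matrix(0, m, t)
    for (j in shared) beta[j, ] <- rnorm(t, mean = 0, sd = 1) +
      sign(rnorm(1)) * 0.5  # shared loci get a common directional component
    for (j in specific) beta[j, sample.int(t, 1)] <- rnorm(1)
    X <- G$dosages
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      na_idx <- which(is.na(X), arr.ind = TRUE)
      X[na_idx] <- mu[na_idx[, 2]]
    }
    Gval <- X[, causal, drop = FALSE] %*% beta[causal, , drop = FALSE]
    noise <- matrix(rnorm(n * t), n, t) %*% chol(cfg$trait_cor)
    traits <- matrix(0, n, t)
    for (k in seq_len(t)) {
      vg <- var(Gval[, k])
      if (cfg$h2[k] == 0 || vg == 0) {
        traits[, k] <- noise[, k]
      } else {
        ve <- vg * (1 - cfg$h2[k]) / cfg$h2[k]
        traits[, k] <- Gval[, k] + noise[, k] * sqrt(ve)
      }
    }
    trait_names <- sprintf("trait%02d", seq_len(t))
    dimnames(traits) <- list(G$samples, trait_names)
    effects <- data.frame(
      marker = rep(G$markers$id[causal], each = t),
      trait = rep(trait_names, length(causal)),
      effect = as.vector(t(beta[causal, , drop = FALSE])),
      stringsAsFactors = FALSE
    )
    effects <- effects[effects$effect != 0, ]
    pleio_markers <- G$markers$id[shared]
    pleio_genes <- character(0)
    if (!is.null(genes) && length(shared)) {
      mk <- G$markers[shared, ]
      hit <- vapply(seq_len(nrow(genes)), function(i) {
        any(mk$chrom == genes$chrom[i] &
            mk$pos >= genes$start[i] & mk$pos <= genes$end[i])
      }, logical(1))
      pleio_genes <- genes$gene[hit]
    }
    panel <- new_trait_panel(traits, covariates = NULL)
    truth <- list(causal_markers = effects,
                  pleiotropic_markers = pleio_markers,
                  pleiotropic_genes = pleio_genes,
                  genetic_values = Gval)
    list(panel = panel, truth = truth)
  })
}

new_trait_panel <- function(traits, covariates = NULL) {
  stopifnot(is.matrix(traits))
  if (!is.null(covariates)) {
    stopifnot(is.matrix(covariates), nrow(covariates) == nrow(traits))
  }
  structure(list(traits = traits, covariates = covariates,
                 trait_names = colnames(traits)),
            class = "trait_panel")
}

#' Simulate a modular expression matrix on the FPKM scale
#'
#' Genes assigned to a planted module share a latent sample factor; the
#' loading is chosen so the expected within-module Pearson correlation on the
#' log scale equals `within_cor`. Unassigned genes are independent noise.
#' Values are exponentiated to a non-negative FPKM-like scale.
#'
#' @param genes gene-model data.frame (only ids are used).
#' @param module_spec named integer vector: planted module -> gene count.
#' @param n_samples number of expression samples.
#' @param within_cor target within-module correlation, in (0, 1).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples FPKM matrix with gene lengths
#'   attribute) and `truth` (gene -> planted module labels; 0 = background).
#' @export
simulate_expression <- function(genes, module_spec, n_samples = 30,
                                within_cor = 0.8, seed = 1L) {
  assert_that(within_cor > 0 && within_cor < 1, "within_cor must be in (0, 1)")
  n_genes <- nrow(genes)
  assert_that(sum(module_spec) <= n_genes,
              "module gene counts exceed the gene universe")
  with_seed(derive_seed(seed, 303L), {
    labels <- rep(0L, n_genes)
    names(labels) <- genes$gene
    pos <- 1L
    for (k in seq_along(module_spec)) {
      cnt <- module_spec[[k]]
      labels[pos:(pos + cnt - 1L)] <- k
      pos <- pos + cnt
    }
    lam <- sqrt(within_cor)
    logx <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    if (length(module_spec)) {
      for (k in seq_along(module_spec)) {
        f <- rnorm(n_samples)
        rows <- which(labels == k)
        logx[rows, ] <- lam * matrix(f, length(rows), n_samples, byrow = TRUE) +
          sqrt(1 - within_cor) * matrix(rnorm(length(rows) * n_samples),
                                        length(rows), n_samples)
      }
    }
    base <- runif(n_genes, 2, 8)  # per-gene baseline log2 abundance
    fpkm <- pmax(2^(base + 1.5 * logx) - 1, 0)
    dimnames(fpkm) <- list(genes$gene, sprintf("smp%03d", seq_len(n_samples)))
    attr(fpkm, "gene_lengths") <- setNames(genes$end - genes$start + 1,
                                           genes$gene)
    attr(fpkm, "unit") <- "FPKM"
    list(expr = fpkm, truth = list(module_labels = labels))
  })
}

#' Simulate gene-set (GMT) annotation and a QTL interval track
#'
#' Terms sample member genes with probability proportional to 1 for
#' background genes and `bias` for the planted pleiotropic genes, so
#' `bias > 1` plants enriched terms. QTL intervals are placed so that a
#' stated fraction overlaps causal genes within a 100 kb window.
#'
#' @param genes gene-model data.frame.
#' @param truth truth list from [simulate_traits()] (uses `pleiotropic_genes`).
#' @param n_terms number of terms to emit.
#' @param term_size_range length-2 integer range of term sizes.
#' @param bias sampling multiplier (>= 1) for pleiotropic genes.
#' @param n_qtls number of QTL intervals.
#' @param qtl_frac_causal fraction of QTL intervals anchored on causal genes.
#' @param qtl_window_bp window used to anchor causal-gene QTLs.
#' @param seed integer seed.
#' @return list with `terms` (term -> gene-symbol sets plus descriptions) and
#'   `qtls` (data.frame: qtl_id, trait, trait_class, chrom, start, end).
#' @export
simulate_annotation <- function(genes, truth, n_terms = 40,
                                term_size_range = c(10, 40), bias = 5,
                                n_qtls = 30, qtl_frac_causal = 0.5,
                                qtl_window_bp = 100000, seed = 1L) {
  assert_that(bias >= 1, "bias must be >= 1")
  assert_that(max(term_size_range) <= nrow(genes),
              "term sizes exceed the gene universe")
  with_seed(derive_seed(seed, 404L), {
    syms <- genes$symbol
    pleio <- genes$symbol[genes$gene %in% truth$pleiotropic_genes]
    w <- ifelse(syms %in% pleio, bias, 1)
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    sets <- lapply(seq_len(n_terms), function(i) {
      sort(sample(syms, sizes[i], prob = w))
    })
    names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    desc <- setNames(sprintf("synthetic term %d", seq_len(n_terms)),
                     names(sets))
    n_causal_qtl <- round(qtl_frac_causal * n_qtls)
    causal_genes <- genes[genes$gene %in% truth$pleiotropic_genes, ,
                          drop = FALSE]
    qtl <- vector("list", n_qtls)
    for (i in seq_len(n_qtls)) {
      if (i <= n_causal_qtl && nrow(causal_genes) > 0) {
        g <- causal_genes[sample.int(nrow(causal_genes), 1), ]
        center <- round((g$start + g$end) / 2) +
          sample(seq(-qtl_window_bp, qtl_window_bp), 1)
        chrom <- g$chrom
      } else {
        g <- genes[sample.int(nrow(genes), 1), ]
        chrom <- g$chrom
        center <- g$start + sample.int(5e5, 1)
      }
      half <- sample(500:5000, 1)
      qtl[[i]] <- data.frame(
        qtl_id = sprintf("QTL%03d", i),
        trait = sprintf("qtl_trait%02d", 1 + (i - 1) %% 10),
        trait_class = ifelse(i %% 2 == 0, "milk", "health"),
        chrom = chrom, start = max(1, center - half), end = center + half,
        stringsAsFactors = FALSE
      )
    }
    qtls <- do.call(rbind, qtl)
    list(terms = list(sets = sets, descriptions = desc), qtls = qtls)
  })
}

#' Generate a complete synthetic fixture bundle
#'
#' Orchestrates the genotype, gene-model, trait, expression and annotation
#' generators into one coherent dataset with ground truth, suitable for
#' end-to-end pipeline runs.
#'
#' @param cfg a [sim_config()].
#' @param markers_per_gene markers tiled into each gene body.
#' @param module_spec planted expression modules (module -> gene count).
#' @param n_expr_samples expression sample count.
#' @param within_cor within-module expression correlation.
#' @param n_terms,term_size_range,bias,n_qtls annotation generator settings.
#' @return list: genotypes, genes, panel, expr, terms, qtls, truth, cfg.
#' @export
simulate_bundle <- function(cfg = sim_config(), markers_per_gene = 5,
                            module_spec = c(M1 = 60, M2 = 60, M3 = 60),
                            n_expr_samples = 30, within_cor = 0.8,
                            n_terms = 40, term_size_range = c(10, 40),
                            bias = 5, n_qtls = 30) {
  G <- simulate_genotypes(cfg)
  genes <- simulate_gene_models(G$markers, markers_per_gene)
  tr <- simulate_traits(G, cfg, genes)
  ex <- simulate_expression(genes, module_spec, n_expr_samples, within_cor,
                            seed = cfg$seed)
  an <- simulate_annotation(genes, tr$truth, n_terms, term_size_range, bias,
                            n_qtls = n_qtls, seed = cfg$seed)
  truth <- c(tr$truth, ex$truth,
             list(enriched_term_bias = bias,
                  planted_terms = names(an$terms$sets)))
  list(genotypes = G, genes = genes, panel = tr$panel, expr = ex$expr,
       terms = an$terms, qtls = an$qtls, truth = truth, cfg = cfg)
}
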