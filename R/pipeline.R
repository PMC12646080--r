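## End-to-end orchestration: configuration, structured logging, and the
## staged run from genotype QC to the prioritized gene list.

#' Pipeline configuration
#'
#' Stage parameters for [run_pipeline()], with the defaults used throughout
#' the package. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    maf_min = 0.01, call_rate_min = 0.95,
    gene_window_bp = 0, qtl_window_bp = 100000,
    fdr = 0.05,
    min_fpkm = 0.2, soft_power = NULL, target_fit = 0.8,
    min_module_size = 30, kmeans_iters = 20, cut_height = 0.9,
    n_walks = 10, walk_length = 80, return_weight = 0.25, inout_weight = 1,
    embed_dims = 32, embed_window = 32, embed_epochs = 20,
    k_grid_step = 100, k_grid_max = 5000,
    top_frac = 0.01, alpha = 0.05,
    em_tol = 1e-6, em_max_iter = 500,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_config("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = log_path, append = TRUE)
  invisible(entry)
}

#' Run the full prioritization pipeline on a fixture bundle
#'
#' Executes QC, the leave-one-chromosome-out association scan, the
#' multi-trait pleiotropy statistic, gene-level p-values, the signed
#' co-expression network with module detection, gene-set and QTL enrichment,
#' network embeddings with top-K diagnostics, the hierarchical EM model and
#' candidate prioritization. Every stage writes its artifact under
#' `out_dir` together with a JSONL log, the resolved configuration and a
#' checksum manifest.
#'
#' @param bundle_dir directory holding a fixture bundle
#'   (see [write_fixture_bundle()]), or a bundle list already in memory.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory results (gene scores,
#'   modules, fit, prioritization, curves, paths).
#' @export
run_pipeline <- function(bundle_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bundle <- if (is.character(bundle_dir)) read_fixture_bundle(bundle_dir)
            else bundle_dir
  t0 <- proc.time()[3]

  ## 1. genotype QC
  G <- qc_genotypes(bundle$genotypes, config$maf_min, config$call_rate_min)
  qc <- attr(G, "qc_report")
  log_stage(log_path, "qc", kept = qc$n_kept, removed_maf = qc$removed_maf,
            removed_call_rate = qc$removed_call_rate)

  ## 2. single-trait LOCO mixed-model scan
  stats <- mlma_loco(G, bundle$panel)
  log_stage(log_path, "mlma_loco", traits = length(stats$traits),
            markers = nrow(stats$beta))

  ## 3. multi-trait pleiotropy statistic
  V <- trait_correlation_matrix(stats)
  pleio <- pleiotropy_statistic(stats, V)
  write.table(pleio, file.path(out_dir, "pleiotropy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(log_path, "pleiotropy", markers = nrow(pleio), df = pleio$df[1])

  ## 4. gene-level p-values
  mapping <- map_snps_to_genes(G$markers, bundle$genes,
                               config$gene_window_bp)
  scores <- gene_level_pvalues(pleio, mapping, G, bundle$genes)
  write.table(scores, file.path(out_dir, "gene_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(log_path, "gene_scores", genes = nrow(scores))

  ## 5. co-expression network and modules
  expr <- filter_low_expression(bundle$expr, config$min_fpkm)
  beta <- config$soft_power %||%
    suppressWarnings(pick_soft_threshold(expr, target_fit = config$target_fit))
  adj <- signed_adjacency(expr, as.numeric(beta))
  tom <- compute_tom(adj)
  modules <- detect_modules(adj, tom, expr,
                            min_module_size = config$min_module_size,
                            kmeans_iters = config$kmeans_iters,
                            cut_height = config$cut_height,
                            seed = config$seed)
  write.table(data.frame(gene = names(modules$labels),
                         module = modules$labels),
              file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage(log_path, "wgcn", beta = as.numeric(beta),
            modules = ncol(modules$eigengenes), genes = nrow(adj))

  ## 6. enrichment: per-module gene sets and QTL windows
  sym_of <- setNames(bundle$genes$symbol, bundle$genes$gene)
  wgcn_genes <- rownames(adj)
  wgcn_syms <- toupper(sym_of[wgcn_genes])
  wgcn_syms <- wgcn_syms[!is.na(wgcn_syms) & nzchar(wgcn_syms)]
  mod_adjs <- module_adjacencies(adj, modules)
  enriched_all <- list()
  for (m in names(mod_adjs)) {
    qsym <- toupper(sym_of[rownames(mod_adjs[[m]])])
    qsym <- qsym[!is.na(qsym) & nzchar(qsym)]
    et <- hypergeom_enrich(qsym, bundle$terms, wgcn_syms, config$fdr)
    et$module <- m
    enriched_all[[m]] <- et
  }
  enrich_tab <- do.call(rbind, enriched_all)
  write.table(enrich_tab, file.path(out_dir, "term_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enriched_terms <- unique(enrich_tab$term[enrich_tab$enriched])
  universe_genes <- bundle$genes[bundle$genes$gene %in% scores$gene, ,
                                 drop = FALSE]
  bg_ann <- annotate_qtls(universe_genes, bundle$qtls, config$qtl_window_bp)
  wgcn_models <- bundle$genes[bundle$genes$gene %in% wgcn_genes, ,
                              drop = FALSE]
  q_ann <- annotate_qtls(wgcn_models, bundle$qtls, config$qtl_window_bp)
  qtl_tab <- qtl_enrich(q_ann, bg_ann, universe_genes$gene,
                        wgcn_models$gene, config$fdr)
  write.table(qtl_tab, file.path(out_dir, "qtl_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(log_path, "enrichment",
            enriched_terms = length(enriched_terms),
            enriched_qtl_traits = sum(qtl_tab$enriched))

  ## 7. incidence matrices for the gene-term networks
  networks <- mod_adjs
  if (length(enriched_terms)) {
    sets <- bundle$terms$sets[enriched_terms]
    inc_terms <- build_incidence(wgcn_syms, sets)
    if (nrow(inc_terms) > 0 && ncol(inc_terms) > 0) {
      networks$terms <- inc_terms
    }
  }
  enr_traits <- qtl_tab$trait[qtl_tab$enriched]
  if (length(enr_traits)) {
    q_sets <- lapply(enr_traits, function(tr) {
      g <- unique(q_ann$gene[q_ann$trait == tr])
      toupper(sym_of[g])
    })
    names(q_sets) <- paste0("QTLTRAIT_", enr_traits)
    inc_q <- build_incidence(wgcn_syms, q_sets)
    if (nrow(inc_q) > 0 && ncol(inc_q) > 0) networks$qtl <- inc_q
  }

  ## map adjacency gene ids to symbols so all networks share the symbol space
  for (m in names(mod_adjs)) {
    a <- networks[[m]]
    sy <- toupper(sym_of[rownames(a)])
    keep <- !is.na(sy) & nzchar(sy)
    a <- a[keep, keep, drop = FALSE]
    dimnames(a) <- list(sy[keep], sy[keep])
    networks[[m]] <- a
  }

  ## 8. embeddings and top-K diagnostics
  ranking_sym <- toupper(sym_of[scores$gene[order(scores$p)]])
  ranking_sym <- ranking_sym[!is.na(ranking_sym) & nzchar(ranking_sym)]
  k_grid <- seq(config$k_grid_step, config$k_grid_max,
                by = config$k_grid_step)
  embeddings <- list()
  curves <- list()
  for (i in seq_along(networks)) {
    nm <- names(networks)[i]
    net <- networks[[i]]
    g <- build_walk_graph(net)
    wcfg <- walk_config(config$n_walks, config$walk_length,
                        config$return_weight, config$inout_weight,
                        seed = derive_seed(config$seed, 700L + i))
    walks <- biased_random_walks(g, wcfg)
    emb <- suppressWarnings(
      skipgram_embed(walks, dims = config$embed_dims,
                     window = config$embed_window,
                     epochs = config$embed_epochs,
                     seed = derive_seed(config$seed, 800L + i)))
    embeddings[[nm]] <- emb
    is_gene_node <- igraph::V(g)$is_gene
    gene_nodes <- igraph::V(g)$name[is_gene_node]
    rk <- ranking_sym[ranking_sym %in% gene_nodes]
    if (nm %in% names(mod_adjs)) {
      if (length(rk) >= 2) {
        curves[[paste0("wed_", nm)]] <- wed_topk(net, rk, k_grid)
      }
    } else if (length(rk) >= 1) {
      bsc <- betweenness_scores(g)
      curves[[paste0("betweenness_", nm)]] <-
        mean_betweenness_topk(bsc[gene_nodes], rk, k_grid)
    }
    write_matrix_tsv(emb, file.path(out_dir,
                                    paste0("embedding_", nm, ".tsv")),
                     "node")
  }
  if (length(curves)) {
    curve_tab <- do.call(rbind, lapply(names(curves), function(nm) {
      data.frame(network = nm, curves[[nm]], stringsAsFactors = FALSE)
    }))
    write.table(curve_tab, file.path(out_dir, "topk_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  log_stage(log_path, "embedding", networks = length(networks))

  ## 9. representation learning + hierarchical EM
  gene_p <- setNames(scores$p, toupper(scores$symbol))
  gene_p <- gene_p[!is.na(names(gene_p)) & nzchar(names(gene_p))]
  soft <- fit_null_mixture(pmax(gene_p, 1e-300))
  reductions <- list()
  for (nm in names(embeddings)) {
    emb <- embeddings[[nm]]
    gene_rows <- intersect(rownames(emb), names(gene_p))
    if (length(gene_rows) < 10) next
    labs <- soft$ppa[match(gene_rows, names(gene_p))]
    if (var(labs) == 0) next
    reductions[[nm]] <- tryCatch(lda_reduce(emb[gene_rows, , drop = FALSE],
                                            labs),
                                 error = function(e) NULL)
  }
  reductions <- reductions[!vapply(reductions, is.null, logical(1))]
  assert_that(length(reductions) >= 1, "no network produced usable features")
  features <- assemble_features(reductions, names(gene_p))
  fit <- em_hierarchical(gene_p, features, tol = config$em_tol,
                         max_iter = config$em_max_iter)
  log_stage(log_path, "em", iterations = fit$iterations,
            converged = fit$converged, a = fit$a)

  ## 10. prioritization
  scores_sym <- scores
  scores_sym$gene <- toupper(scores_sym$symbol)
  scores_sym <- scores_sym[!is.na(scores_sym$gene) &
                             nzchar(scores_sym$gene), , drop = FALSE]
  pri <- prioritize(fit, scores_sym, top_frac = config$top_frac,
                    alpha = config$alpha)
  write.table(pri$table, file.path(out_dir, "ppa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(a = fit$a, beta0 = fit$beta0, beta = as.list(fit$beta),
         loglik = fit$loglik, converged = fit$converged),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "prioritize", retained = length(pri$prioritized),
            significant = length(pri$prioritized_significant),
            elapsed_s = round(proc.time()[3] - t0, 1))

  out_files <- list.files(out_dir, full.names = TRUE)
  out_files <- out_files[!grepl("manifest\\.json$", out_files)]
  manifest <- data.frame(file = basename(out_files),
                         md5 = unname(tools::md5sum(out_files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = G, pleio = pleio, scores = scores,
                 modules = modules, enrichment = enrich_tab,
                 qtl_enrichment = qtl_tab, networks = networks,
                 embeddings = embeddings, curves = curves, fit = fit,
                 prioritization = pri, out_dir = out_dir))
}
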