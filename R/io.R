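## Readers and writers for the interchange formats: VCF 4.2 genotypes, TSV
## dosage/trait/expression matrices, BED gene and QTL tracks, GMT gene sets,
## and the JSON-described fixture bundle.

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: GT fields are converted to dosages 0/1/2 (missing "./." flagged as
#' NA); multi-allelic records are rejected with the locus named. TSV dialect:
#' columns `chrom, pos, id, ref, alt` followed by one column per sample.
#'
#' @param path input file.
#' @param format "vcf" or "tsv" (guessed from the extension by default).
#' @return a `pleio_genotypes`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    fx <- matrix(fx, ncol = ncol(vcfR::getFIX(v)),
                 dimnames = dimnames(vcfR::getFIX(v)))
    multi <- grepl(",", fx[, "ALT"])
    if (any(multi)) {
      stop("multi-allelic record(s) not supported: ",
           paste(head(paste0(fx[multi, "CHROM"], ":", fx[multi, "POS"]), 3),
                 collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(as.integer(alleles))
    })
    dos <- t(dos)  # samples x markers
    markers <- data.frame(
      id = unname(fx[, "ID"]), chrom = unname(fx[, "CHROM"]),
      pos = as.integer(fx[, "POS"]),
      ref = unname(fx[, "REF"]), alt = unname(fx[, "ALT"]),
      stringsAsFactors = FALSE
    )
    colnames(dos) <- markers$id
    new_genotypes(dos, markers, rownames(dos))
  } else {
    d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "id", "ref", "alt")
    assert_that(all(need %in% colnames(d)),
                "dosage TSV must carry columns chrom, pos, id, ref, alt")
    samp <- setdiff(colnames(d), need)
    dos <- t(as.matrix(d[, samp, drop = FALSE]))
    storage.mode(dos) <- "integer"
    markers <- data.frame(id = d$id, chrom = d$chrom, pos = as.integer(d$pos),
                          ref = d$ref, alt = d$alt, stringsAsFactors = FALSE)
    colnames(dos) <- markers$id
    new_genotypes(dos, markers, samp)
  }
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' @param G a `pleio_genotypes`.
#' @param path output path.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "pleio_genotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(G$dosages))) {
    d <- G$dosages[, j]
    g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(G$markers$chrom[j], G$markers$pos[j], G$markers$id[j],
                       G$markers$ref[j], G$markers$alt[j], ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive
#' coordinates; GFF3 `gene` features are taken as-is (already 1-based) with
#' the symbol from the `Name` attribute. Genes without a name keep an empty
#' symbol and are retained.
#'
#' @param path input file.
#' @param format "bed" or "gff3" (guessed from the extension by default).
#' @return gene-model data.frame: gene, symbol, chrom, start, end, strand.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "bed"
  }
  if (format == "bed") {
    d <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
    assert_that(ncol(d) >= 4, "BED needs at least 4 columns (name required)")
    out <- data.frame(
      gene = d[[4]],
      symbol = if (ncol(d) >= 7) d[[7]] else d[[4]],
      chrom = d[[1]],
      start = as.integer(d[[2]]) + 1L,  # 0-based half-open -> 1-based
      end = as.integer(d[[3]]),
      strand = if (ncol(d) >= 6) d[[6]] else "+",
      stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, integer(1)) >= 9]
    f <- f[vapply(f, function(x) x[3] == "gene", logical(1))]
    assert_that(length(f) > 0, "no gene features in GFF3")
    attr_get <- function(s, key) {
      m <- regmatches(s, regexec(paste0("(^|;)", key, "=([^;]+)"), s))[[1]]
      if (length(m) >= 3) m[3] else ""
    }
    out <- do.call(rbind, lapply(f, function(x) {
      data.frame(
        gene = {
          id <- attr_get(x[9], "ID")
          if (nzchar(id)) id else attr_get(x[9], "Name")
        },
        symbol = attr_get(x[9], "Name"),
        chrom = x[1], start = as.integer(x[4]), end = as.integer(x[5]),
        strand = x[7], stringsAsFactors = FALSE
      )
    }))
  }
  bad <- out$end < out$start
  if (any(bad)) {
    stop("gene interval with end < start after conversion: ",
         paste(head(out$gene[bad], 3), collapse = ", "))
  }
  out
}

#' Write gene models (or QTL intervals) as BED
#'
#' Internal 1-based inclusive coordinates are converted to the BED 0-based
#' half-open convention. Extra columns (score placeholder, strand, symbol or
#' trait metadata) follow the name.
#'
#' @param x gene-model data.frame or QTL data.frame.
#' @param path output path.
#' @param what "genes" or "qtls".
#' @export
write_bed <- function(x, path, what = c("genes", "qtls")) {
  what <- match.arg(what)
  if (what == "genes") {
    d <- data.frame(x$chrom, x$start - 1L, x$end, x$gene, 0L, x$strand,
                    x$symbol)
  } else {
    if (nrow(x) == 0) {
      file.create(path)
      return(invisible(path))
    }
    d <- data.frame(x$chrom, x$start - 1L, x$end, x$qtl_id, 0L, "+",
                    x$trait, x$trait_class)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a QTL track from a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, qtl_id, score, strand, trait,
#' trait_class. Start coordinates are converted to 1-based inclusive and
#' clamped at 1.
#'
#' @param path input path.
#' @return QTL data.frame (qtl_id, trait, trait_class, chrom, start, end).
#' @export
read_qtl_track <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(qtl_id = character(0), trait = character(0),
                      trait_class = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  assert_that(ncol(d) >= 8, "QTL track needs 8 columns")
  data.frame(qtl_id = d[[4]], trait = d[[7]], trait_class = d[[8]],
             chrom = d[[1]], start = pmax(as.integer(d[[2]]) + 1L, 1L),
             end = as.integer(d[[3]]), stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: term id, description, member gene symbols. Duplicate
#' members within a line are deduplicated; duplicate term ids or lines
#' without members are errors.
#'
#' @param path input path.
#' @return list with `sets` (term -> unique gene symbols) and `descriptions`.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(f, length, integer(1)) < 3
  if (any(short)) {
    stop("GMT line(s) without member genes (line ",
         paste(head(which(short), 3), collapse = ", "), ")")
  }
  ids <- vapply(f, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  sets <- lapply(f, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  desc <- setNames(vapply(f, `[[`, character(1), 2), ids)
  list(sets = sets, descriptions = desc)
}

#' Write a GMT gene-set file
#'
#' @param terms list with `sets` and optional `descriptions`.
#' @param path output path.
#' @export
write_gmt <- function(terms, path) {
  sets <- if (!is.null(terms$sets)) terms$sets else terms
  desc <- terms$descriptions %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(tm) {
    paste(c(tm, desc[[tm]], sets[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## matrix <-> TSV with a leading id column
write_matrix_tsv <- function(m, path, id_col = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d)[1] <- id_col
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a complete fixture bundle to disk
#'
#' Serializes a [simulate_bundle()] result: VCF genotypes, TSV trait and
#' expression matrices, BED gene models and QTL track, GMT terms, JSON truth
#' and config, plus a manifest with per-file MD5 checksums.
#'
#' @param bundle list from [simulate_bundle()].
#' @param dir output directory (created when absent).
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  assert_that(file.access(dir, 2) == 0, "directory not writable: ", dir)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    traits = file.path(dir, "traits.tsv"),
    expression = file.path(dir, "expression.tsv"),
    genes = file.path(dir, "genes.bed"),
    qtls = file.path(dir, "qtls.bed"),
    terms = file.path(dir, "terms.gmt"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  write_vcf(bundle$genotypes, paths["genotypes"])
  write_matrix_tsv(bundle$panel$traits, paths["traits"], "sample")
  expr_out <- cbind(length = attr(bundle$expr, "gene_lengths"), bundle$expr)
  write_matrix_tsv(expr_out, paths["expression"], "gene")
  write_bed(bundle$genes, paths["genes"], "genes")
  write_bed(bundle$qtls, paths["qtls"], "qtls")
  write_gmt(bundle$terms, paths["terms"])
  truth <- bundle$truth
  truth$genetic_values <- NULL  # large and derivable; keep the labels only
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  cfg <- unclass(bundle$cfg)
  cfg$trait_cor <- as.vector(cfg$trait_cor)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture bundle back from disk
#'
#' @param dir bundle directory written by [write_fixture_bundle()].
#' @return list mirroring [simulate_bundle()] (without genetic values).
#' @export
read_fixture_bundle <- function(dir) {
  assert_that(dir.exists(dir), "bundle directory not found: ", dir)
  G <- read_genotypes(file.path(dir, "genotypes.vcf"))
  traits <- read_matrix_tsv(file.path(dir, "traits.tsv"))
  exprm <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  lengths <- exprm[, 1]
  expr <- exprm[, -1, drop = FALSE]
  attr(expr, "gene_lengths") <- lengths
  attr(expr, "unit") <- "FPKM"
  genes <- read_gene_models(file.path(dir, "genes.bed"), "bed")
  qtls <- read_qtl_track(file.path(dir, "qtls.bed"))
  terms <- read_gmt(file.path(dir, "terms.gmt"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- sim_config(
    n_samples = cfg_raw$n_samples, n_markers = cfg_raw$n_markers,
    n_chrom = cfg_raw$n_chrom, n_traits = cfg_raw$n_traits,
    maf_range = cfg_raw$maf_range, ld_block_size = cfg_raw$ld_block_size,
    ld_rho = cfg_raw$ld_rho, h2 = cfg_raw$h2,
    trait_cor = matrix(cfg_raw$trait_cor, cfg_raw$n_traits),
    n_causal = cfg_raw$n_causal,
    frac_pleiotropic = cfg_raw$frac_pleiotropic,
    missing_rate = cfg_raw$missing_rate, seed = cfg_raw$seed
  )
  list(genotypes = G, genes = genes,
       panel = new_trait_panel(traits),
       expr = expr, terms = terms, qtls = qtls, truth = truth, cfg = cfg)
}
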