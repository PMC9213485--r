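.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Default genotype call symbols
#'
#' The on-disk dialect for genotype files: line-1 homozygotes `A`,
#' heterozygotes `H`, line-2 homozygotes `B`; missing calls are written as
#' the `missing` string of the reader/writer (default `NA`).
#'
#' @return Named character vector over HOM1/HET/HOM2.
#' @export
geno_dialect <- function() c(HOM1 = "A", HET = "H", HOM2 = "B")

#' Read a genotype matrix from delimited files
#'
#' Expects a wide marker-by-individual table (first column marker ids,
#' remaining columns one per individual) and a separate map file with
#' columns `marker_id`, `chr`, `bp` and optionally `cM`.  The separator is
#' inferred from the extension (`.csv` comma, otherwise tab).  Any call
#' symbol outside the dialect is rejected with the offending marker and
#' individual named.
#'
#' @param path Genotype file.
#' @param map_path Map file.
#' @param dialect Named symbols as in [geno_dialect()].
#' @param missing String representing missing calls (default "NA").
#' @return A [genotype_matrix()], markers sorted by (chromosome, bp).
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, map_path, dialect = geno_dialect(),
                           missing = "NA") {
  sep <- .sep_for(path)
  g <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                  colClasses = "character", na.strings = missing,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g[[1L]]))
    stop("duplicate marker id in ", path, ": ",
         paste(unique(g[[1L]][duplicated(g[[1L]])]), collapse = ", "))
  mp <- read.table(map_path, header = TRUE, sep = .sep_for(map_path),
                   stringsAsFactors = FALSE)
  map <- marker_map(mp$marker_id, mp$chr, mp$bp, mp$cM)
  sym <- g[, -1L, drop = FALSE]
  bad <- which(matrix(!(as.matrix(sym) %in% c(dialect, NA)), nrow(sym)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid call symbol '%s' at marker '%s', individual '%s'",
                 sym[bad[1, 1], bad[1, 2]], g[[1L]][bad[1, 1]],
                 colnames(sym)[bad[1, 2]]))
  code <- setNames(.class_codes[names(dialect)], dialect)
  calls <- matrix(code[as.matrix(sym)], nrow = nrow(sym))
  calls <- t(calls)  # individuals x markers
  dimnames(calls) <- list(colnames(sym), g[[1L]])
  genotype_matrix(calls, map)
}

#' Write a genotype matrix to delimited files
#'
#' Inverse of [read_genotypes()]; a write-then-read round trip returns an
#' identical matrix.
#'
#' @param geno A [genotype_matrix()].
#' @param path,map_path Output files (extension decides the separator).
#' @param dialect,missing As in [read_genotypes()].
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(geno, path, map_path, dialect = geno_dialect(),
                            missing = "NA") {
  stopifnot(inherits(geno, "geno"))
  sym <- setNames(dialect[names(.class_codes)], .class_codes)
  m <- matrix(sym[as.character(geno$calls)], nrow = nrow(geno$calls))
  m[is.na(m)] <- missing
  out <- data.frame(marker_id = colnames(geno$calls),
                    t(m), check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("marker_id", rownames(geno$calls))
  write.table(out, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  write.table(geno$map, map_path, sep = .sep_for(map_path), quote = FALSE,
              row.names = FALSE)
  invisible(c(path, map_path))
}

#' Read or write a phenotype table
#'
#' Delimited file with columns `individual_id`, `sex`, `subfamily`,
#' `litter_size`, then one column per trait.
#'
#' @param path File path.
#' @return For the reader, a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = .sep_for(path),
                  stringsAsFactors = FALSE)
  fixed <- c("individual_id", "sex", "subfamily", "litter_size")
  miss <- setdiff(fixed, names(d))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  phenotype_table(d$individual_id, d$sex, d$subfamily, d$litter_size,
                  d[, setdiff(names(d), fixed), drop = FALSE])
}

#' @rdname read_phenotypes
#' @param pheno A [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read or write an expression matrix
#'
#' Delimited file: first column feature ids, remaining columns samples.
#' Group labels are not stored in the file and must be supplied on read.
#'
#' @param path File path.
#' @param groups Group labels for the samples (two levels).
#' @param log2_transformed Whether the stored values are log2 scale.
#' @return For the reader, an [expression_matrix()].
#' @export
read_expression <- function(path, groups, log2_transformed = FALSE) {
  d <- read.table(path, header = TRUE, sep = .sep_for(path),
                  check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(d[, -1L, drop = FALSE])
  rownames(x) <- d[[1L]]
  expression_matrix(x, groups, log2_transformed)
}

#' @rdname read_expression
#' @param expr An [expression_matrix()].
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(feature = rownames(expr$intensities), expr$intensities,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Mapping from VEP consequence terms to scoring categories
#'
#' Translates Ensembl Variant Effect Predictor consequence terms into the
#' coding-consequence and regulatory-feature categories of the decision
#' tree.  Terms absent from this table are treated as out of scope
#' (`none`/`none`) and counted in the reader's skip log.
#'
#' @return Data frame with columns `term`, `consequence`, `regulatory`.
#' @export
vep_consequence_mapping <- function() {
  data.frame(
    term = c("stop_gained", "stop_lost", "missense_variant",
             "stop_gain", "stop_loss", "missense",
             "splice_acceptor_variant", "splice_donor_variant",
             "splice_region_variant", "splice_site",
             "5_prime_UTR_variant", "3_prime_UTR_variant", "utr",
             "promoter", "promoter_variant",
             "enhancer", "enhancer_variant",
             "CTCF_binding_site_variant", "ctcf_binding_site"),
    consequence = c("stop_gain", "stop_loss", "missense",
                    "stop_gain", "stop_loss", "missense",
                    rep("none", 13)),
    regulatory = c(rep("none", 6),
                   rep("splice_site", 4),
                   rep("utr", 3),
                   rep("promoter", 2),
                   rep("enhancer", 2),
                   rep("ctcf_binding_site", 2)),
    stringsAsFactors = FALSE)
}

.normalize_sift <- function(sift, consequence) {
  s <- tolower(sub("\\(.*$", "", trimws(as.character(sift))))
  s[grepl("^deleterious", s)] <- "deleterious"
  s[grepl("^tolerated", s)] <- "tolerated"
  s[!s %in% c("deleterious", "tolerated")] <- "n/a"
  s[consequence != "missense"] <- "n/a"
  s
}

#' Read a variant annotation table
#'
#' Accepts either a delimited table with at least `gene_symbol` and
#' `consequence` columns (plus optional `gene_id`, `chr`, `bp`, `sift`,
#' `in_domain`, `regulatory`), or a VEP-annotated VCF (`.vcf`) whose CSQ
#' INFO field supplies gene symbol, consequence terms, and SIFT class
#' (parsed with the vcfR package).  Consequence terms are translated
#' through [vep_consequence_mapping()]; unmapped terms become
#' (`none`, `none`) and are counted in the skip log (attribute
#' `"n_skipped_terms"`, also reported via `message()`).
#'
#' @param path Input file.
#' @param mapping Term mapping table (default [vep_consequence_mapping()]).
#' @return A [variant_annotation_table()].
#' @export
read_variant_annotations <- function(path, mapping = vep_consequence_mapping()) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    return(.read_annotations_vcf(path, mapping))
  d <- read.table(path, header = TRUE, sep = .sep_for(path),
                  stringsAsFactors = FALSE)
  if (is.null(d$gene_symbol) && !is.null(d$gene)) d$gene_symbol <- d$gene
  need <- c("gene_symbol", "consequence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  .assemble_annotations(
    gene_id = if (!is.null(d$gene_id)) d$gene_id else d$gene_symbol,
    gene_symbol = d$gene_symbol,
    chr = if (!is.null(d$chr)) as.character(d$chr) else "1",
    bp = if (!is.null(d$bp)) d$bp else seq_len(nrow(d)),
    term = d$consequence,
    sift = if (!is.null(d$sift)) d$sift else "n/a",
    in_domain = if (!is.null(d$in_domain)) d$in_domain else FALSE,
    regulatory = if (!is.null(d$regulatory)) d$regulatory else NA_character_,
    mapping = mapping)
}

.assemble_annotations <- function(gene_id, gene_symbol, chr, bp, term, sift,
                                  in_domain, regulatory, mapping) {
  n <- length(term)
  idx <- match(term, mapping$term)
  consequence <- ifelse(is.na(idx), "none", mapping$consequence[idx])
  reg_from_term <- ifelse(is.na(idx), "none", mapping$regulatory[idx])
  reg_lv <- c("promoter", "splice_site", "utr", "enhancer",
              "ctcf_binding_site", "none")
  regulatory <- rep_len(as.character(regulatory), n)
  regulatory <- ifelse(!is.na(regulatory) & regulatory %in% reg_lv,
                       regulatory, reg_from_term)
  skipped <- is.na(idx) & !(term %in% c("none")) & regulatory == "none"
  if (any(skipped))
    message(sum(skipped), " annotation row(s) with out-of-scope consequence term(s): ",
            paste(unique(term[skipped]), collapse = ", "))
  consequence_is_mis <- consequence == "missense"
  out <- variant_annotation_table(data.frame(
    gene_id = rep_len(as.character(gene_id), n),
    gene_symbol = as.character(gene_symbol),
    chr = rep_len(as.character(chr), n),
    bp = rep_len(as.integer(bp), n),
    consequence = consequence,
    sift = .normalize_sift(rep_len(sift, n), consequence),
    in_domain = rep_len(as.logical(in_domain), n) & consequence_is_mis,
    regulatory = regulatory,
    stringsAsFactors = FALSE))
  attr(out, "n_skipped_terms") <- sum(skipped)
  out
}

# VEP-annotated VCF: one annotation row per (variant, transcript,
# consequence term) using the CSQ INFO field.
.read_annotations_vcf <- function(path, mapping) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF annotations requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcfR::queryMETA(v, element = "INFO=<ID=CSQ")
  if (!length(meta)) stop("VCF lacks a CSQ (VEP consequence) INFO field")
  fmt <- grep("Format: ", unlist(meta), value = TRUE)[1L]
  fields <- strsplit(sub(".*Format: ?", "", fmt), "\\|")[[1L]]
  fields <- trimws(sub("['\">]+$", "", fields))
  info <- vcfR::extract.info(v, element = "CSQ")
  fix <- vcfR::getFIX(v)
  rows <- list()
  for (i in seq_along(info)) {
    if (is.na(info[i])) next
    for (tx in strsplit(info[i], ",")[[1L]]) {
      parts <- strsplit(tx, "\\|")[[1L]]
      parts <- c(parts, rep("", max(0, length(fields) - length(parts))))
      names(parts) <- fields
      sym <- if (nzchar(parts["SYMBOL"])) parts["SYMBOL"] else parts["Gene"]
      if (!nzchar(sym) || is.na(sym)) next
      for (term in strsplit(parts["Consequence"], "&")[[1L]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = if (nzchar(parts["Gene"])) parts["Gene"] else sym,
          gene_symbol = sym, chr = fix[i, "CHROM"],
          bp = as.integer(fix[i, "POS"]), term = term,
          sift = if ("SIFT" %in% fields) parts["SIFT"] else "n/a",
          in_domain = "DOMAINS" %in% fields && nzchar(parts["DOMAINS"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no gene annotations found in ", path)
  d <- do.call(rbind, rows)
  .assemble_annotations(d$gene_id, d$gene_symbol, d$chr, d$bp, d$term,
                        d$sift, d$in_domain, NA_character_, mapping)
}

#' Convert QTL regions to BED intervals and back
#'
#' In-memory coordinates are 1-based inclusive bp; BED is 0-based
#' half-open, so a region (start, stop) becomes the BED line
#' (start - 1, stop).  `bed_to_regions()` recovers the original bp values.
#'
#' @param regions A [call_qtl_regions()] data frame.
#' @return `regions_to_bed()`: data.frame with chrom, chromStart,
#'   chromEnd, name, score.
#' @export
regions_to_bed <- function(regions) {
  data.frame(chrom = regions$chr,
             chromStart = regions$start_bp - 1L,
             chromEnd = regions$stop_bp,
             name = paste(regions$trait, regions$top_marker, sep = ":"),
             score = regions$top_lod,
             stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @param bed Data frame as produced by `regions_to_bed()` or read from a
#'   BED file.
#' @export
bed_to_regions <- function(bed) {
  data.frame(chr = as.character(bed[[1L]]),
             start_bp = as.integer(bed[[2L]]) + 1L,
             stop_bp = as.integer(bed[[3L]]),
             stringsAsFactors = FALSE)
}

#' Write pipeline outputs to a directory
#'
#' Writes whichever results are supplied: the per-marker scan table as TSV
#' (marker, chr, bp, class counts, raw and corrected p/LOD, adjusted class
#' means, partial R2), QTL regions as TSV and BED, the correlation matrix,
#' the DE table, gene scores as TSV sorted by descending total, and a JSON
#' run log capturing the configuration, seed, per-scan lambda and the LOD
#' thresholds used.
#'
#' @param out_dir Output directory (created if absent; unwritable
#'   locations raise an error).
#' @param scans List of `"scan_result"` objects (or a single one).
#' @param regions Optional region data frame.
#' @param correlation Optional `"cor_matrix"`.
#' @param de Optional `"de_result"`.
#' @param scores Optional `"gene_score"` table.
#' @param config A [run_config()] recorded in the run log.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(out_dir, scans = NULL, regions = NULL,
                          correlation = NULL, de = NULL, scores = NULL,
                          config = run_config()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  paths <- character()
  wt <- function(d, name) {
    p <- file.path(out_dir, name)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(scans, "scan_result")) scans <- list(scans)
  for (s in scans) wt(s$table, sprintf("scan_%s.tsv", s$trait))
  if (!is.null(regions)) {
    wt(as.data.frame(regions), "qtl_regions.tsv")
    bed <- regions_to_bed(regions)
    p <- file.path(out_dir, "qtl_regions.bed")
    write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(correlation)) {
    wt(data.frame(trait = rownames(correlation$rho), correlation$rho,
                  check.names = FALSE), "correlation_rho.tsv")
    wt(data.frame(trait = rownames(correlation$p), correlation$p,
                  check.names = FALSE), "correlation_p.tsv")
  }
  if (!is.null(de)) wt(as.data.frame(de), "differential_expression.tsv")
  if (!is.null(scores)) wt(rank_genes(scores), "gene_scores.tsv")
  log <- list(config = unclass(config),
              scans = lapply(scans, function(s) list(
                trait = s$trait, lambda = s$lambda,
                lambda_applied = s$lambda_applied, meff = s$meff,
                thresholds = s$thresholds, covariates = s$covariates,
                cofactor = s$cofactor)))
  p <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
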