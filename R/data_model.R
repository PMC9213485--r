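# Genotype calls are stored as the count of line-1 (e.g. BFMI861-S1) alleles:
# 2 = homozygous line 1, 1 = heterozygous, 0 = homozygous line 2, NA = missing.
GENO_HOM1 <- 2L
GENO_HET <- 1L
GENO_HOM2 <- 0L

#' Genotype class labels
#'
#' Ordered labels for the three genotype classes at a biallelic marker in a
#' two-founder cross: homozygous for the line-1 allele, heterozygous,
#' homozygous for the line-2 allele.
#'
#' @return Character vector `c("HOM1", "HET", "HOM2")`.
#' @export
geno_classes <- function() c("HOM1", "HET", "HOM2")

# allele-count code for each class label, in geno_classes() order
.class_codes <- c(HOM1 = 2L, HET = 1L, HOM2 = 0L)

CHROM_LEVELS <- c(as.character(1:19), "X")

#' Construct a marker map
#'
#' A marker map records, for each SNP marker, its chromosome and 1-based
#' physical position (MM10 coordinates in the motivating data).  An optional
#' genetic position in centimorgans may be carried; when absent it can be
#' interpolated from physical position at a fixed cM/Mb rate.
#'
#' @param marker_id Character vector of unique marker names.
#' @param chr Chromosome labels ("1"--"19", "X"); coerced to character.
#' @param bp Integer 1-based physical positions.
#' @param cM Optional numeric genetic positions (centimorgans).
#' @return A `data.frame` with columns `marker_id`, `chr`, `bp` (and `cM`
#'   when supplied), sorted by chromosome then position.
#' @export
marker_map <- function(marker_id, chr, bp, cM = NULL) {
  marker_id <- as.character(marker_id)
  chr <- as.character(chr)
  bp <- as.integer(bp)
  if (anyDuplicated(marker_id))
    stop("duplicate marker ids: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  if (!all(chr %in% CHROM_LEVELS))
    stop("unknown chromosome label(s): ",
         paste(setdiff(unique(chr), CHROM_LEVELS), collapse = ", "))
  if (any(bp < 1L)) stop("position_bp must be >= 1")
  if (anyDuplicated(paste(chr, bp)))
    stop("duplicate (chromosome, bp) pairs in map")
  map <- data.frame(marker_id = marker_id, chr = chr, bp = bp,
                    stringsAsFactors = FALSE)
  if (!is.null(cM)) map$cM <- as.numeric(cM)
  ord <- order(match(map$chr, CHROM_LEVELS), map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  if (!is.null(map$cM)) {
    bad <- tapply(seq_len(nrow(map)), map$chr, function(i) {
      is.unsorted(map$cM[i][!is.na(map$cM[i])])
    })
    if (any(unlist(bad)))
      stop("cM positions must be non-decreasing with bp within a chromosome")
  }
  map
}

#' Construct a genotype matrix
#'
#' The central container for marker data: an individuals-by-markers matrix of
#' genotype calls together with a marker map.  Calls are stored internally as
#' line-1 allele counts (2/1/0, NA = missing).
#'
#' @param calls Integer matrix (individuals x markers) with values in
#'   \{0, 1, 2, NA\}; row names are individual ids, column names marker ids.
#' @param map Marker map from [marker_map()]; its `marker_id` order must
#'   match `colnames(calls)` after sorting.
#' @return An object of class `"geno"`: a list with elements `calls` and
#'   `map`.
#' @seealso [read_genotypes()], [apply_marker_qc()]
#' @export
genotype_matrix <- function(calls, map) {
  if (!is.matrix(calls)) stop("calls must be a matrix")
  storage.mode(calls) <- "integer"
  if (ncol(calls) == 0L) {  # empty marker set (e.g. everything QC-removed)
    if (is.null(colnames(calls))) colnames(calls) <- character(0)
    return(structure(list(calls = calls, map = map[0, , drop = FALSE]),
                     class = "geno"))
  }
  if (is.null(rownames(calls))) stop("calls must have individual ids as rownames")
  if (is.null(colnames(calls))) stop("calls must have marker ids as colnames")
  if (anyDuplicated(rownames(calls))) stop("duplicate individual ids")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (!setequal(colnames(calls), map$marker_id))
    stop("marker ids in calls and map differ")
  calls <- calls[, map$marker_id, drop = FALSE]
  structure(list(calls = calls, map = map), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr))))
  miss <- mean(is.na(x$calls)) * 100
  cat(sprintf("  missing calls: %.1f%%\n", miss))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$calls)

#' Tabulate genotype-class counts for one marker
#'
#' @param g Vector of allele-count calls (0/1/2/NA) for one marker.
#' @return Named integer vector of non-missing counts for classes
#'   HOM1, HET, HOM2.
#' @keywords internal
class_counts <- function(g) {
  c(HOM1 = sum(g == 2L, na.rm = TRUE),
    HET  = sum(g == 1L, na.rm = TRUE),
    HOM2 = sum(g == 0L, na.rm = TRUE))
}

#' Construct a phenotype table
#'
#' Per-individual covariates and quantitative trait values.  Sex, subfamily
#' (the dam defining the family group used for kinship correction) and litter
#' size are the screened covariates; any further numeric columns are traits.
#' Missing trait values are carried as NA and excluded listwise per model
#' fit, never imputed.
#'
#' @param individual_id Character vector of unique ids.
#' @param sex Factor or character, levels "M"/"F".
#' @param subfamily Factor or character family (dam) labels.
#' @param litter_size Positive integers.
#' @param traits Data frame (or named list) of numeric trait columns.
#' @return A `data.frame` of class `"pheno"` with columns `individual_id`,
#'   `sex`, `subfamily`, `litter_size` followed by one column per trait.
#'   `attr(, "traits")` names the trait columns.
#' @export
phenotype_table <- function(individual_id, sex, subfamily, litter_size, traits) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) stop("duplicate individual ids")
  sex <- as.character(sex)
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  litter_size <- as.integer(litter_size)
  if (any(litter_size < 1L, na.rm = TRUE)) stop("litter_size must be positive")
  traits <- as.data.frame(traits)
  if (!all(vapply(traits, is.numeric, logical(1))))
    stop("all trait columns must be numeric")
  ph <- data.frame(individual_id = individual_id,
                   sex = factor(sex, levels = c("F", "M")),
                   subfamily = factor(as.character(subfamily)),
                   litter_size = litter_size,
                   stringsAsFactors = FALSE)
  ph <- cbind(ph, traits)
  attr(ph, "traits") <- names(traits)
  class(ph) <- c("pheno", "data.frame")
  ph
}

#' Trait names of a phenotype table
#' @param pheno A phenotype table.
#' @return Character vector of trait column names.
#' @export
trait_names <- function(pheno) attr(pheno, "traits")

#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline with their conventional
#' defaults: the small-genotype-group threshold used in marker QC, the
#' covariate screening level, the genomic-inflation trigger above which
#' lambda-correction is applied, the simpleM variance fraction, the two
#' genome-wide significance levels, the LOD-drop width for support
#' intervals, and the differential-expression FDR level.
#'
#' @param group_min Minimum observations per genotype class in QC (default 10).
#' @param alpha_covariate Screening level for covariates (default 0.05).
#' @param lambda_trigger Inflation factor above which lambda-correction is
#'   applied (default 1.05).
#' @param simpleM_variance_fraction Eigenvalue variance fraction for the
#'   effective number of tests (default 0.995).
#' @param alpha_sig,alpha_highsig Genome-wide significance levels
#'   (defaults 0.05 and 0.01).
#' @param lod_drop LOD-drop defining support-interval ends (default 1.5).
#' @param de_alpha BH-adjusted significance level for differential
#'   expression (default 0.05).
#' @param kegg_gene_set Character vector of genes in the relevant metabolic
#'   pathways (scoring input; default empty).
#' @param seed Integer seed recorded in the run log.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(group_min = 10L, alpha_covariate = 0.05,
                       lambda_trigger = 1.05,
                       simpleM_variance_fraction = 0.995,
                       alpha_sig = 0.05, alpha_highsig = 0.01,
                       lod_drop = 1.5, de_alpha = 0.05,
                       kegg_gene_set = character(), seed = 1L) {
  stopifnot(group_min >= 1,
            alpha_covariate > 0, alpha_covariate < 1,
            simpleM_variance_fraction > 0, simpleM_variance_fraction <= 1,
            alpha_sig > 0, alpha_sig < 1,
            alpha_highsig > 0, alpha_highsig < 1,
            lod_drop > 0,
            de_alpha > 0, de_alpha < 1)
  structure(list(group_min = as.integer(group_min),
                 alpha_covariate = alpha_covariate,
                 lambda_trigger = lambda_trigger,
                 simpleM_variance_fraction = simpleM_variance_fraction,
                 alpha_sig = alpha_sig, alpha_highsig = alpha_highsig,
                 lod_drop = lod_drop, de_alpha = de_alpha,
                 kegg_gene_set = as.character(kegg_gene_set),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Construct a variant annotation table
#'
#' One row per (variant, gene, feature) with the consequence categories used
#' by the candidate-gene decision tree.  SIFT predictions only apply to
#' missense variants; protein-domain overlap only to missense variants.
#'
#' @param df Data frame with columns `gene_id`, `gene_symbol`, `chr`, `bp`,
#'   `consequence` (one of `stop_gain`, `stop_loss`, `missense`, `none`),
#'   `sift` (`deleterious`, `tolerated`, `n/a`), `in_domain` (logical),
#'   `regulatory` (one of `promoter`, `splice_site`, `utr`, `enhancer`,
#'   `ctcf_binding_site`, `none`).
#' @return The validated data frame with class `"variant_annotation"`.
#' @export
variant_annotation_table <- function(df) {
  need <- c("gene_id", "gene_symbol", "chr", "bp", "consequence", "sift",
            "in_domain", "regulatory")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  cons_lv <- c("stop_gain", "stop_loss", "missense", "none")
  sift_lv <- c("deleterious", "tolerated", "n/a")
  reg_lv <- c("promoter", "splice_site", "utr", "enhancer",
              "ctcf_binding_site", "none")
  if (!all(df$consequence %in% cons_lv)) stop("invalid consequence value")
  if (!all(df$sift %in% sift_lv)) stop("invalid sift value")
  if (!all(df$regulatory %in% reg_lv)) stop("invalid regulatory value")
  if (any(df$sift != "n/a" & df$consequence != "missense"))
    stop("sift class only applies to missense variants")
  df$in_domain <- as.logical(df$in_domain)
  class(df) <- c("variant_annotation", "data.frame")
  df
}

#' Construct an expression matrix
#'
#' Array-style intensities for two groups of samples (the two parental
#' lines).  The transformation state (raw vs log2) is tracked explicitly so
#' that normalization can refuse already-transformed input and vice versa.
#'
#' @param intensities Numeric matrix, features x samples.
#' @param groups Character/factor of length `ncol(intensities)` with two
#'   levels; the first level is the line of interest (group 1) whose mean
#'   enters the fold change with positive sign.
#' @param log2_transformed Logical flag; raw intensities must be positive.
#' @return A list of class `"expr_matrix"` with elements `intensities`,
#'   `groups`, `log2_transformed`.
#' @export
expression_matrix <- function(intensities, groups, log2_transformed = FALSE) {
  if (!is.matrix(intensities)) stop("intensities must be a matrix")
  if (is.null(rownames(intensities))) stop("intensities needs feature rownames")
  groups <- as.factor(groups)
  if (length(groups) != ncol(intensities))
    stop("groups length must equal number of samples")
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("at least 2 samples per group required")
  if (!log2_transformed && any(intensities <= 0)) {
    idx <- which(intensities <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive raw intensity at feature '%s', sample '%s'",
                 rownames(intensities)[idx[1]], colnames(intensities)[idx[2]]))
  }
  structure(list(intensities = intensities, groups = groups,
                 log2_transformed = isTRUE(log2_transformed)),
            class = "expr_matrix")
}
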