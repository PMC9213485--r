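# median of the 1-df chi-square distribution
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Genomic-control lambda correction
#'
#' Converts each p-value to a 1-df chi-square quantile, estimates the
#' genomic inflation factor as the ratio of the median observed quantile to
#' the 1-df chi-square median (0.4549364), and — when lambda exceeds the
#' trigger — deflates the quantiles by lambda before converting back to
#' p-values.  Below the trigger the corrected values equal the raw values;
#' lambda is reported either way.
#'
#' The 1-df convention is the standard genomic-control choice and is used
#' regardless of the scan F-test's degrees of freedom; see the methods
#' vignette for the rationale.
#'
#' @param p Numeric vector of p-values in (0, 1]; NAs are passed through.
#' @param lambda_trigger Inflation factor above which correction is applied
#'   (default 1.05).
#' @return List with `lambda`, `lambda_applied` (logical) and `p_corrected`.
#' @examples
#' lambda_correct(runif(1000))$lambda  # ~1 under the null
#' @export
lambda_correct <- function(p, lambda_trigger = 1.05) {
  obs <- p[!is.na(p)]
  if (!length(obs)) stop("no p-values supplied")
  if (any(obs <= 0 | obs > 1)) stop("p-values must lie in (0, 1]")
  q <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(q, na.rm = TRUE) / CHISQ1_MEDIAN
  applied <- lambda > lambda_trigger
  p_corr <- if (applied) pchisq(q / lambda, df = 1, lower.tail = FALSE) else p
  list(lambda = lambda, lambda_applied = applied, p_corrected = p_corr)
}

#' Effective number of independent tests (simpleM)
#'
#' Eigenvalue-based estimate of the number of independent markers, used to
#' Bonferroni-correct the genome-wide significance level.  Markers are
#' coded 0/1/2 (line-1 allele count); within each chromosome the
#' marker-marker correlation matrix is computed on pairwise-complete calls,
#' its eigenvalues are clipped at zero, and the chromosome's contribution is
#' the smallest k whose top-k eigenvalues reach `variance_fraction` of the
#' eigenvalue sum.  Contributions are summed over chromosomes (linkage
#' disequilibrium does not extend across chromosomes); a genome-wide single
#' block is available via `per_chromosome = FALSE`.
#'
#' @param geno A QC'd [genotype_matrix()].
#' @param variance_fraction Fraction of variance the retained eigenvalues
#'   must explain (default 0.995, the method's published default).
#' @param per_chromosome Apply per chromosome and sum (default) or to the
#'   whole genome at once.
#' @return Integer Meff.
#' @export
simpleM_effective_tests <- function(geno, variance_fraction = 0.995,
                                    per_chromosome = TRUE) {
  stopifnot(inherits(geno, "geno"),
            variance_fraction > 0, variance_fraction <= 1)
  blocks <- if (per_chromosome) split(geno$map$marker_id, geno$map$chr) else
    list(all = geno$map$marker_id)
  meff <- 0L
  for (ids in blocks) {
    X <- geno$calls[, ids, drop = FALSE]
    v <- apply(X, 2L, var, na.rm = TRUE)
    if (any(is.na(v) | v == 0))
      stop("zero-variance marker present; genotype matrix is not QC'd")
    C <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    if (anyNA(C)) {
      warning("marker pairs without complete observations; treating as uncorrelated")
      C[is.na(C)] <- 0
      diag(C) <- 1
    }
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 0] <- 0
    k <- which(cumsum(ev) / sum(ev) >= variance_fraction)[1L]
    meff <- meff + k
  }
  as.integer(meff)
}

#' Bonferroni LOD thresholds from the effective number of tests
#'
#' `LOD = -log10(alpha / Meff)` at the genome-wide significant and highly
#' significant levels.  Comparisons in the pipeline use the full-precision
#' values; the one-decimal display values match conventional reporting.
#'
#' @param meff Effective number of independent tests (>= 1).
#' @param alpha_sig,alpha_highsig Genome-wide levels (defaults 0.05, 0.01).
#' @return List with `lod_sig`, `lod_highsig` (full precision) and
#'   `lod_sig_display`, `lod_highsig_display` (rounded to 1 decimal).
#' @examples
#' lod_thresholds(1365)  # display 4.4 and 5.1
#' @export
lod_thresholds <- function(meff, alpha_sig = 0.05, alpha_highsig = 0.01) {
  stopifnot(meff >= 1)
  sig <- -log10(alpha_sig / meff)
  high <- -log10(alpha_highsig / meff)
  list(lod_sig = sig, lod_highsig = high,
       lod_sig_display = round(sig, 1), lod_highsig_display = round(high, 1))
}

#' Single-marker QTL scan
#'
#' For each marker, fits `trait ~ selected covariates + genotype class`
#' (genotype as a categorical factor: 2 df with three observed classes,
#' 1 df with two, so overdominant patterns are not missed) and tests the
#' genotype factor against the covariates-only null with an F-test on
#' listwise-complete individuals.  The resulting p-value list is
#' genomic-control corrected ([lambda_correct()]); LOD scores are
#' `-log10(p)` for both raw and corrected columns.  simpleM Bonferroni
#' thresholds are attached ([simpleM_effective_tests()], [lod_thresholds()]).
#'
#' Markers with fewer than two observed classes after listwise deletion, or
#' collinear with the cofactor in an MQM scan, are emitted with NA
#' statistics (never dropped from the output table).
#'
#' @param pheno A [phenotype_table()].
#' @param geno A QC'd [genotype_matrix()].
#' @param trait Trait name.
#' @param covariates Character vector of covariates for this trait, or a
#'   [screen_covariates()] result from which the trait's selection is taken.
#' @param config A [run_config()] supplying lambda trigger, simpleM
#'   fraction and alpha levels.
#' @param cofactor Optional marker id whose genotype class is added as a
#'   model covariate (the MQM cofactor); that marker and markers
#'   genotypically collinear with it get NA records.
#' @param meff Optional precomputed effective number of tests.
#' @return Object of class `"scan_result"`: list with `trait`, `table`
#'   (per-marker data.frame: marker, chr, bp, class counts, p/LOD raw and
#'   corrected, partial R2 in percent, adjusted class means), `lambda`,
#'   `lambda_applied`, `meff`, `thresholds`, `covariates`, `cofactor`.
#' @seealso [mqm_scan()], [lod_drop_region()], [call_qtl_regions()]
#' @export
qtl_scan <- function(pheno, geno, trait, covariates = character(),
                     config = run_config(), cofactor = NULL, meff = NULL) {
  stopifnot(inherits(pheno, "pheno"), inherits(geno, "geno"))
  if (inherits(covariates, "covariate_selection"))
    covariates <- selected_covariates(covariates, trait)
  ids <- intersect(pheno$individual_id, rownames(geno$calls))
  if (!length(ids)) stop("no individuals shared between phenotypes and genotypes")
  ph <- pheno[match(ids, pheno$individual_id), , drop = FALSE]
  calls <- geno$calls[ids, , drop = FALSE]
  y <- ph[[trait]]
  if (is.null(y)) stop("unknown trait: ", trait)
  Z <- .covariate_design(as.data.frame(ph), covariates)

  cof_g <- NULL
  if (!is.null(cofactor)) {
    if (!cofactor %in% colnames(calls))
      stop("cofactor marker not in genotype matrix: ", cofactor)
    cof_g <- calls[, cofactor]
    Gc <- factor(cof_g)
    if (nlevels(Gc) > 1L)
      for (l in levels(Gc)[-1L]) {
        Z <- cbind(Z, as.numeric(Gc == l))
        colnames(Z)[ncol(Z)] <- paste0("cofactor", l)
      }
  }

  map <- geno$map
  m <- nrow(map)
  tab <- data.frame(marker = map$marker_id, chr = map$chr, bp = map$bp,
                    n_HOM1 = NA_integer_, n_HET = NA_integer_,
                    n_HOM2 = NA_integer_,
                    p_raw = NA_real_, lod_raw = NA_real_,
                    p_corrected = NA_real_, lod_corrected = NA_real_,
                    partial_r2 = NA_real_,
                    mean_HOM1 = NA_real_, mean_HET = NA_real_,
                    mean_HOM2 = NA_real_, stringsAsFactors = FALSE)
  base_ok <- !is.na(y) & complete.cases(Z)
  for (j in seq_len(m)) {
    mk <- map$marker_id[j]
    g <- calls[, mk]
    cnt <- class_counts(g[base_ok & !is.na(g)])
    tab[j, c("n_HOM1", "n_HET", "n_HOM2")] <- as.list(as.integer(cnt))
    if (!is.null(cofactor) && mk == cofactor) next
    ok <- base_ok & !is.na(g)
    if (!any(ok)) next
    fit <- .fit_geno_model(y[ok], g[ok], Z[ok, , drop = FALSE])
    k_obs <- sum(fit$counts > 0L)
    if (!is.na(fit$df_geno) && k_obs > 1L && fit$df_geno < k_obs - 1L)
      next  # collinear with the cofactor/covariates: NA record
    tab[j, c("mean_HOM1", "mean_HET", "mean_HOM2")] <- as.list(fit$means)
    if (is.na(fit$df_geno) || fit$df_geno < 1L) next  # < 2 observed classes
    tab$p_raw[j] <- fit$p
    tab$partial_r2[j] <- fit$partial_r2
  }
  lc <- if (any(!is.na(tab$p_raw)))
    lambda_correct(tab$p_raw, config$lambda_trigger) else
    list(lambda = NA_real_, lambda_applied = FALSE, p_corrected = tab$p_raw)
  tab$p_corrected <- lc$p_corrected
  tab$lod_raw <- -log10(tab$p_raw)
  tab$lod_corrected <- -log10(tab$p_corrected)
  if (is.null(meff)) {
    # restrict to polymorphic markers so scans on not-yet-QC'd input still
    # get a threshold (simpleM itself insists on QC'd input)
    poly <- vapply(seq_len(m), function(j) {
      v <- var(calls[, j], na.rm = TRUE)
      !is.na(v) && v > 0
    }, logical(1))
    meff <- if (any(poly)) {
      sub <- genotype_matrix(geno$calls[, poly, drop = FALSE],
                             geno$map[poly, , drop = FALSE])
      simpleM_effective_tests(sub, config$simpleM_variance_fraction)
    } else 1L
  }
  structure(list(trait = trait, table = tab,
                 lambda = lc$lambda, lambda_applied = lc$lambda_applied,
                 meff = meff,
                 thresholds = lod_thresholds(meff, config$alpha_sig,
                                             config$alpha_highsig),
                 covariates = covariates, cofactor = cofactor),
            class = "scan_result")
}

#' Cofactor multiple-QTL-mapping scan
#'
#' Rescans the genome with a known QTL's top marker included as a
#' categorical cofactor, so that loci masked by the strong effect become
#' detectable (e.g. `body weight = sex + mother + top marker + marker
#' genotype + error`).  The cofactor marker itself and markers collinear
#' with it are emitted with NA statistics; the new p-value list gets its
#' own genomic-control correction.
#'
#' @inheritParams qtl_scan
#' @param cofactor_marker Marker id of the cofactor (must have passed QC).
#' @return A `"scan_result"`, as for [qtl_scan()].
#' @export
mqm_scan <- function(pheno, geno, trait, covariates = character(),
                     cofactor_marker, config = run_config(), meff = NULL) {
  qtl_scan(pheno, geno, trait, covariates, config,
           cofactor = cofactor_marker, meff = meff)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("QTL scan for '%s': %d markers, lambda = %.3f%s, Meff = %d\n",
              x$trait, nrow(x$table), x$lambda,
              if (x$lambda_applied) " (corrected)" else "", x$meff))
  cat(sprintf("  thresholds: LOD > %.1f significant, > %.1f highly significant\n",
              x$thresholds$lod_sig_display, x$thresholds$lod_highsig_display))
  if (!is.null(x$cofactor)) cat("  MQM cofactor:", x$cofactor, "\n")
  top <- x$table[which.max(x$table$lod_corrected), ]
  if (nrow(top)) cat(sprintf("  top marker: %s (chr %s, %d bp), LOD %.2f\n",
                             top$marker, top$chr, top$bp, top$lod_corrected))
  invisible(x)
}

#' 1.5-LOD-drop support interval on one chromosome
#'
#' The top marker is the chromosome's maximum corrected LOD (ties broken
#' toward the smallest bp).  The region start is the position of the first
#' marker upstream whose LOD has dropped by at least `lod_drop` below the
#' top LOD, or the chromosome's first marker when no such marker exists;
#' the stop position is symmetric downstream.
#'
#' @param scan A `"scan_result"`.
#' @param chr Chromosome label.
#' @param lod_drop Drop defining the interval ends (default 1.5).
#' @param threshold Optional LOD the top marker must reach; when it does
#'   not, NULL is returned (no region, not an error).
#' @return A one-row data.frame of class `"qtl_region"` with columns
#'   trait, chr, start_bp, top_bp, stop_bp, top_marker, top_lod,
#'   percent_variance, mean_HOM1, mean_HET, mean_HOM2 — or NULL.
#' @export
lod_drop_region <- function(scan, chr, lod_drop = 1.5, threshold = NULL) {
  stopifnot(inherits(scan, "scan_result"), lod_drop > 0)
  tab <- scan$table[scan$table$chr == as.character(chr), , drop = FALSE]
  tab <- tab[order(tab$bp), , drop = FALSE]
  lods <- tab$lod_corrected
  if (all(is.na(lods))) return(NULL)
  top_i <- which(lods == max(lods, na.rm = TRUE))[1L]  # ties: smallest bp
  top_lod <- lods[top_i]
  if (!is.null(threshold) && top_lod < threshold) return(NULL)
  cut <- top_lod - lod_drop
  start_bp <- tab$bp[1L]
  if (top_i > 1L) for (i in (top_i - 1L):1L) {
    if (!is.na(lods[i]) && lods[i] <= cut) { start_bp <- tab$bp[i]; break }
  }
  stop_bp <- tab$bp[nrow(tab)]
  if (top_i < nrow(tab)) for (i in (top_i + 1L):nrow(tab)) {
    if (!is.na(lods[i]) && lods[i] <= cut) { stop_bp <- tab$bp[i]; break }
  }
  out <- data.frame(trait = scan$trait, chr = as.character(chr),
                    start_bp = start_bp, top_bp = tab$bp[top_i],
                    stop_bp = stop_bp, top_marker = tab$marker[top_i],
                    top_lod = top_lod,
                    percent_variance = tab$partial_r2[top_i],
                    mean_HOM1 = tab$mean_HOM1[top_i],
                    mean_HET = tab$mean_HET[top_i],
                    mean_HOM2 = tab$mean_HOM2[top_i],
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_region", "data.frame")
  out
}

#' Call QTL regions genome-wide
#'
#' Applies [lod_drop_region()] to every chromosome whose maximum corrected
#' LOD reaches the threshold.
#'
#' @param scan A `"scan_result"`.
#' @param threshold LOD threshold for calling (default the scan's
#'   genome-wide significant threshold).
#' @param lod_drop Support-interval drop (default 1.5).
#' @return Data frame of regions (zero rows when nothing is significant).
#' @export
call_qtl_regions <- function(scan, threshold = scan$thresholds$lod_sig,
                             lod_drop = 1.5) {
  regions <- lapply(unique(scan$table$chr), function(cc)
    lod_drop_region(scan, cc, lod_drop, threshold))
  regions <- regions[!vapply(regions, is.null, logical(1))]
  if (!length(regions)) {
    out <- data.frame(trait = character(), chr = character(),
                      start_bp = integer(), top_bp = integer(),
                      stop_bp = integer(), top_marker = character(),
                      top_lod = numeric(), percent_variance = numeric(),
                      mean_HOM1 = numeric(), mean_HET = numeric(),
                      mean_HOM2 = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("qtl_region", "data.frame")
    return(out)
  }
  out <- do.call(rbind, regions)
  class(out) <- c("qtl_region", "data.frame")
  out
}
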