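#' Log2-transform and quantile-normalize expression intensities
#'
#' Raw positive intensities are log2-transformed, then quantile normalized
#' across all samples: within each sample values are ranked and rank i is
#' replaced by the mean of the i-th order statistics across samples, ties
#' receiving the mean of their spanned quantile means.  After normalization
#' every sample has the same sorted value vector.  Backed by
#' \code{limma::normalizeQuantiles} (ties averaged).
#'
#' @param expr An [expression_matrix()] with `log2_transformed = FALSE`.
#' @return The normalized [expression_matrix()] with
#'   `log2_transformed = TRUE`.
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$log2_transformed) stop("intensities already log2-transformed")
  if (any(expr$intensities <= 0)) {
    idx <- which(expr$intensities <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at feature '%s', sample '%s'",
                 rownames(expr$intensities)[idx[1]],
                 colnames(expr$intensities)[idx[2]]))
  }
  x <- limma::normalizeQuantiles(log2(expr$intensities), ties = TRUE)
  dimnames(x) <- dimnames(expr$intensities)
  expression_matrix(x, expr$groups, log2_transformed = TRUE)
}

#' Per-gene two-group differential expression
#'
#' Two-sample two-tailed t-tests per gene on log2 intensities (pooled
#' variance by default; Welch via `var_equal = FALSE`), Benjamini-Hochberg
#' step-up adjustment across all tested genes, and log2 fold changes as
#' `mean(group 1) - mean(group 2)` — negative values mean downregulated in
#' the line of interest.  Genes with zero variance in both groups and equal
#' means get p = 1 by convention.
#'
#' @param expr A normalized [expression_matrix()]
#'   (`log2_transformed = TRUE`).
#' @param de_alpha BH-adjusted significance level (default 0.05).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return Data frame of class `"de_result"`: gene, mean_group1,
#'   mean_group2, log2_fc, t_statistic, p_value, bh_adjusted_p,
#'   significant.
#' @export
de_test <- function(expr, de_alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$log2_transformed)
    stop("de_test expects log2-transformed (normalized) intensities")
  x <- expr$intensities
  g1 <- expr$groups == levels(expr$groups)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1L, var)
  v2 <- apply(x[, !g1, drop = FALSE], 1L, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    # zero variance in both groups: equal means -> p = 1 by convention;
    # unequal means are a perfect separation, p -> 0 is not defensible with
    # no variance estimate, so flag with NA
    eq <- degenerate & (m1 == m2)
    tstat[eq] <- 0; p[eq] <- 1
    p[degenerate & !eq] <- NA_real_
    message(sum(degenerate), " gene(s) with zero variance in both groups")
  }
  bh <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(x), mean_group1 = m1, mean_group2 = m2,
                    log2_fc = m1 - m2, t_statistic = tstat, p_value = p,
                    bh_adjusted_p = bh,
                    significant = !is.na(bh) & bh < de_alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "de_alpha") <- de_alpha
  attr(out, "groups") <- levels(expr$groups)
  class(out) <- c("de_result", "data.frame")
  out
}
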