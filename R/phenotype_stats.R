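COVARIATES <- c("sex", "subfamily", "litter_size")

#' Screen covariates per trait
#'
#' Each covariate (sex, subfamily, litter size) is tested marginally against
#' each trait with its own linear model: sex and subfamily as categorical
#' factors via the overall F-test, litter size as a linear slope.  A
#' covariate is selected for a trait when its p-value falls below
#' `alpha_covariate`; selected covariates are then carried as fixed effects
#' in the QTL scan for that trait (subfamily doubling as the kinship
#' correction).
#'
#' @param pheno A [phenotype_table()].
#' @param alpha_covariate Selection level (default 0.05).
#' @param traits Traits to screen (default all).
#' @return Data frame of class `"covariate_selection"` with columns
#'   `trait`, `covariate`, `p_value`, `selected`.  A covariate constant
#'   across individuals yields `p_value = NA`, `selected = FALSE` and a
#'   warning.
#' @seealso [selected_covariates()], [qtl_scan()]
#' @export
screen_covariates <- function(pheno, alpha_covariate = 0.05,
                              traits = trait_names(pheno)) {
  stopifnot(inherits(pheno, "pheno"))
  res <- expand.grid(trait = traits, covariate = COVARIATES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- res[order(match(res$trait, traits)), ]
  res$p_value <- NA_real_
  for (i in seq_len(nrow(res))) {
    y <- pheno[[res$trait[i]]]
    x <- pheno[[res$covariate[i]]]
    ok <- !is.na(y) & !is.na(x)
    xx <- if (is.factor(x)) droplevels(x[ok]) else x[ok]
    if ((is.factor(xx) && nlevels(xx) < 2L) ||
        (!is.factor(xx) && var(xx) == 0)) {
      warning(sprintf("covariate '%s' constant for trait '%s'; not selected",
                      res$covariate[i], res$trait[i]))
      next
    }
    fit <- lm(y[ok] ~ xx)
    res$p_value[i] <- anova(fit)[1L, "Pr(>F)"]
  }
  res$selected <- !is.na(res$p_value) & res$p_value < alpha_covariate
  rownames(res) <- NULL
  attr(res, "alpha_covariate") <- alpha_covariate
  class(res) <- c("covariate_selection", "data.frame")
  res
}

#' Covariates selected for one trait
#'
#' @param selection Result of [screen_covariates()].
#' @param trait Trait name.
#' @return Character vector (possibly empty) of selected covariate names.
#' @export
selected_covariates <- function(selection, trait) {
  stopifnot(inherits(selection, "covariate_selection"))
  selection$covariate[selection$trait == trait & selection$selected]
}

#' Spearman correlation matrix across traits
#'
#' Spearman's rank correlation (midranks for ties) between all supplied
#' trait pairs on pairwise-complete observations, with asymptotic t
#' p-values and a Bonferroni per-test threshold `alpha / n_tests`.
#'
#' @param pheno A [phenotype_table()].
#' @param traits Traits to correlate (default all).
#' @param n_tests Number of tests for the Bonferroni threshold; default the
#'   number of distinct trait pairs.
#' @param alpha Family-wise level (default 0.05).
#' @return List of class `"cor_matrix"`: `rho`, `p` (symmetric matrices),
#'   `threshold`, `n_tests`, `significant` (logical matrix).  Pairs
#'   involving a constant trait are NA.
#' @export
spearman_matrix <- function(pheno, traits = trait_names(pheno),
                            n_tests = NULL, alpha = 0.05) {
  k <- length(traits)
  stopifnot(k >= 2L)
  if (is.null(n_tests)) n_tests <- k * (k - 1L) / 2L
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- pheno[[traits[i]]]; y <- pheno[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  thr <- alpha / n_tests
  structure(list(rho = rho, p = p, threshold = thr, n_tests = n_tests,
                 significant = !is.na(p) & p < thr),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations (%d traits); per-test threshold p < %.3g (%d tests)\n",
              nrow(x$rho), x$threshold, x$n_tests))
  print(round(x$rho, digits))
  invisible(x)
}

# Core least-squares machinery shared by adjusted_class_means() and the
# scan: fit y ~ covariate design + genotype class, return the F-test of the
# genotype factor against the covariate-only null plus adjusted class means
# (prediction at design-column means, i.e. covariates at their sample means
# and factor covariates at observed proportions).
#
# y: response; g: allele-count calls (0/1/2/NA); Z: covariate model matrix
# WITH intercept, rows aligned to y.  All rows passed in must be complete.
.fit_geno_model <- function(y, g, Z) {
  classes_present <- sort(unique(g), decreasing = TRUE)  # 2,1,0 order
  k <- length(classes_present)
  out <- list(p = NA_real_, df_geno = NA_integer_, n = length(y),
              partial_r2 = NA_real_,
              means = c(HOM1 = NA_real_, HET = NA_real_, HOM2 = NA_real_),
              counts = class_counts(g))
  if (length(y) == 0L || k < 1L) return(out)
  G <- factor(g, levels = classes_present)
  Xg <- if (k > 1L) model.matrix(~ G)[, -1L, drop = FALSE] else
    matrix(0, length(y), 0L)
  fit0 <- lm.fit(Z, y)
  fit1 <- lm.fit(cbind(Z, Xg), y)
  rank0 <- fit0$rank; rank1 <- fit1$rank
  df_geno <- rank1 - rank0
  df_res <- length(y) - rank1
  sse0 <- sum(fit0$residuals^2)
  sse1 <- sum(fit1$residuals^2)
  # adjusted class means: prediction at covariate design means per class
  beta <- fit1$coefficients
  beta[is.na(beta)] <- 0
  z0 <- colMeans(Z)
  lab <- c(`2` = "HOM1", `1` = "HET", `0` = "HOM2")
  for (ci in seq_along(classes_present)) {
    xg <- if (k > 1L) as.numeric((2:k) == ci) else numeric(0)
    out$means[lab[as.character(classes_present[ci])]] <-
      sum(c(z0, xg) * beta)
  }
  if (df_geno >= 1L && df_res >= 1L) {
    sst <- sum((y - mean(y))^2)
    if (sse0 <= 1e-12 * max(sst, 1)) {
      out$p <- 1  # covariates leave no residual variance: nothing to test
      out$partial_r2 <- 0
    } else {
      f <- (max(sse0 - sse1, 0) / df_geno) / (sse1 / df_res)
      out$p <- pf(f, df_geno, df_res, lower.tail = FALSE)
      out$partial_r2 <- if (sst > 0) max(sse0 - sse1, 0) / sst * 100 else NA_real_
    }
  }
  out$df_geno <- df_geno
  out
}

# covariate design matrix (with intercept) for the named covariates
.covariate_design <- function(pheno, covariates) {
  if (!length(covariates)) return(matrix(1, nrow(pheno), 1L,
                                         dimnames = list(NULL, "(Intercept)")))
  d <- pheno[, covariates, drop = FALSE]
  d[] <- lapply(d, function(x) if (is.factor(x)) droplevels(x) else x)
  model.matrix(~ ., data = d)
}

#' Covariate-adjusted genotype-class means
#'
#' Least-squares means of a trait for the three genotype classes at one
#' marker, adjusting for the selected covariates: the fitted model is
#' `trait ~ covariates + genotype class`, and each class mean is the model
#' prediction for that class with numeric covariates at their sample means
#' and factor covariates at their observed proportions.  With no covariates
#' this reduces exactly to the raw within-class averages.
#'
#' @param pheno A [phenotype_table()].
#' @param trait Trait name.
#' @param g Genotype calls (0/1/2/NA) aligned to `pheno` rows, or a
#'   [genotype_matrix()] plus `marker`.
#' @param covariates Character vector among `c("sex", "subfamily",
#'   "litter_size")`; typically [selected_covariates()].
#' @param marker Marker id when `g` is a genotype matrix.
#' @return Named numeric vector (HOM1, HET, HOM2); classes with no
#'   observations are NA.  Attributes: `n` (class counts), `testable`
#'   (TRUE when >= 2 classes observed).
#' @export
adjusted_class_means <- function(pheno, trait, g, covariates = character(),
                                 marker = NULL) {
  if (inherits(g, "geno")) {
    stopifnot(!is.null(marker))
    g <- g$calls[match(pheno$individual_id, rownames(g$calls)), marker]
  }
  y <- pheno[[trait]]
  Z <- .covariate_design(pheno, covariates)
  ok <- !is.na(y) & !is.na(g) & complete.cases(Z)
  fit <- .fit_geno_model(y[ok], g[ok], Z[ok, , drop = FALSE])
  means <- fit$means
  attr(means, "n") <- fit$counts
  attr(means, "testable") <- sum(fit$counts > 0L) >= 2L
  means
}
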