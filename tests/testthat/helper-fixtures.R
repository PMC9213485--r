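# Build a one-chromosome genotype matrix whose j-th marker has the given
# class counts, in order (HOM1, HET, HOM2, missing).  Individuals are
# recycled across markers so all markers share the same rows.
make_geno_from_counts <- function(counts_list, chr = "1") {
  n <- max(vapply(counts_list, sum, numeric(1)))
  cols <- lapply(counts_list, function(ct) {
    stopifnot(length(ct) == 4L, sum(ct) <= n)
    c(rep(2L, ct[1]), rep(1L, ct[2]), rep(0L, ct[3]),
      rep(NA_integer_, ct[4] + n - sum(ct)))
  })
  calls <- do.call(cbind, cols)
  dimnames(calls) <- list(sprintf("ind%03d", seq_len(n)),
                          sprintf("m%03d", seq_along(counts_list)))
  genotype_matrix(calls,
                  marker_map(colnames(calls), rep(chr, ncol(calls)),
                             seq_len(ncol(calls)) * 1000L))
}

# Random genotype matrix for property tests (arbitrary missingness).
random_geno <- function(n_ind, n_mark, p_missing = 0.1) {
  calls <- matrix(sample(c(0:2, NA), n_ind * n_mark, replace = TRUE,
                         prob = c((1 - p_missing) * c(0.25, 0.5, 0.25),
                                  p_missing)),
                  n_ind, n_mark,
                  dimnames = list(sprintf("i%03d", seq_len(n_ind)),
                                  sprintf("m%03d", seq_len(n_mark))))
  genotype_matrix(calls, marker_map(colnames(calls), rep("1", n_mark),
                                    seq_len(n_mark) * 500L))
}

# Phenotype table wrapper around plain vectors.
make_pheno <- function(traits, sex = NULL, subfamily = NULL,
                       litter_size = NULL, ids = NULL) {
  traits <- as.data.frame(traits)
  n <- nrow(traits)
  phenotype_table(
    if (is.null(ids)) sprintf("ind%03d", seq_len(n)) else ids,
    if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex,
    if (is.null(subfamily)) rep("fam1", n) else subfamily,
    if (is.null(litter_size)) rep(5L, n) else litter_size,
    traits)
}

# One-row annotation helper for scoring tests.
ann_rows <- function(gene, specs) {
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    data.frame(gene_id = gene, gene_symbol = gene, chr = "1", bp = i,
               consequence = sp[["consequence"]] %||% "none",
               sift = sp[["sift"]] %||% "n/a",
               in_domain = isTRUE(sp[["in_domain"]]),
               regulatory = sp[["regulatory"]] %||% "none",
               stringsAsFactors = FALSE)
  })
  variant_annotation_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sylvester-construction Hadamard matrix of order 2^k (for exact
# orthogonal-marker simpleM cases).
hadamard <- function(k) {
  H <- matrix(1, 1, 1)
  for (i in seq_len(k)) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}
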