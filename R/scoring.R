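#' Score one gene with the prioritization decision tree
#'
#' Converts a gene's variant annotations, liver differential-expression
#' status and pathway membership into an integer priority score.  Each
#' scoring category counts at most once per gene no matter how many
#' variants trigger it (category-once semantics):
#' \itemize{
#'   \item stop gain / stop loss: 3
#'   \item missense located in a functional protein domain: 3
#'   \item missense SIFT class: deleterious 3, else tolerated 1
#'     (deleterious dominates; the domain and SIFT components of the same
#'     missense variant add)
#'   \item non-coding variant in a promoter or splice site: 3
#'   \item non-coding variant in a UTR, enhancer or CTCF binding site: 1 each
#'   \item differentially expressed in liver (BH-adjusted p < `de_alpha`): 2
#'   \item member of the relevant KEGG metabolic pathways: 1
#' }
#' The total is the component sum (maximum 21).
#'
#' @param annotations [variant_annotation_table()] rows, all for this gene
#'   (may have zero rows).
#' @param de Optional one-row slice of a [de_test()] result for the gene,
#'   or NULL when the gene was not measured.
#' @param in_kegg Pathway membership flag.
#' @param de_alpha Significance level applied to `de$bh_adjusted_p`
#'   (default the level stored on the DE result, else 0.05).
#' @return One-row data.frame of class `"gene_score"` with the component
#'   columns `coding_stop`, `coding_domain_missense`, `coding_sift`,
#'   `promoter`, `splice`, `utr`, `enhancer`, `ctcf`, `de_liver`, `kegg`
#'   and their sum `total`.
#' @examples
#' ann <- variant_annotation_table(data.frame(
#'   gene_id = "g", gene_symbol = "g", chr = "1", bp = 1:5,
#'   consequence = c("missense", rep("none", 4)),
#'   sift = c("deleterious", rep("n/a", 4)),
#'   in_domain = c(TRUE, rep(FALSE, 4)),
#'   regulatory = c("none", "ctcf_binding_site", "utr", "enhancer",
#'                  "promoter")))
#' score_gene(ann)$total  # 12
#' @export
score_gene <- function(annotations, de = NULL, in_kegg = FALSE,
                       de_alpha = NULL) {
  if (nrow(annotations) && length(unique(annotations$gene_symbol)) > 1L)
    stop("annotations must belong to a single gene")
  a <- annotations
  mis <- a$consequence == "missense"
  coding_stop <- if (any(a$consequence %in% c("stop_gain", "stop_loss"))) 3L else 0L
  coding_domain <- if (any(mis & a$in_domain)) 3L else 0L
  coding_sift <- if (any(mis & a$sift == "deleterious")) 3L else
    if (any(mis & a$sift == "tolerated")) 1L else 0L
  promoter <- if (any(a$regulatory == "promoter")) 3L else 0L
  splice <- if (any(a$regulatory == "splice_site")) 3L else 0L
  utr <- if (any(a$regulatory == "utr")) 1L else 0L
  enhancer <- if (any(a$regulatory == "enhancer")) 1L else 0L
  ctcf <- if (any(a$regulatory == "ctcf_binding_site")) 1L else 0L
  de_sig <- FALSE
  if (!is.null(de) && nrow(de) == 1L && !is.na(de$bh_adjusted_p)) {
    if (is.null(de_alpha))
      de_alpha <- if (!is.null(attr(de, "de_alpha"))) attr(de, "de_alpha") else 0.05
    de_sig <- de$bh_adjusted_p < de_alpha
  }
  de_liver <- if (de_sig) 2L else 0L
  kegg <- if (isTRUE(in_kegg)) 1L else 0L
  gene <- if (nrow(a)) a$gene_symbol[1L] else NA_character_
  out <- data.frame(gene = gene, coding_stop = coding_stop,
                    coding_domain_missense = coding_domain,
                    coding_sift = coding_sift, promoter = promoter,
                    splice = splice, utr = utr, enhancer = enhancer,
                    ctcf = ctcf, de_liver = de_liver, kegg = kegg,
                    stringsAsFactors = FALSE)
  out$total <- coding_stop + coding_domain + coding_sift + promoter +
    splice + utr + enhancer + ctcf + de_liver + kegg
  class(out) <- c("gene_score", "data.frame")
  out
}

#' Score every gene in an annotation table
#'
#' @param annotations A [variant_annotation_table()].
#' @param de Optional [de_test()] result matched by gene symbol.
#' @param kegg_gene_set Character vector of pathway member genes.
#' @param genes Genes to score (default: all genes in the annotation table,
#'   extend to include DE-only genes via this argument).
#' @param de_alpha Significance level for the DE component.
#' @return Data frame of per-gene scores (one row per gene), class
#'   `"gene_score"`.
#' @seealso [score_gene()], [rank_genes()]
#' @export
score_genes <- function(annotations, de = NULL, kegg_gene_set = character(),
                        genes = unique(annotations$gene_symbol),
                        de_alpha = NULL) {
  if (is.null(de_alpha) && !is.null(de) && !is.null(attr(de, "de_alpha")))
    de_alpha <- attr(de, "de_alpha")
  rows <- lapply(genes, function(g) {
    de_row <- NULL
    if (!is.null(de)) {
      hit <- which(de$gene == g)
      if (length(hit)) de_row <- de[hit[1L], , drop = FALSE]
    }
    sc <- score_gene(annotations[annotations$gene_symbol == g, , drop = FALSE],
                     de = de_row, in_kegg = g %in% kegg_gene_set,
                     de_alpha = de_alpha)
    sc$gene <- g
    sc
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gene_score", "data.frame")
  out
}

#' Rank scored genes
#'
#' Orders genes by descending total score, ties broken alphabetically by
#' gene symbol.  Genes with total 0 stay at the bottom and are flagged
#' `unscored` (non-polymorphic or carrying no scoring feature).
#'
#' @param scores A [score_genes()] result (one row per gene).
#' @return The reordered data.frame with an added logical `unscored`
#'   column.
#' @export
rank_genes <- function(scores) {
  if (anyDuplicated(scores$gene))
    stop("duplicate gene entries; aggregate scores per gene first")
  scores <- scores[order(-scores$total, scores$gene), , drop = FALSE]
  scores$unscored <- scores$total == 0L
  rownames(scores) <- NULL
  scores
}
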