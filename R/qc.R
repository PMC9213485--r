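#' Marker quality control for a two-founder cross
#'
#' Applies, in order, the three filtering rules used to reduce the raw
#' marker set to the analysis set:
#' \enumerate{
#'   \item remove markers whose calls are all missing;
#'   \item remove non-segregating markers (exactly one observed genotype
#'     class among HOM1/HET/HOM2);
#'   \item require at least two genotype classes with at least `group_min`
#'     non-missing observations each.  Markers failing this are removed;
#'     markers passing it keep their calls except that any class with fewer
#'     than `group_min` observations is masked to missing (the marker is
#'     kept), preventing spurious associations driven by tiny groups.
#' }
#' Masking is symmetric across classes: a small heterozygote class is masked
#' just like a small homozygote class.
#'
#' @param geno A [genotype_matrix()].
#' @param group_min Minimum per-class observation count (default 10, the
#'   conventional choice for an F2/AIL of ~100 animals).
#' @return A list with elements `geno` (the filtered genotype matrix) and
#'   `report` (class `"qc_report"`): counts of input markers, markers removed
#'   by each rule, calls masked, and output markers.
#' @examples
#' g <- rbind(a = c(2, 2), b = c(1, NA), c = c(0, NA), d = c(2, 2))
#' colnames(g) <- c("m1", "m2")
#' gm <- genotype_matrix(g, marker_map(c("m1", "m2"), c("1", "1"), c(100, 200)))
#' apply_marker_qc(gm, group_min = 1)$report
#' @export
apply_marker_qc <- function(geno, group_min = 10L) {
  stopifnot(inherits(geno, "geno"), group_min >= 1)
  calls <- geno$calls
  n_input <- ncol(calls)

  counts <- vapply(seq_len(ncol(calls)), function(j) class_counts(calls[, j]),
                   integer(3))  # 3 x markers

  all_missing <- colSums(counts) == 0L
  n_classes <- colSums(counts > 0L)
  non_seg <- !all_missing & n_classes == 1L

  big <- colSums(counts >= group_min)
  group_fail <- !all_missing & !non_seg & big < 2L

  keep <- !(all_missing | non_seg | group_fail)

  # mask small classes on surviving markers
  n_masked <- 0L
  for (j in which(keep)) {
    small <- counts[, j] > 0L & counts[, j] < group_min
    if (any(small)) {
      codes <- .class_codes[names(which(small))]
      idx <- calls[, j] %in% codes
      n_masked <- n_masked + sum(idx)
      calls[idx, j] <- NA_integer_
    }
  }

  out <- genotype_matrix(calls[, keep, drop = FALSE],
                         geno$map[geno$map$marker_id %in% colnames(calls)[keep], ,
                                  drop = FALSE])
  report <- structure(list(
    n_input_markers = n_input,
    n_removed_all_missing = sum(all_missing),
    n_removed_non_segregating = sum(non_seg),
    n_removed_group_rule = sum(group_fail),
    n_masked_calls = n_masked,
    n_output_markers = sum(keep),
    group_min = as.integer(group_min)), class = "qc_report")
  if (report$n_output_markers == 0L)
    message("marker QC removed every marker; downstream scans will be empty")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Marker QC (group_min = %d)\n",
    "  input markers:            %d\n",
    "  removed, all missing:     %d\n",
    "  removed, non-segregating: %d\n",
    "  removed, small groups:    %d\n",
    "  calls masked to missing:  %d\n",
    "  output markers:           %d\n"),
    x$group_min, x$n_input_markers, x$n_removed_all_missing,
    x$n_removed_non_segregating, x$n_removed_group_rule,
    x$n_masked_calls, x$n_output_markers))
  invisible(x)
}
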