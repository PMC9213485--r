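#' Format a genotype-class mean contrast
#'
#' Turns two covariate-adjusted class means into the effect figure used in
#' reporting: either the percent increase of the first class over the
#' second, `(m1 / m2 - 1) * 100`, rounded to the nearest whole percent for
#' display, or the absolute difference `m1 - m2` in trait units, displayed
#' at two decimals.
#'
#' @param m1,m2 Class means (e.g. from [adjusted_class_means()] or a scan
#'   table), `m1` the class being described, `m2` the reference class.
#' @param type `"percent"` or `"difference"`.
#' @return List with `value` (full precision) and `display` (rounded as
#'   above).
#' @examples
#' class_contrast(1.81, 1.55)$display            # 17 (percent)
#' class_contrast(42.46, 32.37, "difference")$display  # 10.09 (units)
#' @export
class_contrast <- function(m1, m2, type = c("percent", "difference")) {
  type <- match.arg(type)
  stopifnot(is.finite(m1), is.finite(m2))
  if (type == "percent") {
    if (m2 == 0) stop("percent contrast undefined for a zero reference mean")
    v <- (m1 / m2 - 1) * 100
    list(value = v, display = round(v))
  } else {
    v <- m1 - m2
    list(value = v, display = round(v, 2))
  }
}
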