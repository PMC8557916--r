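# TMT-style quantification: per-sample total-intensity normalization and
# two-sample Student's t-test differential expression with fold-change and
# p-value gates.

#' Normalize a reporter-intensity matrix by per-sample totals
#'
#' Each column is divided by its total intensity; by default columns are then
#' rescaled by the mean of the original column sums so values stay on the
#' intensity scale. All normalized column sums are equal either way.
#'
#' @param matrix Numeric matrix, proteins in rows, samples in columns; no
#'   negative values.
#' @param rescale Rescale by the mean original column sum (default `TRUE`).
#' @return Normalized matrix of the same shape.
#' @export
normalize_intensities <- function(matrix, rescale = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(matrix < 0)) stop("negative intensities", call. = FALSE)
  totals <- colSums(matrix)
  if (any(totals == 0)) stop("zero-sum sample column(s)", call. = FALSE)
  out <- sweep(matrix, 2, totals, "/")
  if (rescale) out <- out * mean(totals)
  out
}

#' Call differentially expressed proteins (DEPs)
#'
#' Per protein: fold change as the ratio of condition means
#' (treatment/control) on the normalized intensities, and an equal-variance
#' two-sample Student's t test (Welch available via `var_equal = FALSE`). A
#' protein is a DEP when the fold change is `>= fc_up` or `<= fc_down` and
#' the p-value is `< alpha`. No multiple-testing correction is applied by
#' default (`adjust = "none"`); Benjamini-Hochberg is available via
#' `adjust = "BH"`.
#'
#' @param matrix Normalized intensity matrix ([normalize_intensities()]).
#' @param groups Character/factor vector, one label per column.
#' @param treatment,control The two group labels to compare; default the
#'   second and first unique label.
#' @param fc_up,fc_down DEP fold-change gates (defaults 1.2 and 0.83).
#' @param alpha DEP p-value gate (default 0.05, strict `<`).
#' @param var_equal Equal-variance (Student's) t test (default `TRUE`).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   for the DEP gate (default `"none"`).
#' @return `data.frame`: `protein_id`, `mean_control`, `mean_treatment`,
#'   `fold_change`, `p_value`, `p_adjusted`, `is_dep`, in input row order.
#' @export
call_deps <- function(matrix, groups, treatment = NULL, control = NULL,
                      fc_up = 1.2, fc_down = 0.83, alpha = 0.05,
                      var_equal = TRUE, adjust = "none") {
  stopifnot(length(groups) == ncol(matrix))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (is.null(control)) control <- lv[1]
  if (is.null(treatment)) treatment <- setdiff(lv, control)[1]
  ti <- which(groups == treatment)
  ci <- which(groups == control)
  if (length(ti) < 2L || length(ci) < 2L)
    stop("each compared condition needs at least 2 replicates", call. = FALSE)
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("protein", seq_len(nrow(matrix)))
  res <- t(vapply(seq_len(nrow(matrix)), function(i) {
    x <- matrix[i, ti]
    y <- matrix[i, ci]
    p <- if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0   # degenerate: no within-group spread
    } else {
      stats::t.test(x, y, var.equal = var_equal)$p.value
    }
    c(mean_control = mean(y), mean_treatment = mean(x),
      fold_change = mean(x) / mean(y), p_value = p)
  }, c(mean_control = 0, mean_treatment = 0, fold_change = 0, p_value = 0)))
  out <- data.frame(protein_id = ids, res, stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$is_dep <- (out$fold_change >= fc_up | out$fold_change <= fc_down) &
    out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
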