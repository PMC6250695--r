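#' Median-of-ratios library-size factors
#'
#' Per-sample scale factor = median, over genes with all-positive
#' counts, of the ratio of the gene's count to its geometric mean across
#' samples; factors are rescaled to geometric mean 1. This is the
#' standard library-size adjustment for over-dispersed count data.
#'
#' @param counts An [expression_matrix()] of kind `counts`.
#' @return Named numeric vector of class `SizeFactors` (one positive
#'   factor per sample, geometric mean 1).
#' @export
median_of_ratios <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$value_kind != "counts") {
    stop_validation("median_of_ratios requires a counts matrix")
  }
  x <- counts$values
  if (ncol(x) == 1) {
    sf <- stats::setNames(1, counts$sample_ids)
    class(sf) <- "SizeFactors"
    return(sf)
  }
  eligible <- rowSums(x > 0) == ncol(x)
  if (!any(eligible)) {
    stop_validation(paste("no gene has positive counts in every sample;",
                          "filter all-zero-containing genes or supply factors"))
  }
  logx <- log(x[eligible, , drop = FALSE])
  log_geo <- rowMeans(logx)
  sf <- apply(logx, 2, function(col) exp(stats::median(col - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  sf <- stats::setNames(as.numeric(sf), counts$sample_ids)
  class(sf) <- "SizeFactors"
  sf
}

#' Two-group differential-expression test
#'
#' A self-contained stand-in for a full count-model DE engine:
#' counts are divided by median-of-ratios size factors, shifted by a
#' pseudocount of 1 and log2-transformed; each gene is tested with a
#' Welch t-test between the two groups, and p-values are BH-adjusted.
#' `log2fc` is the difference of group means of `log2(normalized + 1)`
#' (B minus A). Genes with zero counts in every used sample get
#' `log2fc = 0`, `p = p_adj = 1` so the table stays complete for
#' universe accounting. Externally produced DE tables (from any engine)
#' are accepted everywhere a `DEResultTable` is, via [read_de_table()].
#'
#' @param counts An [expression_matrix()] of kind `counts`.
#' @param design A [sample_design()] covering the matrix's samples.
#' @param groupA,groupB Group labels; the contrast is B minus A.
#' @param size_factors Optional [median_of_ratios()] output; computed
#'   from the used samples when `NULL`.
#' @return A [de_result_table()] with one row per gene, in input order.
#' @export
de_test <- function(counts, design, groupA, groupB, size_factors = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"), inherits(design, "SampleDesign"))
  for (g in c(groupA, groupB)) {
    if (!g %in% design$group) stop_validation(sprintf("group '%s' absent from design", g))
  }
  sA <- design_samples(design, groupA)
  sB <- design_samples(design, groupB)
  if (length(sA) < 2 || length(sB) < 2) {
    stop_validation("each compared group needs at least 2 samples")
  }
  used <- c(sA, sB)
  missing <- setdiff(used, counts$sample_ids)
  if (length(missing)) {
    stop_validation(sprintf("sample '%s' not in count matrix", missing[[1]]))
  }
  sub <- counts$values[, used, drop = FALSE]
  if (is.null(size_factors)) {
    size_factors <- median_of_ratios(
      expression_matrix(sub, "counts"))
  }
  sf <- unclass(size_factors)[used]
  if (anyNA(sf)) stop_validation("size factors missing for some used samples")
  norm <- sweep(sub, 2, sf, `/`)
  logn <- log2(norm + 1)

  welch <- welch_rows(logn[, sA, drop = FALSE], logn[, sB, drop = FALSE])
  all_zero <- rowSums(sub) == 0
  log2fc <- welch$meanB - welch$meanA
  p <- welch$p
  log2fc[all_zero] <- 0
  p[all_zero] <- 1
  p_adj <- bh_adjust(p)
  de_result_table(data.frame(
    gene_id = counts$gene_ids, log2fc = log2fc, p = p, p_adj = p_adj,
    base_mean = rowMeans(norm), stringsAsFactors = FALSE))
}

# Vectorized per-row Welch t-test; returns group means and two-sided p.
# Rows with zero variance in both groups get p = 1 when means are equal
# and p = 0 when they differ (degenerate separation).
welch_rows <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- rowSums((a - mA)^2) / (nA - 1)
  vB <- rowSums((b - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t_stat <- (mB - mA) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(mA[degen] == mB[degen], 1, 0)
  list(meanA = mA, meanB = mB, p = as.numeric(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, order-preserving with the
#' input. Thin validating wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
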