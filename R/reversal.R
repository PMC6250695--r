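# Per-gene and per-pathway quantification of treatment reversal of
# disease expression, and the marker relative-expression matrix.

#' Classify per-gene treatment reversal
#'
#' A gene is a disease DEG iff its FDR-adjusted p-value in the
#' disease-vs-healthy contrast is at most `alpha`. A disease DEG counts
#' as reversed iff its treated-vs-disease log2 fold change opposes the
#' sign of its disease-vs-healthy log2 fold change (both nonzero), the
#' treated-vs-disease change is itself significant at `treated_alpha`,
#' and -- under `rule = "strict"` -- the treated state additionally lands
#' closer to healthy than the disease state did
#' (`|lfc_disease + lfc_treated| < |lfc_disease|`). Setting
#' `treated_alpha = 1` disables the significance gate and yields the
#' plain sign-opposition rule, under which a treatment with no effect
#' still "reverses" about half of the disease genes by chance.
#'
#' @param disease_vs_healthy,treated_vs_disease [de_result_table()]s
#'   sharing gene ids; genes present in only one table are excluded with
#'   a warning.
#' @param alpha FDR threshold defining a disease DEG (default 0.05).
#' @param treated_alpha FDR threshold the treated-vs-disease change must
#'   meet to count as a reversal (default `alpha`; set to 1 for the
#'   ungated sign rule).
#' @param rule `"sign"` (default) or `"strict"` (see above).
#' @return A data.frame of class `ReversalStatus` with columns
#'   `gene_id`, `is_deg`, `is_reversed`, `status` (one of `not_deg`,
#'   `deg_reversed`, `deg_not_reversed`); attribute `n_excluded` counts
#'   genes present in one table only.
#' @export
classify_reversal <- function(disease_vs_healthy, treated_vs_disease,
                              alpha = 0.05, treated_alpha = alpha,
                              rule = c("sign", "strict")) {
  rule <- match.arg(rule)
  stopifnot(inherits(disease_vs_healthy, "DEResultTable"),
            inherits(treated_vs_disease, "DEResultTable"))
  shared <- intersect(disease_vs_healthy$gene_id, treated_vs_disease$gene_id)
  n_excluded <- length(union(disease_vs_healthy$gene_id,
                             treated_vs_disease$gene_id)) - length(shared)
  if (n_excluded > 0) {
    warning(sprintf("%d gene(s) present in only one table were excluded",
                    n_excluded), call. = FALSE)
  }
  dd <- disease_vs_healthy[match(shared, disease_vs_healthy$gene_id), ]
  tt <- treated_vs_disease[match(shared, treated_vs_disease$gene_id), ]

  is_deg <- !is.na(dd$p_adj) & dd$p_adj <= alpha
  sign_opposed <- !is.na(tt$log2fc) & dd$log2fc != 0 & tt$log2fc != 0 &
    sign(tt$log2fc) == -sign(dd$log2fc)
  treated_sig <- !is.na(tt$p_adj) & tt$p_adj <= treated_alpha
  is_rev <- is_deg & sign_opposed & treated_sig
  if (rule == "strict") {
    closer <- abs(dd$log2fc + tt$log2fc) < abs(dd$log2fc)
    is_rev <- is_rev & closer
  }
  status <- ifelse(!is_deg, "not_deg",
                   ifelse(is_rev, "deg_reversed", "deg_not_reversed"))
  out <- data.frame(gene_id = shared, is_deg = is_deg, is_reversed = is_rev,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("ReversalStatus", "data.frame")
  out
}

#' Percent of disease DEGs reversed by treatment, per pathway
#'
#' For each gene set, counts its members that are disease DEGs and the
#' subset of those classified as reversed;
#' `percent_reversed = 100 * n_reversed / n_disease_degs`. Pathways with
#' zero disease DEGs are reported with `NA` percent, not dropped.
#' Pathway members not in the status table (unmeasured genes) are
#' ignored, so the percentage is invariant to padding a pathway with
#' non-DEG genes.
#'
#' @param status Output of [classify_reversal()].
#' @param pathways A [gene_set_collection()].
#' @return A data.frame with one row per pathway: `pathway_name`,
#'   `n_pathway_genes`, `n_disease_degs`, `n_reversed`,
#'   `percent_reversed`.
#' @export
pathway_percent_reversed <- function(status, pathways) {
  stopifnot(inherits(status, "ReversalStatus"), inherits(pathways, "GeneSetCollection"))
  rows <- lapply(seq_along(pathways$sets), function(i) {
    members <- pathways$sets[[i]]
    in_tab <- status[status$gene_id %in% members, , drop = FALSE]
    n_deg <- sum(in_tab$is_deg)
    n_rev <- sum(in_tab$is_reversed)
    data.frame(pathway_name = names(pathways$sets)[i],
               n_pathway_genes = length(members),
               n_disease_degs = n_deg, n_reversed = n_rev,
               percent_reversed = if (n_deg > 0) 100 * n_rev / n_deg else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marker expression relative to a reference group
#'
#' For each marker gene and group: the log2 ratio of the group's mean
#' normalized expression (pseudocount 1) to the reference group's, so
#' the reference column is identically zero. Markers absent from the
#' matrix are omitted with a warning and listed in the `missing_markers`
#' attribute.
#'
#' @param counts An [expression_matrix()] of kind `counts`.
#' @param design A [sample_design()].
#' @param markers Character vector of marker gene ids.
#' @param reference_group Group label used as baseline.
#' @param size_factors Optional [median_of_ratios()] output.
#' @return Numeric matrix markers x groups of log2 ratios.
#' @export
marker_relative_matrix <- function(counts, design, markers, reference_group,
                                   size_factors = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"), inherits(design, "SampleDesign"))
  groups <- attr(design, "group_levels")
  if (!reference_group %in% groups) {
    stop_validation(sprintf("reference group '%s' not in design", reference_group))
  }
  missing <- setdiff(markers, counts$gene_ids)
  if (length(missing)) {
    warning(sprintf("marker(s) absent from matrix and omitted: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  markers <- intersect(markers, counts$gene_ids)
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  sf <- unclass(size_factors)[counts$sample_ids]
  norm <- sweep(counts$values[markers, , drop = FALSE], 2, sf, `/`)
  group_means <- vapply(groups, function(g) {
    rowMeans(norm[, design_samples(design, g), drop = FALSE])
  }, numeric(length(markers)))
  if (length(markers) == 1) group_means <- matrix(group_means, nrow = 1,
                                                  dimnames = list(markers, groups))
  logm <- log2(group_means + 1)
  out <- logm - logm[, reference_group]
  attr(out, "missing_markers") <- missing
  out
}
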