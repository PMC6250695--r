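#' Directional signature (paired up/down feature lists)
#'
#' @param up,down Character vectors of feature ids, ordered by strength.
#' @param n_per_arm Configured per-arm cap.
#' @param source Provenance string.
#' @return Object of class `DirectionalSignature`.
#' @export
directional_signature <- function(up, down, n_per_arm, source = "") {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop_validation("ids must be unique within each arm")
  }
  if (length(intersect(up, down))) {
    stop_validation(sprintf("arms overlap at '%s'", intersect(up, down)[1]))
  }
  if (length(up) > n_per_arm || length(down) > n_per_arm) {
    stop_validation("arm exceeds n_per_arm cap")
  }
  structure(list(up = up, down = down, n_per_arm = as.integer(n_per_arm),
                 source = source),
            class = "DirectionalSignature")
}

#' @export
print.DirectionalSignature <- function(x, ...) {
  cat(sprintf("DirectionalSignature: %d up / %d down (cap %d)%s\n",
              length(x$up), length(x$down), x$n_per_arm,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Robust z-scoring of log-expression profiles
#'
#' Per sample column: `z = (x - median) / (1.4826 * MAD)`, where MAD is
#' the median absolute deviation from the column median and 1.4826 makes
#' the scale consistent with a normal SD. This is the differential
#' expression transform applied to normalized landmark profiles before
#' signature extraction and connectivity scoring.
#'
#' @param profile An [expression_matrix()] of kind `logexpr` with at
#'   least 3 features per sample.
#' @return An [expression_matrix()] of kind `zscore`.
#' @export
robust_z <- function(profile) {
  stopifnot(inherits(profile, "ExpressionMatrix"))
  if (profile$value_kind != "logexpr") {
    stop_validation("robust_z expects a log-expression matrix")
  }
  if (length(profile$gene_ids) < 3) {
    stop_validation("robust_z needs at least 3 features per sample")
  }
  z <- profile$values
  for (j in seq_len(ncol(z))) {
    x <- profile$values[, j]
    med <- stats::median(x)
    scale <- stats::mad(x)  # 1.4826 * median(|x - median|)
    if (scale == 0) {
      stop_validation(sprintf("degenerate profile: MAD is zero in sample '%s'",
                              profile$sample_ids[j]))
    }
    z[, j] <- (x - med) / scale
  }
  expression_matrix(z, "zscore")
}

signature_ranking <- function(x) {
  if (inherits(x, "DEResultTable")) {
    # genes filtered before testing (p_adj missing) never enter signatures
    keep <- !is.na(x$p_adj)
    stats::setNames(x$log2fc[keep], x$gene_id[keep])
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop_validation("expected a DEResultTable or a named numeric vector")
  }
}

#' Extract the top-N up/down directional signature
#'
#' Ranks features by the signed key (log2 fold change for a DE table, z
#' for a named z-score vector); the up arm takes the `n_per_arm` largest
#' strictly positive values, the down arm the `n_per_arm` most negative.
#' Features with a missing key are excluded first; zero-valued features
#' enter neither arm. Ties are broken by (|value| descending, id
#' ascending), so at an arm boundary the lexicographically smaller id is
#' kept.
#'
#' @param x A [de_result_table()] or a named numeric vector (one z-score
#'   column).
#' @param n_per_arm Per-arm cap (e.g. 250 per arm for a top-500
#'   cross-species signature, 500 per arm for a CMAP disease signature).
#' @param source Provenance string stored on the signature.
#' @return A [directional_signature()].
#' @export
extract_signature <- function(x, n_per_arm, source = "") {
  if (n_per_arm <= 0) stop_validation("n_per_arm must be positive")
  key <- signature_ranking(x)
  key <- key[!is.na(key)]
  ids <- names(key)
  pos <- key > 0
  neg <- key < 0
  up_ord <- order(-key[pos], ids[pos])
  down_ord <- order(key[neg], ids[neg])
  directional_signature(
    up = utils::head(ids[pos][up_ord], n_per_arm),
    down = utils::head(ids[neg][down_ord], n_per_arm),
    n_per_arm = n_per_arm, source = source)
}

#' Threshold-based up/down gene sets
#'
#' Inclusive comparisons: `up` holds genes with `log2fc >= tau`, `down`
#' genes with `log2fc <= -tau`.
#'
#' @param table A [de_result_table()].
#' @param tau Positive log2 fold-change threshold (the cross-species
#'   comparisons use 0.5).
#' @return Object of class `ThresholdSet` with elements `up`, `down`,
#'   `tau`.
#' @export
threshold_set <- function(table, tau) {
  stopifnot(inherits(table, "DEResultTable"))
  if (!is.numeric(tau) || tau <= 0) stop_validation("tau must be positive")
  keep <- !is.na(table$log2fc) & !is.na(table$p_adj)
  structure(list(up = table$gene_id[keep & table$log2fc >= tau],
                 down = table$gene_id[keep & table$log2fc <= -tau],
                 tau = tau),
            class = "ThresholdSet")
}

#' Write a directional signature as a pair of GRP files
#'
#' @param sig A [directional_signature()].
#' @param prefix Path prefix; writes `<prefix>_up.grp` and
#'   `<prefix>_down.grp`.
#' @return The two paths, invisibly.
#' @export
write_signature <- function(sig, prefix) {
  stopifnot(inherits(sig, "DirectionalSignature"))
  paths <- paste0(prefix, c("_up.grp", "_down.grp"))
  write_grp(sig$up, paths[1])
  write_grp(sig$down, paths[2])
  invisible(paths)
}
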