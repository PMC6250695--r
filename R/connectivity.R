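# Weighted Kolmogorov-Smirnov connectivity scoring of compound z-score
# profiles against directional disease signatures, with a permutation
# null and collection-level screening.

# Rank positions (1 = largest z) of all features of a profile column;
# ties broken by feature id ascending for platform-independent
# determinism.
profile_ranking <- function(z) {
  ids <- names(z)
  ord <- order(-z, ids)
  stats::setNames(seq_along(ord)[order(ord)], ids)  # id -> rank position
}

# Signed maximum running-sum deviation (unit-weight KS enrichment) of an
# arm whose members sit at sorted positions `pos` among `n` ranked
# features. The running sum after rank k is
#   D(k) = (#members <= k)/t - (k - #members <= k)/(n - t),
# i.e. the proportion of arm members seen so far minus the proportion of
# non-members. ES is D at the position of maximum |D|; D is piecewise
# linear, so only the jump points k = pos_i and k = pos_i - 1 need
# evaluating. Deviations are compared in exact integer arithmetic
# (common denominator t*(n-t)); when the maximal positive and negative
# deviations tie exactly the arm carries no direction and ES is 0 --
# the only value consistent with reversal antisymmetry.
es_from_positions <- function(pos, n) {
  t <- length(pos)
  if (t >= n) stop_validation("arm cannot cover the whole feature space")
  i <- seq_len(t)
  d_hi <- i * (n - t) - (pos - i) * t            # D just after each hit (scaled)
  d_lo <- d_hi - (n - t)                         # D just before each hit
  d_max <- max(d_hi, 0)
  d_min <- min(d_lo, 0)
  if (d_max > -d_min) {
    d_max / (t * (n - t))
  } else if (-d_min > d_max) {
    d_min / (t * (n - t))
  } else {
    0
  }
}

#' Weighted-KS connectivity score of a profile against a signature
#'
#' Features are ranked by z descending (ties broken by feature id
#' ascending). For each signature arm the signed maximum deviation of
#' the running proportion of arm members versus non-members along the
#' ranking is computed (`ES_up`, `ES_down`); the connectivity score is
#' `(ES_up - ES_down) / 2` when the two enrichment signs differ and 0
#' otherwise. Positive scores mean the profile mimics the disease
#' signature (up tags at the top, down tags at the bottom); negative
#' scores mean it opposes it. The score lies in `[-1, 1]` and, being
#' rank-based, is invariant under strictly monotone transforms of z.
#'
#' @param profile_column Named numeric vector of z-scores over features.
#' @param signature A [directional_signature()] with non-empty arms
#'   whose features all occur in the profile.
#' @param method `"ks"` (default, the canonical connectivity statistic)
#'   or `"spearman"` (rank correlation of the profile's z values with a
#'   +1/-1 template restricted to signature members, a sensitivity
#'   scorer for the literal "inverse correlation" reading).
#' @return Signed score in `[-1, 1]`.
#' @export
ks_connectivity <- function(profile_column, signature, method = c("ks", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(signature, "DirectionalSignature"))
  if (!length(signature$up) || !length(signature$down)) {
    stop_validation("both signature arms must be non-empty")
  }
  missing <- setdiff(c(signature$up, signature$down), names(profile_column))
  if (length(missing)) {
    stop_validation(sprintf("signature feature(s) missing from profile: %s",
                            paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (method == "spearman") {
    members <- c(signature$up, signature$down)
    template <- c(rep(1, length(signature$up)), rep(-1, length(signature$down)))
    return(as.numeric(stats::cor(profile_column[members], template,
                                 method = "spearman")))
  }
  ranks <- profile_ranking(profile_column)
  n <- length(profile_column)
  es_up <- es_from_positions(sort(ranks[signature$up]), n)
  es_down <- es_from_positions(sort(ranks[signature$down]), n)
  if (sign(es_up) != sign(es_down) && es_up != 0 && es_down != 0) {
    (es_up - es_down) / 2
  } else {
    0
  }
}

connectivity_result <- function(compound_id, score, p_perm, n_perms, alpha,
                                p_adj = p_perm) {
  call <- if (!is.na(p_adj) && p_adj <= alpha) {
    if (score < 0) "inverse" else if (score > 0) "concordant" else "null"
  } else "null"
  structure(list(compound_id = compound_id, score = score, p_perm = p_perm,
                 n_perms = n_perms, direction_call = call),
            class = "ConnectivityResult")
}

#' @export
print.ConnectivityResult <- function(x, ...) {
  cat(sprintf("ConnectivityResult %s: score %.4f, p_perm %.4g (%d perms) -> %s\n",
              x$compound_id, x$score, x$p_perm, x$n_perms, x$direction_call))
  invisible(x)
}

# Null connectivity scores from random arms of the given sizes. The KS
# score is rank-based, so this null depends only on (n features, arm
# sizes) and can be shared across compounds scored against the same
# signature.
null_connectivity_scores <- function(n_features, n_up, n_down, n_perms) {
  if (n_up + n_down > n_features) {
    stop_validation("signature arms exceed the profile's feature count")
  }
  vapply(seq_len(n_perms), function(b) {
    pos <- sample.int(n_features, n_up + n_down)
    es_up <- es_from_positions(sort(pos[seq_len(n_up)]), n_features)
    es_down <- es_from_positions(sort(pos[n_up + seq_len(n_down)]), n_features)
    if (sign(es_up) != sign(es_down) && es_up != 0 && es_down != 0) {
      (es_up - es_down) / 2
    } else 0
  }, numeric(1))
}

#' Permutation p-value for one compound-signature pair
#'
#' The null re-draws random disjoint arms of the observed sizes from the
#' profile's feature space and rescores; the two-sided p-value is
#' `(1 + #\{|s*| >= |s_obs|\}) / (n_perms + 1)`. Direction is assessed
#' separately by the score's sign.
#'
#' @inheritParams ks_connectivity
#' @param n_perms Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param alpha Significance level used for the direction call.
#' @param compound_id Label stored on the result.
#' @param null_scores Optional precomputed null score vector (used by
#'   [screen_collection()] to share one null across compounds).
#' @return A `ConnectivityResult`: `compound_id`, `score`, `p_perm`,
#'   `n_perms`, `direction_call` in `{inverse, concordant, null}`.
#' @export
permutation_p <- function(profile_column, signature, n_perms = 999, seed = 1,
                          alpha = 0.05, compound_id = "compound",
                          method = c("ks", "spearman"), null_scores = NULL) {
  method <- match.arg(method)
  if (is.null(null_scores) && n_perms < 100) {
    stop_validation("n_perms must be at least 100")
  }
  s_obs <- ks_connectivity(profile_column, signature, method = method)
  if (is.null(null_scores)) {
    null_scores <- with_substream(seed, "perm_null", {
      if (method == "ks") {
        null_connectivity_scores(length(profile_column), length(signature$up),
                                 length(signature$down), n_perms)
      } else {
        n <- length(profile_column)
        vapply(seq_len(n_perms), function(b) {
          idx <- sample.int(n, length(signature$up) + length(signature$down))
          fake <- directional_signature(
            names(profile_column)[idx[seq_along(signature$up)]],
            names(profile_column)[idx[length(signature$up) + seq_along(signature$down)]],
            n_per_arm = max(lengths(signature[c("up", "down")])))
          ks_connectivity(profile_column, fake, method = "spearman")
        }, numeric(1))
      }
    })
  }
  n_perms <- length(null_scores)
  p <- (1 + sum(abs(null_scores) >= abs(s_obs))) / (n_perms + 1)
  connectivity_result(compound_id, s_obs, p, n_perms, alpha)
}

#' Screen a compound collection against a disease signature
#'
#' Scores every compound profile, attaches permutation p-values from a
#' single shared null (valid because the rank-based null distribution
#' depends only on the feature count and arm sizes), BH-adjusts across
#' compounds, and calls a compound `inverse` iff its score is negative
#' and its adjusted p-value is at most `alpha`. Results are sorted by
#' score ascending, so the strongest inverse candidate ranks first.
#'
#' @param profiles An [expression_matrix()] of kind `zscore`
#'   (features x compounds).
#' @param signature A [directional_signature()].
#' @param alpha BH-adjusted significance level for direction calls.
#' @param n_perms Number of shared null permutations.
#' @param seed Integer seed.
#' @inheritParams ks_connectivity
#' @return A data.frame of class `ConnectivityScreen` with columns
#'   `compound_id`, `score`, `p_perm`, `p_adj`, `direction_call`.
#' @export
screen_collection <- function(profiles, signature, alpha = 0.05, n_perms = 499,
                              seed = 1, method = c("ks", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles, "ExpressionMatrix"))
  if (!length(profiles$sample_ids)) {
    out <- data.frame(compound_id = character(0), score = numeric(0),
                      p_perm = numeric(0), p_adj = numeric(0),
                      direction_call = character(0), stringsAsFactors = FALSE)
    class(out) <- c("ConnectivityScreen", "data.frame")
    return(out)
  }
  scores <- vapply(profiles$sample_ids, function(cpd) {
    ks_connectivity(stats::setNames(profiles$values[, cpd], profiles$gene_ids),
                    signature, method = method)
  }, numeric(1))
  null_scores <- with_substream(seed, "screen_null", {
    if (method == "ks") {
      null_connectivity_scores(length(profiles$gene_ids), length(signature$up),
                               length(signature$down), n_perms)
    } else {
      stop_validation("screening is only implemented for the KS scorer")
    }
  })
  p <- vapply(scores, function(s) {
    (1 + sum(abs(null_scores) >= abs(s))) / (n_perms + 1)
  }, numeric(1))
  p_adj <- bh_adjust(p)
  call <- ifelse(p_adj <= alpha & scores < 0, "inverse",
                 ifelse(p_adj <= alpha & scores > 0, "concordant", "null"))
  out <- data.frame(compound_id = profiles$sample_ids, score = scores,
                    p_perm = p, p_adj = p_adj, direction_call = call,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$compound_id), ]
  rownames(out) <- NULL
  class(out) <- c("ConnectivityScreen", "data.frame")
  out
}
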