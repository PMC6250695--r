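# Cross-species signature concordance and reversal: ortholog mapping,
# directional 2x2 overlap tables over the mappable universe, Fisher's
# exact test and sample odds ratio.

#' Ortholog map between two gene-identifier spaces
#'
#' Pairs of (source, target) ids with a declared many-to-many resolution
#' policy: `one2one_only` removes every source and target involved in a
#' multi-mapping; `first_alphabetical` keeps, for each duplicated id,
#' the pair with the lexicographically smallest counterpart.
#'
#' @param source_id,target_id Character vectors of equal length.
#' @param policy Resolution policy.
#' @param resolve Apply the policy now (default) or lazily at use time.
#' @return Object of class `OrthologMap` with elements `pairs`
#'   (data.frame) and `policy`.
#' @export
ortholog_map <- function(source_id, target_id,
                         policy = c("one2one_only", "first_alphabetical"),
                         resolve = TRUE) {
  policy <- match.arg(policy)
  if (length(source_id) != length(target_id)) {
    stop_validation("source_id and target_id must have equal length")
  }
  pairs <- unique(data.frame(source_id = as.character(source_id),
                             target_id = as.character(target_id),
                             stringsAsFactors = FALSE))
  out <- structure(list(pairs = pairs, policy = policy), class = "OrthologMap")
  if (resolve) out$pairs <- resolved_pairs(out)
  out
}

#' @export
print.OrthologMap <- function(x, ...) {
  cat(sprintf("OrthologMap: %d pairs (policy %s)\n", nrow(x$pairs), x$policy))
  invisible(x)
}

# Apply the map's resolution policy, returning a one-to-one pair table.
resolved_pairs <- function(map) {
  p <- map$pairs
  if (!nrow(p)) return(p)
  if (map$policy == "one2one_only") {
    multi_src <- p$source_id[duplicated(p$source_id)]
    multi_tgt <- p$target_id[duplicated(p$target_id)]
    p <- p[!(p$source_id %in% multi_src) & !(p$target_id %in% multi_tgt), ,
           drop = FALSE]
  } else {
    p <- p[order(p$source_id, p$target_id), , drop = FALSE]
    p <- p[!duplicated(p$source_id), , drop = FALSE]
    p <- p[order(p$target_id, p$source_id), , drop = FALSE]
    p <- p[!duplicated(p$target_id), , drop = FALSE]
    p <- p[order(p$source_id), , drop = FALSE]
  }
  rownames(p) <- NULL
  p
}

#' Map gene ids through an ortholog map
#'
#' Unmapped ids are dropped and reported, never fatal. The map's
#' resolution policy is applied before mapping, so under `one2one_only`
#' a source with several targets is dropped entirely.
#'
#' @param ids Character vector of ids to map.
#' @param map An [ortholog_map()].
#' @param direction `"source_to_target"` or `"target_to_source"`.
#' @return A list: `mapped` (translated ids, input order, duplicates
#'   removed), `n_dropped`, `dropped_ids`.
#' @export
apply_ortholog_map <- function(ids, map,
                               direction = c("source_to_target", "target_to_source")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "OrthologMap"))
  p <- resolved_pairs(map)
  if (direction == "source_to_target") {
    from <- p$source_id; to <- p$target_id
  } else {
    from <- p$target_id; to <- p$source_id
  }
  ids <- as.character(ids)
  hit <- match(ids, from)
  dropped <- ids[is.na(hit)]
  mapped <- unique(to[hit[!is.na(hit)]])
  list(mapped = mapped, n_dropped = length(dropped), dropped_ids = dropped)
}

#' Fisher's exact test for overlap of two gene lists over a universe
#'
#' Builds the 2x2 table a = in both lists, b = list1 only, c = list2
#' only, d = in neither, with `a + b + c + d` equal to the declared
#' universe size, and computes the exact hypergeometric tail p-value.
#' The odds ratio reported is the plain sample odds ratio
#' `(a*d)/(b*c)`, with a Haldane 0.5 correction applied to every cell
#' iff any cell is zero (not the conditional-MLE estimate some software
#' reports).
#'
#' @param list1,list2 Character vectors, subsets of `universe`.
#' @param universe Character vector: the declared gene universe, e.g.
#'   genes measured in both studies and mappable one-to-one.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two_sided"`.
#' @return Object of class `OverlapResult` with fields `a`, `b`, `c`,
#'   `d`, `universe_n`, `odds_ratio`, `p_value`, `alternative`.
#' @export
fisher_overlap <- function(list1, list2, universe,
                           alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  list1 <- unique(as.character(list1))
  list2 <- unique(as.character(list2))
  out1 <- setdiff(list1, universe)
  if (length(out1)) stop_validation(sprintf("list1 element outside universe: '%s'", out1[[1]]))
  out2 <- setdiff(list2, universe)
  if (length(out2)) stop_validation(sprintf("list2 element outside universe: '%s'", out2[[1]]))
  a <- length(intersect(list1, list2))
  b <- length(list1) - a
  c <- length(list2) - a
  d <- length(universe) - a - b - c
  overlap_result(a, b, c, d, alternative)
}

# Construct an OverlapResult from table cells.
overlap_result <- function(a, b, c, d, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (min(a, b, c, d) < 0) stop_validation("table cells must be non-negative")
  n <- a + b + c + d
  m <- a + b       # size of list1
  k <- a + c       # size of list2
  if (alternative == "greater") {
    p <- stats::phyper(a - 1, m, n - m, k, lower.tail = FALSE)
  } else {
    # two-sided: total probability of tables (given margins) no more
    # likely than the observed one
    lo <- max(0L, k - (n - m)); hi <- min(m, k)
    probs <- stats::dhyper(lo:hi, m, n - m, k)
    p_obs <- stats::dhyper(a, m, n - m, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  p <- min(1, p)
  if (min(a, b, c, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  structure(list(a = a, b = b, c = c, d = d, universe_n = n,
                 odds_ratio = or, p_value = p, alternative = alternative),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: a=%d b=%d c=%d d=%d (universe %d); OR=%.3f, p=%.4g (%s)\n",
              x$a, x$b, x$c, x$d, x$universe_n, x$odds_ratio, x$p_value,
              x$alternative))
  invisible(x)
}

#' Cross-species directional concordance test
#'
#' Tests whether the up arm of a (human) directional signature overlaps
#' the up arm of a (mouse) threshold set, and likewise for the down
#' arms, over the universe of genes measured in both studies and
#' mappable between species. When `map` is given, the threshold set's
#' ids and the universe side of the second study are translated into the
#' signature's id space first.
#'
#' @param human_sig A [directional_signature()] in the target id space.
#' @param mouse_set A [threshold_set()] in the source id space (or
#'   already translated when `map` is `NULL`).
#' @param universe Character vector of mappable genes measured in both
#'   studies, in the signature's id space.
#' @param map Optional [ortholog_map()] (source = mouse, target =
#'   human).
#' @param alternative Passed to [fisher_overlap()].
#' @return List with elements `up` and `down`, each an `OverlapResult`.
#' @export
concordance_test <- function(human_sig, mouse_set, universe, map = NULL,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(human_sig, "DirectionalSignature"))
  if (!length(universe)) stop_validation("universe is empty")
  m_up <- mouse_set$up; m_down <- mouse_set$down
  if (!is.null(map)) {
    m_up <- apply_ortholog_map(m_up, map)$mapped
    m_down <- apply_ortholog_map(m_down, map)$mapped
  }
  list(up = fisher_overlap(intersect(human_sig$up, universe),
                           intersect(m_up, universe), universe, alternative),
       down = fisher_overlap(intersect(human_sig$down, universe),
                             intersect(m_down, universe), universe, alternative))
}

#' Cross-species reversal test
#'
#' Tests whether genes up-regulated in the (human) disease signature
#' overlap genes down-regulated by treatment in the (mouse) model --
#' i.e. a reversal of the disease signature by the compound -- over the
#' mappable universe.
#'
#' @param human_up_arm Character vector: the signature's up arm (target
#'   id space).
#' @param mouse_treated_down A [threshold_set()] down arm (character
#'   vector) from the vehicle-vs-treated contrast, or a `ThresholdSet`
#'   whose down arm is used.
#' @inheritParams concordance_test
#' @return An `OverlapResult`.
#' @export
reversal_test <- function(human_up_arm, mouse_treated_down, universe, map = NULL,
                          alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (inherits(mouse_treated_down, "ThresholdSet")) {
    mouse_treated_down <- mouse_treated_down$down
  }
  if (!length(universe)) stop_validation("universe is empty")
  if (!is.null(map)) {
    mouse_treated_down <- apply_ortholog_map(mouse_treated_down, map)$mapped
  }
  human_up_arm <- intersect(human_up_arm, universe)
  if (!length(human_up_arm)) {
    stop_validation("human up arm is empty after mapping to the universe; no test possible")
  }
  fisher_overlap(human_up_arm, intersect(mouse_treated_down, universe),
                 universe, alternative)
}
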