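# Non-transcriptomic endpoint statistics: NAFLD activity scoring,
# rank-based and ANOVA group comparisons, comparative-Ct qPCR
# quantification, and the mean +/- 2 SD outlier rule.

#' Per-animal histology record
#'
#' @param animal_id,group Identifiers.
#' @param steatosis_pct Percent of hepatocytes with fat, in `[0, 100]`.
#' @param foci_per_field Inflammatory foci per 200x field, `>= 0`.
#' @param ballooning_category `"none"`, `"few"` or `"many"`.
#' @return A list of class `HistologyRecord`.
#' @export
histology_record <- function(animal_id = "animal", group = "group",
                             steatosis_pct, foci_per_field,
                             ballooning_category = c("none", "few", "many")) {
  ballooning_category <- match.arg(ballooning_category)
  if (is.na(steatosis_pct) || steatosis_pct < 0 || steatosis_pct > 100) {
    stop_validation("steatosis_pct must lie in [0, 100]")
  }
  if (is.na(foci_per_field) || foci_per_field < 0) {
    stop_validation("foci_per_field must be non-negative")
  }
  structure(list(animal_id = animal_id, group = group,
                 steatosis_pct = steatosis_pct,
                 foci_per_field = foci_per_field,
                 ballooning_category = ballooning_category),
            class = "HistologyRecord")
}

#' NAFLD activity score (NAS) from a histology record
#'
#' Kleiner-rubric components: steatosis scores 0/1/2/3 for <5%,
#' 5-33%, 33-66% and >66% of hepatocytes with fat; lobular inflammation
#' scores 0/1/2/3 for none, fewer than 2, 2-4 and more than 4 foci per
#' 200x field; ballooning scores 0/1/2 for none/few/many. The total NAS
#' is the component sum (0-8). Band edges: 5 and 33 open the next
#' steatosis band ([5,33) scores 1, [33,66] scores 2) while 66 itself
#' stays in band 2 because band 3 is literally "greater than 66%";
#' likewise inflammation counts of exactly 2 or 4 score 2, and any
#' positive count below 2 scores 1.
#'
#' @param record A [histology_record()], or `NULL` when the component
#'   arguments are given directly.
#' @param steatosis_pct,foci_per_field,ballooning_category Used when
#'   `record` is `NULL`.
#' @return A list of class `NASResult`: `steatosis_score`,
#'   `inflammation_score`, `ballooning_score`, `total`.
#' @export
nas_score <- function(record = NULL, steatosis_pct = NULL, foci_per_field = NULL,
                      ballooning_category = NULL) {
  if (is.null(record)) {
    record <- histology_record(steatosis_pct = steatosis_pct,
                               foci_per_field = foci_per_field,
                               ballooning_category = ballooning_category)
  }
  stopifnot(inherits(record, "HistologyRecord"))
  s <- record$steatosis_pct
  steatosis <- if (s < 5) 0L else if (s < 33) 1L else if (s <= 66) 2L else 3L
  f <- record$foci_per_field
  inflammation <- if (f == 0) 0L else if (f < 2) 1L else if (f <= 4) 2L else 3L
  ballooning <- c(none = 0L, few = 1L, many = 2L)[[record$ballooning_category]]
  structure(list(steatosis_score = steatosis,
                 inflammation_score = inflammation,
                 ballooning_score = ballooning,
                 total = steatosis + inflammation + ballooning),
            class = "NASResult")
}

#' @export
print.NASResult <- function(x, ...) {
  cat(sprintf("NAS %d (steatosis %d + inflammation %d + ballooning %d)\n",
              x$total, x$steatosis_score, x$inflammation_score, x$ballooning_score))
  invisible(x)
}

#' NAS for every row of a histology table
#'
#' @param histology data.frame with columns `steatosis_pct`,
#'   `foci_per_field`, `ballooning_category` (and optionally
#'   `animal_id`, `group`).
#' @return The input with appended score columns and `nas_total`.
#' @export
nas_score_table <- function(histology) {
  scores <- lapply(seq_len(nrow(histology)), function(i) {
    nas_score(steatosis_pct = histology$steatosis_pct[i],
              foci_per_field = histology$foci_per_field[i],
              ballooning_category = histology$ballooning_category[i])
  })
  histology$steatosis_score <- vapply(scores, `[[`, integer(1), "steatosis_score")
  histology$inflammation_score <- vapply(scores, `[[`, integer(1), "inflammation_score")
  histology$ballooning_score <- vapply(scores, `[[`, integer(1), "ballooning_score")
  histology$nas_total <- vapply(scores, `[[`, integer(1), "total")
  histology
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' The statistic is the rank sum of group A over the pooled midranks.
#' In exact mode (default for `nA + nB <= 12`) the full distribution of
#' the statistic is enumerated over all assignments of the pooled
#' observed values to the two groups, so ties are handled exactly; the
#' two-sided p-value is the probability of a statistic at least as far
#' from its enumeration mean as observed. Otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' If every pooled value is identical the p-value is 1.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (rank sum of A) and `p_two_sided`.
#' @export
wilcoxon_ranksum <- function(groupA, groupB, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(groupA) || !length(groupB)) {
    stop_validation("both groups must be non-empty")
  }
  nA <- length(groupA); nB <- length(groupB); n <- nA + nB
  pooled <- c(groupA, groupB)
  r <- rank(pooled)  # midranks
  w_obs <- sum(r[seq_len(nA)])
  if (mode == "auto") mode <- if (n <= 12) "exact" else "normal"
  if (mode == "exact") {
    assignments <- utils::combn(n, nA)
    ws <- colSums(matrix(r[assignments], nrow = nA))
    mu <- mean(ws)
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    mu <- nA * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(statistic = w_obs, p_two_sided = p)
}

#' One-way ANOVA followed by Fisher's LSD pairwise tests
#'
#' Fits a one-way ANOVA across the groups (via [stats::aov()]) and
#' computes unadjusted pairwise Fisher least-significant-difference
#' t-tests, `t = (m_i - m_j) / sqrt(MSE * (1/n_i + 1/n_j))` with
#' `df = N - k`. When all values in all groups are identical the F
#' statistic is 0 and every p-value 1.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List with `F`, `p_anova`, and `pairwise` (data.frame with
#'   `group1`, `group2`, `t`, `p`).
#' @export
anova_lsd <- function(groups) {
  if (length(groups) < 2) stop_validation("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_validation("groups must be named")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop_validation(sprintf("group '%s' has fewer than 2 values",
                            names(groups)[sizes < 2][1]))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  df_resid <- tab["Residuals", "Df"]
  if (stats::var(df$value) == 0) {
    # every value identical: no variation to partition
    f_stat <- 0; p_anova <- 1; mse <- 0
  } else {
    f_stat <- tab["group", "F value"]
    p_anova <- tab["group", "Pr(>F)"]
  }
  means <- vapply(groups, mean, numeric(1))
  combos <- utils::combn(names(groups), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    se <- sqrt(mse * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    t_stat <- if (se == 0) {
      if (means[[g1]] == means[[g2]]) 0 else Inf * sign(means[[g1]] - means[[g2]])
    } else (means[[g1]] - means[[g2]]) / se
    p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), df_resid) else
      if (t_stat == 0) 1 else 0
    data.frame(group1 = g1, group2 = g2, t = t_stat, p = p,
               stringsAsFactors = FALSE)
  }))
  pairwise$p[pairwise$t == 0] <- 1
  rownames(pairwise) <- NULL
  list(F = f_stat, p_anova = p_anova, pairwise = pairwise)
}

#' Comparative Ct (delta-delta-Ct) relative quantification
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; the group contrast is
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change
#' `2^(-ddCt)`. The reference gene is a required argument: assay designs
#' differ in their internal reference, so none is assumed.
#'
#' @param ct_table data.frame with columns `sample_id`, `group`, `gene`,
#'   `ct`.
#' @param target Target gene name.
#' @param reference_gene Internal reference gene name (e.g. `"Rplp0"`).
#' @param control_group,treated_group Group labels contrasted.
#' @return List with `delta_ct` (data.frame sample_id/group/delta_ct),
#'   `ddct`, `fold_change`.
#' @export
ddct <- function(ct_table, target, reference_gene, control_group, treated_group) {
  need <- c("sample_id", "group", "gene", "ct")
  missing_cols <- setdiff(need, names(ct_table))
  if (length(missing_cols)) {
    stop_format(sprintf("Ct table missing column '%s'", missing_cols[[1]]))
  }
  tt <- ct_table[ct_table$gene == target & ct_table$group %in%
                   c(control_group, treated_group), , drop = FALSE]
  if (!nrow(tt)) stop_validation(sprintf("no Ct rows for target '%s'", target))
  rr <- ct_table[ct_table$gene == reference_gene, , drop = FALSE]
  ref_ct <- rr$ct[match(tt$sample_id, rr$sample_id)]
  if (anyNA(ref_ct)) {
    bad <- tt$sample_id[is.na(ref_ct)][1]
    stop_validation(sprintf("missing reference gene '%s' Ct for sample '%s'",
                            reference_gene, bad))
  }
  delta <- data.frame(sample_id = tt$sample_id, group = tt$group,
                      delta_ct = tt$ct - ref_ct, stringsAsFactors = FALSE)
  for (g in c(control_group, treated_group)) {
    if (!any(delta$group == g)) stop_validation(sprintf("no samples in group '%s'", g))
  }
  dd <- mean(delta$delta_ct[delta$group == treated_group]) -
    mean(delta$delta_ct[delta$group == control_group])
  list(delta_ct = delta, ddct = dd, fold_change = 2^(-dd))
}

#' Single-pass mean +/- 2 SD outlier mask
#'
#' A value is excluded iff it lies outside `mean +/- 2 * SD`, with both
#' statistics computed once on all values (sample SD, n-1 denominator);
#' the rule is not re-applied to the retained values. With zero SD all
#' values are retained.
#'
#' @param values Numeric vector of length >= 3.
#' @return Logical mask, `TRUE` for retained values.
#' @export
outlier_mask <- function(values) {
  if (length(values) < 3) stop_validation("need at least 3 values")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  values >= m - 2 * s & values <= m + 2 * s
}
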