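# Small in-code fixtures shared across test files.

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, "counts")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_de <- function(gene_id, log2fc, p = NULL, p_adj = NULL) {
  p <- p %||% rep(0.01, length(gene_id))
  de_result_table(data.frame(gene_id = gene_id, log2fc = log2fc, p = p,
                             p_adj = p_adj %||% bh_adjust(p),
                             stringsAsFactors = FALSE))
}

# A seeded random z-score profile over the landmark space plus a random
# disjoint-arm signature of the given sizes.
make_profile_sig <- function(seed, n_features = 200, n_up = 20, n_down = 20) {
  set.seed(seed)
  z <- stats::setNames(stats::rnorm(n_features), landmark_ids(n_features))
  pick <- sample(names(z), n_up + n_down)
  list(z = z,
       sig = directional_signature(pick[seq_len(n_up)],
                                   pick[n_up + seq_len(n_down)],
                                   n_per_arm = max(n_up, n_down)))
}

# Run the full simulate -> DE -> cross-species path once; returns the
# pieces the overlap tests need.
run_xspecies_pair <- function(cfg) {
  m <- simulate_three_group_counts(cfg)
  map <- simulate_ortholog_map(cfg, m$counts$gene_ids)
  h <- simulate_human_cohort(cfg, m$truth, map)
  de_dis <- de_test(m$counts, m$design, "healthy", "disease")
  de_trt <- de_test(m$counts, m$design, "disease", "treated")
  de_hum <- de_test(h$counts, h$design, "control", "nash")
  universe <- intersect(apply_ortholog_map(de_dis$gene_id, map)$mapped,
                        de_hum$gene_id)
  sig <- extract_signature(de_hum[de_hum$gene_id %in% universe, ], 250)
  list(mouse = m, human = h, map = map, de_dis = de_dis, de_trt = de_trt,
       de_hum = de_hum, universe = universe, sig = sig)
}
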