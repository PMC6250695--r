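#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generator. Defaults
#' emulate the study design the pipeline targets: a three-group
#' (healthy / disease / treated) mouse cohort with 4 animals per group
#' profiled by RNA-seq, a two-group human cohort sharing a controllable
#' fraction of concordant disease effects through an ortholog map, and a
#' compound z-score collection over 978 landmark features containing one
#' implanted inverse-connectivity compound.
#'
#' @param seed Integer global seed. Each generator draws from its own
#'   named substream derived from this seed, so outputs are
#'   bit-reproducible and adding a generator never perturbs another.
#' @param n_genes Number of genes in the count matrices.
#' @param n_landmarks Number of landmark features in compound profiles
#'   (default 978, the L1000 landmark space size).
#' @param samples_per_group Samples per group in the mouse cohort
#'   (default 4, matching a typical small in-vivo RNA-seq arm).
#' @param human_samples_per_group Samples per group in the human cohort.
#' @param nb_dispersion Negative-binomial dispersion (1/size); a single
#'   value shared by all genes.
#' @param baseline_log_mean,baseline_log_sd Parameters (natural-log
#'   scale) of the log-normal distribution of gene baseline means.
#' @param libsize_range Length-2 numeric: per-sample library-size factors
#'   are drawn uniformly from this range.
#' @param de_fraction Fraction pi of genes given a disease effect.
#' @param effect_size,effect_sd Mean and spread (log2 units) of the
#'   disease effect magnitude; sign is +/- with equal probability.
#' @param reversal_fraction Fraction r of disease genes whose treated
#'   mean is moved back toward healthy.
#' @param reversal_strength rho in (0, 1]: fraction of the way back to
#'   the healthy mean that a reversed gene travels.
#' @param concordance Fraction c of mapped mouse disease genes that
#'   receive a same-direction effect in the human cohort.
#' @param map_coverage Fraction of mouse genes covered by the simulated
#'   ortholog map.
#' @param one2many_fraction Fraction of mapped mouse genes given two
#'   human targets (to exercise resolution policies).
#' @param n_compounds Number of compound profiles in the collection.
#' @param inverse_strength z-units subtracted from the implanted inverse
#'   compound's up-tag features (and added to its down-tag features).
#' @param endpoint_n Named integer vector: animals per endpoint group.
#' @param n_ct_outliers Number of outlier Ct values injected (at
#'   mean + 5 SD of the affected gene/group cell).
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_landmarks = 978L,
                       samples_per_group = 4L,
                       human_samples_per_group = samples_per_group,
                       nb_dispersion = 0.1,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1,
                       libsize_range = c(0.7, 1.3),
                       de_fraction = 0.1,
                       effect_size = 2,
                       effect_sd = 0.25,
                       reversal_fraction = 0.7,
                       reversal_strength = 1,
                       concordance = 0.8,
                       map_coverage = 0.9,
                       one2many_fraction = 0.1,
                       n_compounds = 20L,
                       inverse_strength = 2,
                       endpoint_n = c(healthy = 7L, vehicle = 16L, treated = 7L),
                       n_ct_outliers = 1L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_landmarks = as.integer(n_landmarks),
              samples_per_group = as.integer(samples_per_group),
              human_samples_per_group = as.integer(human_samples_per_group),
              nb_dispersion = nb_dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              libsize_range = libsize_range,
              de_fraction = de_fraction, effect_size = effect_size,
              effect_sd = effect_sd,
              reversal_fraction = reversal_fraction,
              reversal_strength = reversal_strength,
              concordance = concordance, map_coverage = map_coverage,
              one2many_fraction = one2many_fraction,
              n_compounds = as.integer(n_compounds),
              inverse_strength = inverse_strength,
              endpoint_n = endpoint_n, n_ct_outliers = as.integer(n_ct_outliers))
  for (f in c("de_fraction", "reversal_fraction", "concordance",
              "map_coverage", "one2many_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_config(sprintf("'%s' must lie in [0, 1]", f))
    }
  }
  if (cfg$reversal_strength <= 0 || cfg$reversal_strength > 1) {
    stop_config("'reversal_strength' must lie in (0, 1]")
  }
  if (cfg$n_landmarks <= 0) stop_config("'n_landmarks' must be positive")
  if (cfg$samples_per_group < 2 || cfg$human_samples_per_group < 2) {
    stop_config("at least 2 samples per group are required")
  }
  if (cfg$nb_dispersion <= 0) stop_config("'nb_dispersion' must be positive")
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0)) {
    stop_config("'libsize_range' must be two positive numbers")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

nb_draw <- function(mu_matrix, dispersion) {
  counts <- matrix(stats::rnbinom(length(mu_matrix), mu = mu_matrix,
                                  size = 1 / dispersion),
                   nrow = nrow(mu_matrix), dimnames = dimnames(mu_matrix))
  counts
}

#' Simulate a three-group mouse cohort with implanted reversal
#'
#' Healthy samples sit at gene baselines; disease samples shift a
#' fraction `de_fraction` of genes by signed log2 effects; treated
#' samples return each reversed gene a fraction `reversal_strength` of
#' the way to the healthy mean and leave non-reversed disease genes at
#' the disease level. Counts are negative binomial with per-sample
#' library-size factors. Reversal is implanted on the mean scale so the
#' ground-truth direction of every gene is exact.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` ([expression_matrix()]),
#'   `design` ([sample_design()] with groups healthy/disease/treated) and
#'   `truth` (a list carrying the per-gene data.frame `gene` with columns
#'   `gene_id`, `is_de`, `direction`, `is_reversed`).
#' @export
simulate_three_group_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_substream(config$seed, "mouse_counts", {
    n <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(n))
    mu0 <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)

    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    direction <- integer(n)
    direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    magnitude <- numeric(n)
    magnitude[de_idx] <- abs(stats::rnorm(n_de, config$effect_size, config$effect_sd))

    n_rev <- round(config$reversal_fraction * n_de)
    rev_idx <- if (n_rev > 0) sample(de_idx, n_rev) else integer(0)
    is_rev <- logical(n); is_rev[rev_idx] <- TRUE

    mu_healthy <- mu0
    mu_disease <- mu0 * 2^(direction * magnitude)
    mu_treated <- mu_disease
    mu_treated[rev_idx] <- mu0[rev_idx] *
      2^(direction[rev_idx] * magnitude[rev_idx] * (1 - config$reversal_strength))

    k <- config$samples_per_group
    groups <- c("healthy", "disease", "treated")
    sample_ids <- as.vector(vapply(groups, function(g) sprintf("%s_%d", g, seq_len(k)),
                                   character(k)))
    libsize <- stats::runif(3 * k, config$libsize_range[1], config$libsize_range[2])
    mu_mat <- cbind(matrix(mu_healthy, n, k), matrix(mu_disease, n, k),
                    matrix(mu_treated, n, k))
    mu_mat <- sweep(mu_mat, 2, libsize, `*`)
    dimnames(mu_mat) <- list(gene_ids, sample_ids)
    counts <- nb_draw(mu_mat, config$nb_dispersion)

    truth <- list(
      gene = data.frame(gene_id = gene_ids,
                        is_de = seq_len(n) %in% de_idx,
                        direction = direction,
                        is_reversed = is_rev,
                        effect_log2 = direction * magnitude,
                        stringsAsFactors = FALSE),
      library_size = stats::setNames(libsize, sample_ids))
    list(counts = expression_matrix(counts, "counts"),
         design = sample_design(sample_ids, rep(groups, each = k), groups),
         truth = truth)
  })
}

#' Simulate a mouse-to-human ortholog map
#'
#' Covers `map_coverage` of the given mouse genes; a fraction
#' `one2many_fraction` of covered genes receive two human targets so
#' that resolution policies can be exercised.
#'
#' @param config A [sim_config()].
#' @param mouse_genes Character vector of mouse gene ids.
#' @return An [ortholog_map()] with policy `one2one_only`.
#' @export
simulate_ortholog_map <- function(config, mouse_genes) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_substream(config$seed, "ortholog_map", {
    n_cov <- round(config$map_coverage * length(mouse_genes))
    covered <- sort(sample(mouse_genes, n_cov))
    targets <- toupper(sub("^g", "H", covered))
    n_multi <- round(config$one2many_fraction * n_cov)
    multi <- if (n_multi > 0) sample(seq_len(n_cov), n_multi) else integer(0)
    extra <- if (length(multi)) paste0(targets[multi], "B") else character(0)
    src <- c(covered, covered[multi])
    tgt <- c(targets, extra)
    ortholog_map(src, tgt, policy = "one2one_only", resolve = FALSE)
  })
}

#' Simulate a two-group human cohort concordant with mouse truth
#'
#' Human genes are the targets of the ortholog map plus a tail of
#' human-only genes. A fraction `concordance` of mapped mouse disease
#' genes receive a same-direction log2 effect in the disease (NASH)
#' group; all other genes have no effect.
#'
#' @param config A [sim_config()].
#' @param mouse_truth The `truth` element of
#'   [simulate_three_group_counts()].
#' @param map An [ortholog_map()] from mouse to human ids.
#' @return A list with `counts`, `design` (groups control/nash) and
#'   `truth` (`gene` data.frame plus `pair` data.frame flagging
#'   concordant ortholog pairs).
#' @export
simulate_human_cohort <- function(config, mouse_truth, map) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(map, "OrthologMap"))
  pairs <- resolved_pairs(map)
  if (!nrow(pairs)) stop_validation("ortholog map is empty after resolution")
  with_substream(config$seed, "human_counts", {
    human_ids <- sort(unique(pairs$target_id))
    n_extra <- round(0.1 * length(human_ids))
    extra <- if (n_extra > 0) sprintf("HONLY%04d", seq_len(n_extra)) else character(0)
    gene_ids <- c(human_ids, extra)
    n <- length(gene_ids)

    mouse_de <- mouse_truth$gene[mouse_truth$gene$is_de, , drop = FALSE]
    mapped_de <- pairs[pairs$source_id %in% mouse_de$gene_id, , drop = FALSE]
    n_conc <- round(config$concordance * nrow(mapped_de))
    conc_rows <- if (n_conc > 0) sample(seq_len(nrow(mapped_de)), n_conc) else integer(0)
    conc <- mapped_de[conc_rows, , drop = FALSE]

    direction <- stats::setNames(integer(n), gene_ids)
    magnitude <- stats::setNames(numeric(n), gene_ids)
    if (nrow(conc)) {
      src_dir <- mouse_de$direction[match(conc$source_id, mouse_de$gene_id)]
      direction[conc$target_id] <- src_dir
      magnitude[conc$target_id] <- abs(stats::rnorm(nrow(conc), config$effect_size,
                                                    config$effect_sd))
    }

    mu0 <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    mu_control <- mu0
    mu_nash <- mu0 * 2^(direction * magnitude)

    k <- config$human_samples_per_group
    sample_ids <- c(sprintf("control_%d", seq_len(k)), sprintf("nash_%d", seq_len(k)))
    libsize <- stats::runif(2 * k, config$libsize_range[1], config$libsize_range[2])
    mu_mat <- cbind(matrix(mu_control, n, k), matrix(mu_nash, n, k))
    mu_mat <- sweep(mu_mat, 2, libsize, `*`)
    dimnames(mu_mat) <- list(gene_ids, sample_ids)
    counts <- nb_draw(mu_mat, config$nb_dispersion)

    truth <- list(
      gene = data.frame(gene_id = gene_ids,
                        is_de = direction != 0,
                        direction = as.integer(direction),
                        stringsAsFactors = FALSE),
      pair = data.frame(source_id = pairs$source_id, target_id = pairs$target_id,
                        is_concordant = paste(pairs$source_id, pairs$target_id) %in%
                          paste(conc$source_id, conc$target_id),
                        stringsAsFactors = FALSE))
    list(counts = expression_matrix(counts, "counts"),
         design = sample_design(sample_ids, rep(c("control", "nash"), each = k),
                                c("control", "nash")),
         truth = truth)
  })
}

#' Simulate a compound z-score collection with one implanted inverse hit
#'
#' Profiles are standard-normal z-scores over the landmark feature
#' space. One compound (recorded in the ground truth) has
#' `inverse_strength` subtracted from the disease signature's up-tag
#' features and added to its down-tag features, making it an inverse
#' connectivity hit; at `inverse_strength = 0` it is exchangeable with
#' the null compounds.
#'
#' @param config A [sim_config()].
#' @param disease_signature A [directional_signature()] whose features
#'   lie inside the landmark space `L0001 ... L<n_landmarks>`.
#' @return A list with `profiles` (an [expression_matrix()] of kind
#'   `zscore`, landmarks x compounds) and `truth` (data.frame with
#'   `compound_id`, `is_inverse_hit`).
#' @export
simulate_compound_collection <- function(config, disease_signature) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(disease_signature, "DirectionalSignature"))
  features <- landmark_ids(config$n_landmarks)
  sig_feats <- c(disease_signature$up, disease_signature$down)
  if (length(sig_feats) > config$n_landmarks) {
    stop_validation("signature is larger than the landmark feature space")
  }
  missing <- setdiff(sig_feats, features)
  if (length(missing)) {
    stop_validation(sprintf("signature feature(s) outside landmark space: %s",
                            paste(utils::head(missing, 5), collapse = ", ")))
  }
  with_substream(config$seed, "compounds", {
    n_cpd <- config$n_compounds
    compound_ids <- sprintf("cpd%03d", seq_len(n_cpd))
    z <- matrix(stats::rnorm(config$n_landmarks * n_cpd),
                nrow = config$n_landmarks,
                dimnames = list(features, compound_ids))
    hit <- if (n_cpd > 0) sample.int(n_cpd, 1) else integer(0)
    if (length(hit)) {
      z[disease_signature$up, hit] <- z[disease_signature$up, hit] - config$inverse_strength
      z[disease_signature$down, hit] <- z[disease_signature$down, hit] + config$inverse_strength
    }
    list(profiles = expression_matrix(z, "zscore"),
         truth = data.frame(compound_id = compound_ids,
                            is_inverse_hit = seq_len(n_cpd) %in% hit,
                            stringsAsFactors = FALSE))
  })
}

#' Landmark feature identifiers
#'
#' @param n Number of landmark features.
#' @return Character vector `L0001 ... L<n>`.
#' @export
landmark_ids <- function(n) sprintf("L%04d", seq_len(n))

# Group-level endpoint distribution parameters. Chosen so that expected
# NAS totals track a healthy ~0.7 / vehicle ~4.4 / treated ~2.6 design,
# with treatment improving inflammation and ballooning more than
# steatosis.
endpoint_params <- function() {
  list(
    healthy = list(steatosis_mean = 2,  steatosis_sd = 1.5, foci_lambda = 0.2,
                   ballooning_prob = c(none = 0.95, few = 0.05, many = 0)),
    vehicle = list(steatosis_mean = 20, steatosis_sd = 6,  foci_lambda = 3,
                   ballooning_prob = c(none = 0.1, few = 0.5, many = 0.4)),
    treated = list(steatosis_mean = 18, steatosis_sd = 6,  foci_lambda = 1,
                   ballooning_prob = c(none = 0.5, few = 0.45, many = 0.05)))
}

#' Simulate per-animal histology and qPCR Ct tables
#'
#' Histology: per-animal steatosis percentage (truncated normal), focal
#' inflammation count (Poisson, per 200x field) and ballooning category,
#' drawn from group-specific distributions. Ct table: marker genes plus
#' the reference gene `Rplp0`, with `n_ct_outliers` values displaced to
#' mean + 5 SD of their gene/group cell (recorded in the ground truth).
#'
#' @param config A [sim_config()].
#' @return A list with `histology` (data.frame of [histology_record()]
#'   fields), `ct` (data.frame sample_id/group/gene/ct) and `truth`
#'   (ids of injected Ct outliers).
#' @export
simulate_endpoint_tables <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_substream(config$seed, "endpoints", {
    params <- endpoint_params()
    groups <- names(config$endpoint_n)
    hist_rows <- list()
    for (g in groups) {
      p <- params[[g]] %||% params$vehicle
      n <- config$endpoint_n[[g]]
      steat <- pmin(100, pmax(0, stats::rnorm(n, p$steatosis_mean, p$steatosis_sd)))
      foci <- stats::rpois(n, p$foci_lambda)
      ball <- sample(names(p$ballooning_prob), n, replace = TRUE,
                     prob = p$ballooning_prob)
      hist_rows[[g]] <- data.frame(
        animal_id = sprintf("%s_%02d", g, seq_len(n)), group = g,
        steatosis_pct = steat, foci_per_field = foci,
        ballooning_category = ball, stringsAsFactors = FALSE)
    }
    histology <- do.call(rbind, hist_rows)
    rownames(histology) <- NULL

    markers <- c("Tnf", "Ccl2", "Ifng", "Timp1", "Col1a1", "Tgfb1")
    # disease raises marker expression => lower Ct; treatment partially restores
    group_shift <- c(healthy = 0, vehicle = -2, treated = -0.8)
    ct_rows <- list()
    for (g in groups) {
      n <- config$endpoint_n[[g]]
      ids <- sprintf("%s_%02d", g, seq_len(n))
      shift <- group_shift[[g]] %||% 0
      ref_ct <- stats::rnorm(n, 18, 0.3)
      ct_rows[[paste0(g, "_ref")]] <- data.frame(
        sample_id = ids, group = g, gene = "Rplp0", ct = ref_ct,
        stringsAsFactors = FALSE)
      for (m in markers) {
        base_dct <- 6 + 0.5 * match(m, markers)
        ct_rows[[paste0(g, "_", m)]] <- data.frame(
          sample_id = ids, group = g, gene = m,
          ct = ref_ct + base_dct + shift + stats::rnorm(n, 0, 0.4),
          stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, ct_rows)
    rownames(ct) <- NULL

    outlier_ids <- character(0)
    if (config$n_ct_outliers > 0) {
      target_rows <- which(ct$gene != "Rplp0")
      picked <- sample(target_rows, min(config$n_ct_outliers, length(target_rows)))
      for (i in picked) {
        cell <- ct$gene == ct$gene[i] & ct$group == ct$group[i]
        m <- mean(ct$ct[cell]); s <- stats::sd(ct$ct[cell])
        ct$ct[i] <- m + 5 * s
        outlier_ids <- c(outlier_ids, paste(ct$sample_id[i], ct$gene[i], sep = ":"))
      }
    }
    list(histology = histology, ct = ct,
         truth = list(ct_outliers = outlier_ids))
  })
}
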