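# End-to-end wiring of the two workflows: prediction (signature ->
# connectivity screen) and validation (DE -> cross-species -> reversal
# -> endpoints), on a simulated or user-supplied workspace.

#' Pipeline configuration
#'
#' Collects the analysis parameters of both workflows with their
#' standard defaults: 250 genes per arm for cross-species signatures,
#' 500 per arm for compound-screen disease signatures, log2 fold-change
#' threshold `tau = 0.5`, FDR level `alpha = 0.05`.
#'
#' @param path Optional YAML file whose fields override the defaults.
#' @param ... Field overrides (applied after the file).
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    n_per_arm_xspecies = 250L,
    n_per_arm_cmap = 500L,
    tau = 0.5,
    alpha = 0.05,
    n_perms = 499L,
    scorer = "ks",
    reversal_rule = "sign",
    ortholog_policy = "one2one_only",
    sim = list())
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("config file not found: '%s'", path))
    over <- yaml::read_yaml(path)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop_config(sprintf("unknown config field: '%s'", unknown[[1]]))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_config(sprintf("unknown config field: '%s'", unknown[[1]]))
  cfg[names(dots)] <- dots
  if (cfg$tau <= 0) stop_config("'tau' must be positive")
  if (cfg$alpha < 0 || cfg$alpha > 1) stop_config("'alpha' must lie in [0, 1]")
  if (!cfg$scorer %in% c("ks", "spearman")) stop_config("'scorer' must be ks or spearman")
  if (!cfg$reversal_rule %in% c("sign", "strict")) {
    stop_config("'reversal_rule' must be sign or strict")
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

pipeline_path <- function(dir, name) file.path(dir, name)

#' Run a pipeline stage (or all of them) against a workspace directory
#'
#' Stages communicate only through files in `dir`, so `"all"` equals the
#' composition of the individual stages in order: `simulate` writes
#' every input with ground truth; `de` fits the three contrasts;
#' `signature` extracts the cross-species and compound-screen
#' signatures; `connect` screens the compound collection; `xspecies`
#' runs the concordance and reversal overlap tests; `reversal` computes
#' per-pathway percent reversal; `endpoints` scores histology and qPCR
#' tables. A JSON manifest recording the package version, configuration
#' and md5 checksums of all artifacts is written after every run.
#'
#' @param config A [pipeline_config()].
#' @param subcommand One of `simulate`, `de`, `signature`, `connect`,
#'   `xspecies`, `reversal`, `endpoints`, `all`.
#' @param dir Workspace directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
pipeline_run <- function(config, subcommand, dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- c("simulate", "de", "signature", "connect", "xspecies",
              "reversal", "endpoints")
  if (!subcommand %in% c(stages, "all")) {
    stop_config(sprintf("unknown subcommand '%s'", subcommand))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  run_one <- function(stage) {
    fun <- switch(stage,
                  simulate = stage_simulate, de = stage_de,
                  signature = stage_signature, connect = stage_connect,
                  xspecies = stage_xspecies, reversal = stage_reversal,
                  endpoints = stage_endpoints)
    fun(config, dir)
  }
  if (subcommand == "all") lapply(stages, run_one) else run_one(subcommand)
  manifest <- write_manifest(config, dir)
  invisible(manifest)
}

write_manifest <- function(config, dir) {
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  sums <- tools::md5sum(file.path(dir, files))
  cfg_plain <- unclass(config)
  manifest <- list(
    package = "revsig",
    version = as.character(utils::packageVersion("revsig")),
    config = cfg_plain,
    config_hash = unname(tools::md5sum(local({
      f <- tempfile(); writeLines(deparse(cfg_plain), f); f
    }))),
    artifacts = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, pipeline_path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

sim_from_config <- function(config) {
  do.call(sim_config, c(list(seed = config$seed), config$sim))
}

stage_simulate <- function(config, dir) {
  scfg <- sim_from_config(config)
  mouse <- simulate_three_group_counts(scfg)
  map <- simulate_ortholog_map(scfg, mouse$counts$gene_ids)
  human <- simulate_human_cohort(scfg, mouse$truth, map)
  write_expression_matrix(mouse$counts, pipeline_path(dir, "mouse_counts.tsv"))
  utils::write.table(mouse$design, pipeline_path(dir, "mouse_design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(human$counts, pipeline_path(dir, "human_counts.tsv"))
  utils::write.table(human$design, pipeline_path(dir, "human_design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ortholog_map(map, pipeline_path(dir, "ortholog_map.tsv"))
  ep <- simulate_endpoint_tables(scfg)
  utils::write.table(ep$histology, pipeline_path(dir, "histology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ep$ct, pipeline_path(dir, "ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # a generator-truth pathway collection: all disease genes plus controls
  truth_gene <- mouse$truth$gene
  gsc <- gene_set_collection(list(
    disease_program = truth_gene$gene_id[truth_gene$is_de],
    all_genes = truth_gene$gene_id))
  write_gmt(gsc, pipeline_path(dir, "pathways.gmt"))
  jsonlite::write_json(
    list(mouse = mouse$truth$gene, human = human$truth$gene,
         pairs = human$truth$pair, ct_outliers = ep$truth$ct_outliers),
    pipeline_path(dir, "ground_truth.json"))
  invisible(NULL)
}

read_workspace_counts <- function(dir, prefix) {
  list(counts = read_expression_matrix(pipeline_path(dir, paste0(prefix, "_counts.tsv")),
                                       "counts"),
       design = read_sample_design(pipeline_path(dir, paste0(prefix, "_design.tsv"))))
}

stage_de <- function(config, dir) {
  mouse <- read_workspace_counts(dir, "mouse")
  human <- read_workspace_counts(dir, "human")
  write_de_table(de_test(mouse$counts, mouse$design, "healthy", "disease"),
                 pipeline_path(dir, "de_disease_vs_healthy.tsv"))
  write_de_table(de_test(mouse$counts, mouse$design, "disease", "treated"),
                 pipeline_path(dir, "de_treated_vs_disease.tsv"))
  write_de_table(de_test(human$counts, human$design, "control", "nash"),
                 pipeline_path(dir, "de_human_nash_vs_control.tsv"))
  invisible(NULL)
}

stage_signature <- function(config, dir) {
  human_de <- read_de_table(pipeline_path(dir, "de_human_nash_vs_control.tsv"))
  sig <- extract_signature(human_de, config$n_per_arm_xspecies, source = "human_de")
  write_signature(sig, pipeline_path(dir, "human_signature"))
  invisible(NULL)
}

stage_connect <- function(config, dir) {
  scfg <- sim_from_config(config)
  # landmark-space disease signature with implanted inverse compound
  feats <- with_substream(scfg$seed, "landmark_sig",
                          sample(landmark_ids(scfg$n_landmarks), 100))
  sig <- directional_signature(feats[1:50], feats[51:100], n_per_arm = 50,
                               source = "landmark_disease")
  cpd <- simulate_compound_collection(scfg, sig)
  screen <- screen_collection(cpd$profiles, sig, alpha = config$alpha,
                              n_perms = config$n_perms, seed = config$seed)
  utils::write.table(screen, pipeline_path(dir, "connectivity_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_xspecies <- function(config, dir) {
  map <- read_ortholog_map(pipeline_path(dir, "ortholog_map.tsv"),
                           policy = config$ortholog_policy)
  human_de <- read_de_table(pipeline_path(dir, "de_human_nash_vs_control.tsv"))
  mouse_dis <- read_de_table(pipeline_path(dir, "de_disease_vs_healthy.tsv"))
  mouse_trt <- read_de_table(pipeline_path(dir, "de_treated_vs_disease.tsv"))
  universe <- intersect(apply_ortholog_map(mouse_dis$gene_id, map)$mapped,
                        human_de$gene_id)
  sig <- extract_signature(
    human_de[human_de$gene_id %in% universe, ],
    config$n_per_arm_xspecies, source = "human_de")
  conc <- concordance_test(sig, threshold_set(mouse_dis, config$tau),
                           universe, map)
  rev <- reversal_test(sig$up, threshold_set(mouse_trt, config$tau),
                       universe, map)
  jsonlite::write_json(
    list(concordance_up = unclass(conc$up), concordance_down = unclass(conc$down),
         reversal = unclass(rev)),
    pipeline_path(dir, "xspecies_results.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_reversal <- function(config, dir) {
  dis <- read_de_table(pipeline_path(dir, "de_disease_vs_healthy.tsv"))
  trt <- read_de_table(pipeline_path(dir, "de_treated_vs_disease.tsv"))
  status <- classify_reversal(dis, trt, alpha = config$alpha,
                              rule = config$reversal_rule)
  pw <- pathway_percent_reversed(status, read_gmt(pipeline_path(dir, "pathways.gmt")))
  utils::write.table(pw, pipeline_path(dir, "pathway_reversal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_endpoints <- function(config, dir) {
  histology <- utils::read.delim(pipeline_path(dir, "histology.tsv"),
                                 stringsAsFactors = FALSE)
  scored <- nas_score_table(histology)
  utils::write.table(scored, pipeline_path(dir, "nas_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- split(scored$nas_total, scored$group)
  tests <- list()
  for (g in setdiff(names(groups), "vehicle")) {
    if (!"vehicle" %in% names(groups)) break
    w <- wilcoxon_ranksum(groups[[g]], groups$vehicle)
    tests[[paste0("nas_", g, "_vs_vehicle")]] <- w$p_two_sided
  }
  ct <- utils::read.delim(pipeline_path(dir, "ct.tsv"), stringsAsFactors = FALSE)
  markers <- setdiff(unique(ct$gene), "Rplp0")
  fc <- lapply(markers, function(m) {
    ddct(ct, m, "Rplp0", "vehicle", "treated")$fold_change
  })
  jsonlite::write_json(
    list(wilcoxon_p = tests,
         fold_change_treated_vs_vehicle = stats::setNames(fc, markers)),
    pipeline_path(dir, "endpoint_results.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
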