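## End-to-end pipeline: simulate (or load) -> normalize -> exact-test DE ->
## group catalogue + PCA -> seed-based targets -> STEM clustering of target
## genes -> interaction network.  Every intermediate table is written as TSV
## and a JSON manifest records package version, seed, config hash and file
## checksums, so a rerun with identical config and seed is byte-identical.

#' Default pipeline configuration (synthetic scenario)
#'
#' The default scenario mirrors the two-breed eight-stage design: 200 miRNAs
#' in pooled one-per-breed-per-stage libraries of 1e6 mapped tags, 20 planted
#' 4-fold effects (10 higher in the reference breed at the postnatal stages,
#' 10 lower at the embryonic stages), 300 genes with model-profile FPKM time
#' courses over the embryonic stages, 100 planted miRNA-target pairs with
#' 7-mer seed-complement sites in 500-nt UTRs, and a 48-pair interaction
#' table.
#'
#' @param seed integer seed driving every random draw.
#' @param out_dir output directory for all pipeline artifacts.
#' @return a nested list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("mirnatime_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulation = list(
      n_mirnas = 200, n_genes = 300, library_size = 1e6,
      n_planted_de = 20, planted_log2fc = 2,
      noise_model = "poisson", profile_noise_sd = 0.25,
      n_target_genes = 100, utr_length = 500,
      n_interaction_pairs = 48),
    de = list(rule = "pairwise", fdr_mode = "monotone", pseudo = 0.5),
    stem = list(c = 2, m = 50, concentrated_frac = 0.6),
    network = list(score_min = 0.4),
    pca_pseudocount = 1)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_lists(base, config)
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

write_df_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full temporal miRNA-mRNA analysis pipeline
#'
#' Executes normalize -> exact-test DE -> group classification and PCA ->
#' seed-based target prediction -> STEM clustering of the predicted target
#' genes -> interaction-network assembly, on data simulated from the
#' configuration (or supplied via its `inputs` block), writing every
#' intermediate table plus a run manifest under `config$out_dir`.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sim <- config$simulation
  grouping <- stage_grouping()
  breeds <- c("LR", "LT")
  stages <- DEFAULT_STAGES

  ## ---- simulate ---------------------------------------------------------
  res <- stage_step("simulate", {
    n_de <- sim$n_planted_de
    half <- n_de %/% 2
    ids <- sprintf("mir-%03d", seq_len(sim$n_mirnas))
    planted <- c(
      lapply(ids[seq_len(half)], function(m)
        list(mirna = m, stages = grouping$G2, log2fc = -sim$planted_log2fc)),
      lapply(ids[seq.int(half + 1, n_de)], function(m)
        list(mirna = m, stages = grouping$G1, log2fc = sim$planted_log2fc)))
    cfg <- sim_config(n_mirnas = sim$n_mirnas, n_genes = sim$n_genes,
                      breeds = breeds, stages = stages,
                      library_size = sim$library_size, planted_de = planted,
                      noise_model = sim$noise_model,
                      profile_noise_sd = sim$profile_noise_sd, seed = seed)
    counts_sim <- gen_count_libraries(cfg)
    mirna_seqs <- gen_mirna_sequences(sim$n_mirnas, seed = seed + 3L)
    gene_ids <- sprintf("gene-%04d", seq_len(sim$n_genes))
    tgt_genes <- gene_ids[seq_len(sim$n_target_genes)]
    true_targets <- data.frame(
      mirna_id = ids[rep(seq_len(n_de), length.out = sim$n_target_genes)],
      gene_id = tgt_genes, stringsAsFactors = FALSE)
    utr_sim <- gen_utr_sequences(cfg, true_targets, mirna_seqs,
                                 utr_length = sim$utr_length)
    pairs <- data.frame(gene_a = tgt_genes[seq_len(sim$n_interaction_pairs)],
                        gene_b = tgt_genes[seq_len(sim$n_interaction_pairs) %%
                                             sim$n_target_genes + 1L],
                        stringsAsFactors = FALSE)
    interactions <- gen_interaction_table(pairs, seed = seed + 4L)
    universe <- generate_model_profiles(4, config$stem$c)
    selected <- select_representative_profiles(universe, config$stem$m)
    sel_vals <- profile_value_matrix(selected)
    up_cor <- stats::cor(t(sel_vals), c(0, 1, 2, 3))[, 1]
    templ_a <- which.max(up_cor)  # the most monotone-increasing representative
    n_conc <- round(config$stem$concentrated_frac * sim$n_target_genes)
    others <- setdiff(seq_along(selected), templ_a)
    template_index <- c(
      rep(templ_a, n_conc),
      rep(others, length.out = sim$n_target_genes - n_conc),
      rep(seq_along(selected), length.out = sim$n_genes - sim$n_target_genes))
    expr_sim <- gen_expression_profiles(cfg, selected,
                                        stage_labels = grouping$G1,
                                        template_index = template_index)
    list(cfg = cfg, counts = counts_sim$counts, de_truth = counts_sim$truth,
         mirna_seqs = mirna_seqs, utrs = utr_sim$utrs,
         target_truth = utr_sim$truth, interactions = interactions,
         profiles = selected, fpkm = expr_sim$fpkm,
         profile_truth = expr_sim$truth)
  })

  ## ---- normalize --------------------------------------------------------
  tpm <- stage_step("normalize", tpm_normalize(res$counts))

  ## ---- differential expression -----------------------------------------
  de <- stage_step("detest", {
    comparisons <- data.frame(
      library1 = paste("LR", stages, sep = "_"),
      library2 = paste("LT", stages, sep = "_"),
      stage = stages, stringsAsFactors = FALSE)
    de_test(res$counts, comparisons,
            criteria = significance_criteria(config$de$rule),
            fdr_mode = config$de$fdr_mode, pseudo = config$de$pseudo)
  })

  ## ---- classify + ordinate ---------------------------------------------
  catalog <- stage_step("classify", classify_groups(de, grouping))
  de_ids <- sort(unique(de$mirna_id[de$de]))
  ordination <- stage_step("ordinate", pca_ordination(
    tpm, mirna_set = de_ids, pseudocount = config$pca_pseudocount))

  ## ---- target prediction ------------------------------------------------
  targets <- stage_step("targets", {
    mirna_set <- if (length(de_ids)) de_ids else names(res$mirna_seqs)
    predict_targets(res$mirna_seqs[names(res$mirna_seqs) %in% mirna_set],
                    res$utrs)
  })

  ## ---- STEM clustering of predicted target genes -----------------------
  stem <- stage_step("stem", {
    genes <- intersect(unique(targets$gene_id), rownames(res$fpkm$fpkm))
    series <- res$fpkm$log2_values[genes, , drop = FALSE]
    assignments <- assign_profiles(series, res$profiles)
    enrichment <- profile_significance(series, res$profiles,
                                       assignments = assignments)
    list(series = series, assignments = assignments, enrichment = enrichment)
  })

  ## ---- network ----------------------------------------------------------
  network <- stage_step("network", {
    sig_profiles <- stem$enrichment$profile_id[stem$enrichment$significant]
    sig_genes <- stem$assignments$gene_id[
      !stem$assignments$excluded &
        stem$assignments$profile_id %in% sig_profiles]
    tgt <- targets[targets$gene_id %in% sig_genes, , drop = FALSE]
    build_network(tgt, res$interactions,
                  score_min = config$network$score_min)
  })

  ## ---- write artifacts --------------------------------------------------
  files <- character(0)
  wf <- function(fn, name) { fn; files <<- c(files, name); NULL }
  wf(write_matrix_tsv(res$counts, file.path(out, "counts.tsv"), "mirna_id"),
     "counts.tsv")
  wf(write_matrix_tsv(tpm, file.path(out, "tpm.tsv"), "mirna_id"), "tpm.tsv")
  wf(write_matrix_tsv(res$fpkm, file.path(out, "fpkm.tsv"), "gene_id"),
     "fpkm.tsv")
  wf(write_df_tsv(as.data.frame(de), file.path(out, "de_results.tsv")),
     "de_results.tsv")
  wf(write_df_tsv(catalog$stage_counts, file.path(out, "stage_counts.tsv")),
     "stage_counts.tsv")
  wf(write_json_file(catalog$sets, file.path(out, "catalog_sets.json")),
     "catalog_sets.json")
  venn <- as.list(venn_overlap(catalog, "G1_down", "G2_up"))
  wf(write_json_file(venn, file.path(out, "venn_G1down_G2up.json")),
     "venn_G1down_G2up.json")
  wf(write_df_tsv(data.frame(library = rownames(ordination$scores),
                             ordination$scores[, 1:2, drop = FALSE]),
                  file.path(out, "ordination_scores.tsv")),
     "ordination_scores.tsv")
  wf(write_df_tsv(targets, file.path(out, "targets.tsv")), "targets.tsv")
  prof_df <- data.frame(
    profile_id = vapply(res$profiles, function(p) p$id, integer(1)),
    values = vapply(res$profiles,
                    function(p) paste(p$values, collapse = ","), ""))
  wf(write_df_tsv(prof_df, file.path(out, "profiles.tsv")), "profiles.tsv")
  wf(write_df_tsv(as.data.frame(stem$assignments),
                  file.path(out, "assignments.tsv")), "assignments.tsv")
  wf(write_df_tsv(as.data.frame(stem$enrichment),
                  file.path(out, "profile_enrichment.tsv")),
     "profile_enrichment.tsv")
  wf(write_sif(network, file.path(out, "network.sif")), "network.sif")
  wf(write_graphml(network, file.path(out, "network.graphml")),
     "network.graphml")
  wf(write_df_tsv(node_stats(network), file.path(out, "node_degrees.tsv")),
     "node_degrees.tsv")

  cfg_path <- file.path(out, "config.json")
  write_json_file(config[setdiff(names(config), "out_dir")], cfg_path)
  files <- c(files, "config.json")
  manifest <- list(
    package = "mirnatime",
    version = as.character(utils::packageVersion("mirnatime")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    files = as.list(tools::md5sum(file.path(out, sort(files)))))
  names(manifest$files) <- sort(files)
  write_json_file(manifest, file.path(out, "manifest.json"))

  invisible(list(config = config, simulated = res, tpm = tpm, de = de,
                 catalog = catalog, ordination = ordination,
                 targets = targets, stem = stem, network = network,
                 manifest = manifest))
}
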