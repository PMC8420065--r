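# Full analysis chain over an emtrn_study (or a directory of files written
# by write_study), plus directory round-trip helpers.

#' Run the full EMTRN inference chain
#'
#' Executes every stage in order: probe missingness filter and kNN
#' imputation; enhancer region construction and region-level beta
#' summarisation; moderated differential testing and DMER calling;
#' promoter mapping, gene-level summarisation and DPMG calling; the
#' promoter-regulated exclusion list; distance- and correlation-screened
#' DMER-gene pairs; the shared-miRNA hypergeometric background network
#' intersected with DMER targets and screened by co-expression; the EMTRN
#' with hyper-/hypo-subnetworks; maximal-biclique modules of the
#' hypo-EMTRN and their train/test Cox/log-rank prognostic screen; module
#' diagnostic AUCs on the validation matrix; and the drug-lncRNA network.
#'
#' @param study an `emtrn_study` (from [simulate_study()] or
#'   [read_study()]).
#' @param config threshold list from [emtrn_config()].
#' @return named list with each stage's output (see the methods vignette
#'   for the walk-through): `filtered`, `imputed`, `regions`,
#'   `region_meth`, `region_diff`, `dmers`, `promoter_map`,
#'   `promoter_meth`, `promoter_diff`, `dpmgs`, `promoter_regulated`,
#'   `candidates`, `dmer_lnc_pairs`, `dmer_mrna_pairs`, `cerna_pairs`,
#'   `edges`, `networks`, `modules`, `module_screen`, `module_auc`,
#'   `drug_network`.
#' @export
run_emtrn_pipeline <- function(study, config = emtrn_config()) {
  cfg <- config
  out <- list()
  expr_all <- rbind(study$lnc_expr, study$mrna_expr)

  ## methylome
  out$filtered <- filter_probes_by_missingness(study$beta, cfg$missing_max)
  out$imputed <- knn_impute(out$filtered, cfg$knn_k)
  out$regions <- build_enhancer_regions(study$manifest, cfg$half_width)
  # probes lost to the missingness filter leave their region; empty regions drop
  out$regions$probe_ids <- lapply(out$regions$probe_ids,
                                  intersect, rownames(out$imputed))
  out$regions$n_probes <- lengths(out$regions$probe_ids)
  out$regions <- out$regions[out$regions$n_probes > 0L, , drop = FALSE]
  out$region_meth <- summarize_region_methylation(out$imputed, out$regions)
  out$region_diff <- fit_group_difference(out$region_meth,
                                          study$sample_groups)
  out$dmers <- call_dmers(out$region_diff, cfg$dmer_lfc, cfg$dmer_adj_p)

  ## promoters
  out$promoter_map <- map_promoter_probes(study$manifest, study$genes,
                                          cfg$promoter_upstream)
  out$promoter_meth <- summarize_promoter_methylation(out$imputed,
                                                      out$promoter_map)
  out$promoter_diff <- fit_group_difference(out$promoter_meth,
                                            study$sample_groups)
  out$dpmgs <- call_dpmgs(out$promoter_diff, cfg$dpmg_delta, cfg$dpmg_adj_p)
  out$promoter_regulated <- identify_promoter_regulated_genes(
    out$promoter_meth, expr_all, out$dpmgs, cfg$link_p)

  ## DMER -> gene links
  dmer_tab <- merge(out$regions[, c("region_id", "chrom", "start", "end",
                                    "center")],
                    out$dmers[out$dmers$direction != "ns",
                              c("feature_id", "direction")],
                    by.x = "region_id", by.y = "feature_id")
  out$candidates <- candidate_pairs_by_distance(
    dmer_tab, study$genes, cfg$max_distance,
    exclude_genes = out$promoter_regulated)
  screened <- screen_pairs_by_correlation(out$candidates, out$region_meth,
                                          expr_all, cfg$link_p)
  out$dmer_lnc_pairs <- screened[screened$gene_type == "lncRNA", , drop = FALSE]
  out$dmer_mrna_pairs <- screened[screened$gene_type == "mRNA", , drop = FALSE]

  ## ceRNA network
  bg_pairs <- shared_mirna_significance(study$lnc_mirna, study$mirna_mrna,
                                        cfg$min_shared_mirna, cfg$cerna_fdr)
  out$cerna_pairs <- intersect_with_dmer_targets(bg_pairs,
                                                 out$dmer_lnc_pairs,
                                                 out$dmer_mrna_pairs)
  out$edges <- coexpression_screen(out$cerna_pairs, study$lnc_expr,
                                   study$mrna_expr, cfg$coexpr_pcc,
                                   cfg$coexpr_p)
  out$networks <- assemble_emtrn(out$edges, out$dmer_lnc_pairs,
                                 out$dmer_mrna_pairs, cfg$hub_top_frac)

  ## modules + survival
  out$modules <- enumerate_maximal_bicliques(out$networks$hypo$edges,
                                             cfg$biclique_min_lnc,
                                             cfg$biclique_min_mrna)
  out$module_screen <- screen_prognostic_modules(
    out$modules, expr_all, study$survival, cfg$seed, cfg$survival_p,
    cfg$standardize_cox)

  ## downstream
  out$module_auc <- lapply(seq_len(nrow(out$modules)), function(i)
    module_auc(study$val_expr, study$val_groups,
               c(out$modules$lncRNAs[[i]], out$modules$mRNAs[[i]])))
  names(out$module_auc) <- out$modules$module_id
  out$drug_network <- build_drug_network(study$drugs, out$networks$hypo)
  out
}

#' Write or read a synthetic study as a directory of portable files
#'
#' All tables are written in the package's TSV dialect (see the I/O
#' readers); the planted ground truth goes to `ground_truth.json`.
#'
#' @param study an `emtrn_study`.
#' @param dir directory path (created if needed).
#' @return `dir` (write) / an `emtrn_study` (read).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE, na = "NA")
  w(study$manifest, "probe_manifest.tsv")
  w(study$genes, "gene_models.tsv")
  write_matrix(study$beta, file.path(dir, "beta.tsv"), "probe_id")
  samples <- rbind(
    data.frame(sample_id = names(study$sample_groups),
               group = unname(study$sample_groups), cohort = "discovery",
               stringsAsFactors = FALSE),
    data.frame(sample_id = names(study$val_groups),
               group = unname(study$val_groups), cohort = "validation",
               stringsAsFactors = FALSE))
  w(samples, "samples.tsv")
  write_matrix(study$lnc_expr, file.path(dir, "expr_lncRNA.tsv"), "gene_id")
  write_matrix(study$mrna_expr, file.path(dir, "expr_mRNA.tsv"), "gene_id")
  write_matrix(study$val_expr, file.path(dir, "expr_validation.tsv"), "gene_id")
  w(study$lnc_mirna, "lnc_mirna.tsv")
  w(study$mirna_mrna, "mirna_mrna.tsv")
  w(study$survival, "survival.tsv")
  w(study$drugs, "drug_lncRNA.tsv")
  gt <- study$ground_truth
  gt$module_factors <- NULL            # internal; not a portable artifact
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  samples <- read_tsv_checked(file.path(dir, "samples.tsv"),
                              c("sample_id", "group", "cohort"), "samples")
  disc <- samples[samples$cohort == "discovery", ]
  val <- samples[samples$cohort == "validation", ]
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    g$modules <- lapply(seq_len(length(g$modules$lncRNAs)), function(i)
      list(lncRNAs = g$modules$lncRNAs[[i]], mRNAs = g$modules$mRNAs[[i]]))
    g
  } else NULL
  study <- list(
    manifest = read_probe_manifest(file.path(dir, "probe_manifest.tsv")),
    genes = read_gene_models(file.path(dir, "gene_models.tsv")),
    beta = read_matrix(file.path(dir, "beta.tsv")),
    sample_groups = setNames(disc$group, disc$sample_id),
    lnc_expr = read_matrix(file.path(dir, "expr_lncRNA.tsv")),
    mrna_expr = read_matrix(file.path(dir, "expr_mRNA.tsv")),
    val_expr = read_matrix(file.path(dir, "expr_validation.tsv")),
    val_groups = setNames(val$group, val$sample_id),
    lnc_mirna = read_edge_list(file.path(dir, "lnc_mirna.tsv"),
                               c("lncRNA", "miRNA")),
    mirna_mrna = read_edge_list(file.path(dir, "mirna_mrna.tsv"),
                                c("miRNA", "mRNA")),
    survival = read_survival_table(file.path(dir, "survival.tsv")),
    drugs = read_edge_list(file.path(dir, "drug_lncRNA.tsv"),
                           c("drug", "lncRNA", "direction")),
    ground_truth = gt)
  class(study) <- "emtrn_study"
  study
}

#' Write the main pipeline outputs to a directory
#'
#' Exports the portable artifacts of a [run_emtrn_pipeline()] result:
#' region BED, differential tables, screened pair tables, the EMTRN edge
#' lists and GraphML files with node tables, the module table with its
#' survival screen, and the drug network.
#'
#' @param result list from [run_emtrn_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE, na = "NA")
  write_regions_bed(result$regions, file.path(dir, "enhancer_regions.bed"))
  w(result$dmers, "dmer_calls.tsv")
  w(result$dpmgs, "dpmg_calls.tsv")
  w(result$dmer_lnc_pairs, "dmer_lncRNA_pairs.tsv")
  w(result$dmer_mrna_pairs, "dmer_mRNA_pairs.tsv")
  for (nm in c("full", "hyper", "hypo")) {
    net <- result$networks[[nm]]
    write_network_tsv(net, file.path(dir, sprintf("emtrn_%s.tsv", nm)))
    write_network_graphml(net, file.path(dir, sprintf("emtrn_%s.graphml", nm)))
    w(net$nodes, sprintf("emtrn_%s_nodes.tsv", nm))
  }
  mods <- result$modules
  flat <- data.frame(module_id = mods$module_id,
                     lncRNAs = vapply(mods$lncRNAs, paste, "", collapse = ","),
                     mRNAs = vapply(mods$mRNAs, paste, "", collapse = ","),
                     n_lnc = mods$n_lnc, n_mrna = mods$n_mrna,
                     stringsAsFactors = FALSE)
  w(flat, "modules.tsv")
  scr <- result$module_screen
  scr$coef <- vapply(scr$coef, function(b)
    if (is.null(b)) "" else paste(sprintf("%s=%.6g", names(b), b),
                                  collapse = ","), "")
  w(scr, "module_survival.tsv")
  write_network_tsv(result$drug_network, file.path(dir, "drug_network.tsv"))
  write_network_graphml(result$drug_network,
                        file.path(dir, "drug_network.graphml"))
  invisible(dir)
}
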