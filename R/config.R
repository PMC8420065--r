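#' Analysis thresholds for the EMTRN pipeline
#'
#' Returns the list of tunable thresholds used across the pipeline, with
#' defaults matching the published analysis conventions for this kind of
#' study. Any element can be overridden by name.
#'
#' @param ... named overrides of individual thresholds.
#'
#' @return A named list of class `emtrn_config`:
#' \describe{
#'   \item{missing_max}{maximum tolerated per-probe missing fraction
#'     (probes with a strictly larger fraction are removed); default 0.30.}
#'   \item{knn_k}{number of nearest probe neighbours for imputation; 10.}
#'   \item{half_width}{enhancer window half-width in bp around each CpG; 500.}
#'   \item{promoter_upstream}{promoter length upstream of the TSS in bp; 2000.}
#'   \item{max_distance}{maximum enhancer-centre-to-TSS distance in bp; 1e6.}
#'   \item{dmer_lfc}{minimum absolute group-difference coefficient for a
#'     DMER call; 0.01.}
#'   \item{dmer_adj_p}{BH-adjusted p cut for DMER calls; 0.05.}
#'   \item{dpmg_delta}{minimum absolute tumour-normal median beta difference
#'     for a promoter-gene (DPMG) call; 0.1.}
#'   \item{dpmg_adj_p}{BH-adjusted p cut for DPMG calls; 0.05.}
#'   \item{link_p}{p cut for the negative methylation-expression
#'     correlation screen of DMER-gene pairs; 0.05.}
#'   \item{min_shared_mirna}{minimum number of shared miRNAs for a ceRNA
#'     candidate pair; 2.}
#'   \item{cerna_fdr}{BH FDR cut for the shared-miRNA hypergeometric test;
#'     0.05.}
#'   \item{coexpr_pcc}{Pearson correlation an edge must strictly exceed;
#'     0.5.}
#'   \item{coexpr_p}{p cut for the co-expression screen; 0.05.}
#'   \item{biclique_min_lnc, biclique_min_mrna}{minimum lncRNA- and
#'     mRNA-side sizes of a reported biclique module; 2 each.}
#'   \item{survival_p}{log-rank p cut a module must meet in both the
#'     training and the test partition; 0.05.}
#'   \item{ora_p}{p cut for gene-set over-representation; 0.01.}
#'   \item{hub_top_frac}{fraction of top-degree nodes flagged as hubs;
#'     0.15.}
#'   \item{standardize_cox}{standardize module gene expression before the
#'     Cox fit; FALSE.}
#'   \item{seed}{integer seed used for the train/test split (and, in
#'     [run_emtrn_pipeline()], any other randomised step).}
#' }
#' @export
#' @examples
#' cfg <- emtrn_config(max_distance = 5e5)
#' cfg$max_distance
emtrn_config <- function(...) {
  cfg <- list(
    missing_max       = 0.30,
    knn_k             = 10L,
    half_width        = 500L,
    promoter_upstream = 2000L,
    max_distance      = 1e6,
    dmer_lfc          = 0.01,
    dmer_adj_p        = 0.05,
    dpmg_delta        = 0.1,
    dpmg_adj_p        = 0.05,
    link_p            = 0.05,
    min_shared_mirna  = 2L,
    cerna_fdr         = 0.05,
    coexpr_pcc        = 0.5,
    coexpr_p          = 0.05,
    biclique_min_lnc  = 2L,
    biclique_min_mrna = 2L,
    survival_p        = 0.05,
    ora_p             = 0.01,
    hub_top_frac      = 0.15,
    standardize_cox   = FALSE,
    seed              = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("emtrn_config() overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "emtrn_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path file path of the YAML document.
#' @return `read_config_yaml()` returns an `emtrn_config` list; unknown keys
#'   are an error so that typos do not silently fall back to defaults.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(emtrn_config, vals)
}

#' @rdname read_config_yaml
#' @param config an `emtrn_config` list.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
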