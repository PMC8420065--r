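# Synthetic-study generator with planted, machine-readable ground truth.
# The defaults define the package's reference in-silico study: 60 tumour /
# 30 normal methylomes over ~2,000 enhancer probes on 3 chromosomes, 300
# genes, 100 miRNAs, 20 planted hypomethylated-enhancer -> gene links (16
# of them organised into 3 complete-bipartite ceRNA modules, one of which
# drives survival), 10 hypermethylated regions, and 5 positively-coupled
# decoy links that the negative-correlation screen must reject.

#' Default parameters of the synthetic study
#'
#' @param ... named overrides.
#' @return named list of generator parameters. The headline knobs:
#'   `delta_meth` (raw-beta group shift of planted regions, default 0.25),
#'   `coupling_slope` (log2-expression change per unit region beta,
#'   default -0.8), `module_loading` (loading of module genes on their
#'   shared latent factor, default 0.45, chosen so that within-module
#'   pairwise expression PCC is about 0.7 once the methylation coupling is
#'   added), `hazard_coef` (log-hazard per unit of the prognostic module's
#'   factor, default 0.8), `baseline_hazard` (events/day, default
#'   log(2)/430, a 430-day median survival), `censor_rate` (default 3e-4,
#'   about 85% observed events), `missing_fraction` (overall fraction of
#'   masked beta cells, default 0.01) and `n_high_missing` (background
#'   probes given 40% missingness to exercise the QC filter, default 20).
#' @export
emtrn_sim_params <- function(...) {
  p <- list(
    n_chrom = 3L, chrom_length = 3e7,
    n_background_probes = 1900L,
    n_lncRNA = 100L, n_mRNA = 200L, n_miRNA = 100L,
    n_tumor = 60L, n_normal = 30L,
    module_sizes = list(c(3L, 3L), c(2L, 3L), c(2L, 3L)),  # (lnc, mRNA)
    prognostic_module = 1L,
    n_extra_links = 4L,          # planted links outside modules (1 lnc + 3 mRNA)
    n_extra_hypo = 5L,           # planted hypo regions without a target
    n_hyper = 10L,
    n_decoy = 5L,                # hypo regions with positively coupled targets
    n_promoter_regulated = 6L,   # DPMGs with coupled expression
    n_dpmg_uncoupled = 4L,       # DPMGs without coupled expression
    delta_meth = 0.25, delta_promoter = 0.2,
    hypo_normal_mean = 0.65, hyper_normal_mean = 0.35,
    probe_noise_sd = 0.05,
    region_sd_normal = 0.10, region_sd_tumor = 0.18,
    meth_factor_loading = 0.15,  # module region beta loss per unit factor
    coupling_slope = -0.8, module_loading = 0.5,
    expr_noise_sd = 0.35, bg_expr_sd = 0.5,
    promoter_expr_noise_sd = 0.2,
    baseline_log2_mean = 3, baseline_log2_sd = 1,
    mirnas_per_module = 6L, mirna_bg_density = 0.05,
    hazard_coef = 0.8, baseline_hazard = log(2) / 430, censor_rate = 3e-4,
    n_val_tumor = 40L, n_val_normal = 20L,
    val_shift = 1.0, val_noise_sd = 0.8,
    n_drugs = 8L, n_drug_hits = 6L,
    missing_fraction = 0.01, n_high_missing = 20L, high_missing_fraction = 0.4
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}

#' Exponential survival times under a proportional-hazards model
#'
#' Event times are Exponential with rate `baseline_hazard *
#' exp(linear_predictor)`; censoring times are Exponential with rate
#' `censor_rate`, independent; the observed time is the minimum and the
#' event flag records whether the event came first.
#'
#' @param linear_predictor numeric vector (optionally named by sample id).
#' @param baseline_hazard,censor_rate positive rates.
#' @param seed optional integer seed.
#' @return data.frame: `sample_id`, `time`, `event`.
#' @export
simulate_survival_times <- function(linear_predictor, baseline_hazard,
                                    censor_rate, seed = NULL) {
  if (baseline_hazard <= 0 || censor_rate <= 0)
    stop("rates must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(linear_predictor)
  te <- rexp(n, rate = baseline_hazard * exp(linear_predictor))
  tc <- rexp(n, rate = censor_rate)
  ids <- names(linear_predictor)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  data.frame(sample_id = ids,
             time = pmin(te, tc),
             event = as.integer(te <= tc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mask matrix cells uniformly at random
#'
#' Exactly `floor(fraction * length(m))` cells are set to `NA`. Optionally
#' a chosen minority of rows is first given `high_fraction` missingness
#' (to exercise the per-probe missingness filter); the remaining budget is
#' spread uniformly over all other cells.
#'
#' @param m numeric matrix.
#' @param fraction overall missing fraction in `[0, 1)`.
#' @param seed optional integer seed.
#' @param high_rows row indices (or names) to overload.
#' @param high_fraction per-row missing fraction for `high_rows`;
#'   default 0.4.
#' @return `m` with `NA`s inserted.
#' @export
inject_missingness <- function(m, fraction, seed = NULL,
                               high_rows = integer(0), high_fraction = 0.4) {
  if (fraction >= 1) stop("fraction must be < 1")
  if (!is.null(seed)) set.seed(seed)
  total <- floor(fraction * length(m))
  if (total == 0L && !length(high_rows)) return(m)
  if (is.character(high_rows)) high_rows <- match(high_rows, rownames(m))
  idx_high <- integer(0)
  if (length(high_rows)) {
    ncell <- floor(high_fraction * ncol(m))
    idx_high <- unlist(lapply(high_rows, function(i)
      (sample.int(ncol(m), ncell) - 1L) * nrow(m) + i))
    if (length(idx_high) > total) {
      high_rows <- high_rows[seq_len(max(0L, total %/% ncell))]
      idx_high <- idx_high[seq_len(length(high_rows) * ncell)]
    }
  }
  rem <- total - length(idx_high)
  pool <- setdiff(seq_along(m), idx_high)
  idx <- c(idx_high, sample(pool, max(rem, 0L)))
  m[idx] <- NA_real_
  m
}

clip01 <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Simulate a complete in-silico enhancer-methylation study
#'
#' Generates, deterministically for a given seed, every table the EMTRN
#' pipeline consumes -- probe manifest, beta matrix with group labels and
#' injected missingness, gene models, tumour expression matrices, a
#' tumour/normal validation expression matrix, lncRNA-miRNA and
#' miRNA-mRNA interaction lists, a survival table and a drug association
#' table -- together with machine-readable ground truth describing what
#' was planted (differentially methylated regions, region-gene couplings,
#' complete-bipartite ceRNA modules, the prognostic module, drug hits).
#'
#' See `emtrn_sim_params()` for the tunable parameters and the methods
#' vignette for the generative model.
#'
#' @param params parameter list from [emtrn_sim_params()].
#' @param seed integer seed; the output is a deterministic function of
#'   (`params`, `seed`).
#' @return an `emtrn_study` list; see Details.
#' @export
simulate_study <- function(params = emtrn_sim_params(), seed = 1L) {
  p <- params
  if (p$n_tumor < 4L || p$n_normal < 4L)
    stop("need at least 4 samples per group")
  set.seed(seed)
  chroms <- paste0("chr", seq_len(p$n_chrom))
  tumor_ids <- sprintf("T%03d", seq_len(p$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(p$n_normal))
  groups <- setNames(c(rep("tumor", p$n_tumor), rep("normal", p$n_normal)),
                     c(tumor_ids, normal_ids))

  ## ---- planted enhancer clusters -------------------------------------
  mod_lnc_n <- vapply(p$module_sizes, `[`, 0L, 1L)
  mod_mrna_n <- vapply(p$module_sizes, `[`, 0L, 2L)
  n_module_genes <- sum(mod_lnc_n) + sum(mod_mrna_n)
  n_linked <- n_module_genes + p$n_extra_links
  n_clusters <- n_linked + p$n_decoy + p$n_extra_hypo + p$n_hyper
  roles <- c(rep("module", n_module_genes),
             rep("extra_link", p$n_extra_links),
             rep("decoy", p$n_decoy),
             rep("extra_hypo", p$n_extra_hypo),
             rep("hyper", p$n_hyper))
  cl_chrom <- rep(chroms, length.out = n_clusters)
  centers <- unlist(lapply(chroms, function(ch) {
    k <- sum(cl_chrom == ch)
    base <- seq(2e6, p$chrom_length - 2e6, length.out = k)
    round(base + runif(k, -2e4, 2e4))
  }))
  cl <- data.frame(cluster = seq_len(n_clusters), role = roles,
                   chrom = cl_chrom[order(cl_chrom)], center = centers,
                   stringsAsFactors = FALSE)
  # roles were laid out in cluster order; re-shuffle so roles are spread
  # over chromosomes rather than blocked
  cl$role <- sample(roles)
  cl$direction <- ifelse(cl$role == "hyper", "hyper", "hypo")

  cl_probes <- lapply(seq_len(n_clusters), function(i) {
    k <- sample(2:3, 1L)
    off <- sort(sample(seq(-300L, 300L, by = 5L), k))
    data.frame(cluster = i, chrom = cl$chrom[i],
               position = cl$center[i] + off, stringsAsFactors = FALSE)
  })
  cl_probes <- do.call(rbind, cl_probes)

  ## ---- background enhancer probes ------------------------------------
  bg <- data.frame(chrom = sample(chroms, p$n_background_probes, replace = TRUE),
                   stringsAsFactors = FALSE)
  bg$position <- round(runif(p$n_background_probes, 1e4, p$chrom_length - 1e4))
  # keep clear of planted clusters so planted regions stay intact
  near <- vapply(seq_len(nrow(bg)), function(i) {
    any(cl$chrom == bg$chrom[i] & abs(cl$center - bg$position[i]) < 1500)
  }, TRUE)
  while (any(near)) {
    bg$position[near] <- round(runif(sum(near), 1e4, p$chrom_length - 1e4))
    near <- vapply(seq_len(nrow(bg)), function(i) {
      any(cl$chrom == bg$chrom[i] & abs(cl$center - bg$position[i]) < 1500)
    }, TRUE)
  }

  ## ---- gene models ----------------------------------------------------
  n_genes <- p$n_lncRNA + p$n_mRNA
  genes <- data.frame(
    gene_id = c(sprintf("LNC_%04d", seq_len(p$n_lncRNA)),
                sprintf("MRNA_%04d", seq_len(p$n_mRNA))),
    gene_type = c(rep("lncRNA", p$n_lncRNA), rep("mRNA", p$n_mRNA)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = round(runif(n_genes, 1e4, p$chrom_length - 1e4)),
    stringsAsFactors = FALSE)

  # assign planted target genes to clusters with a gene role
  linked_cl <- which(cl$role %in% c("module", "extra_link", "decoy"))
  need_lnc <- sum(mod_lnc_n) + 1L + 2L       # modules + 1 extra + 2 decoys
  need_mrna <- length(linked_cl) - need_lnc
  lnc_pick <- sample(which(genes$gene_type == "lncRNA"), need_lnc)
  mrna_pick <- sample(which(genes$gene_type == "mRNA"), need_mrna)
  # order linked clusters so module clusters come first, then extras, decoys
  linked_cl <- linked_cl[order(match(cl$role[linked_cl],
                                     c("module", "extra_link", "decoy")))]
  # lncRNA targets first (modules, extra, decoys), then mRNA targets
  lnc_cl <- c(linked_cl[cl$role[linked_cl] == "module"][seq_len(sum(mod_lnc_n))],
              linked_cl[cl$role[linked_cl] == "extra_link"][1L],
              linked_cl[cl$role[linked_cl] == "decoy"][1:2])
  mrna_cl <- setdiff(linked_cl, lnc_cl)
  mrna_cl <- mrna_cl[order(match(cl$role[mrna_cl],
                                 c("module", "extra_link", "decoy")))]
  target_gene <- integer(n_clusters)        # gene row per cluster (0 = none)
  target_gene[lnc_cl] <- lnc_pick
  target_gene[mrna_cl] <- mrna_pick
  gi <- which(target_gene > 0L)
  off <- sample(c(-1, 1), length(gi), TRUE) * round(runif(length(gi), 5e4, 8e5))
  genes$chrom[target_gene[gi]] <- cl$chrom[gi]
  genes$tss[target_gene[gi]] <-
    pmin(pmax(cl$center[gi] + off, 1e4), p$chrom_length - 1e4)

  # module membership (gene ids)
  mod_idx_lnc <- split(lnc_pick[seq_len(sum(mod_lnc_n))],
                       rep(seq_along(p$module_sizes), mod_lnc_n))
  mod_idx_mrna <- split(mrna_pick[seq_len(sum(mod_mrna_n))],
                        rep(seq_along(p$module_sizes), mod_mrna_n))
  module_members <- lapply(seq_along(p$module_sizes), function(m)
    list(lncRNAs = sort(genes$gene_id[mod_idx_lnc[[m]]]),
         mRNAs = sort(genes$gene_id[mod_idx_mrna[[m]]])))

  # planted DPMGs drawn from genes without an enhancer role
  free_genes <- setdiff(seq_len(n_genes), target_gene[gi])
  dpmg_idx <- sample(free_genes, p$n_promoter_regulated + p$n_dpmg_uncoupled)
  promreg_idx <- dpmg_idx[seq_len(p$n_promoter_regulated)]
  dpmg_unc_idx <- setdiff(dpmg_idx, promreg_idx)

  ## ---- promoter probes ------------------------------------------------
  tss0 <- genes$tss - 1L
  pstart <- ifelse(genes$strand == "+", tss0 - 2000L, tss0)
  pend <- ifelse(genes$strand == "+", tss0, tss0 + 2000L)
  pstart <- pmax(pstart, 0L)
  has_prom <- runif(n_genes) < 0.9 | seq_len(n_genes) %in% dpmg_idx
  prom_probes <- lapply(which(has_prom), function(g) {
    k <- if (g %in% dpmg_idx) 2L else sample(1:2, 1L)
    pos0 <- sample(seq(pstart[g] + 10L, pend[g] - 10L, by = 7L), k)
    data.frame(gene = g, chrom = genes$chrom[g], position = pos0 + 1L,
               stringsAsFactors = FALSE)
  })
  prom_probes <- do.call(rbind, prom_probes)
  # a handful of enhancer-flagged probes inside promoters (must be ignored
  # by the promoter mapper) -- placed for 5 random genes
  enh_in_prom <- sample(which(has_prom), 5L)
  eip <- data.frame(chrom = genes$chrom[enh_in_prom],
                    position = pmax(pstart[enh_in_prom] + 500L, 1L) + 1L,
                    stringsAsFactors = FALSE)

  ## ---- manifest -------------------------------------------------------
  manifest <- rbind(
    data.frame(probe_id = sprintf("EPRB_%05d", seq_len(nrow(cl_probes))),
               chrom = cl_probes$chrom, position = cl_probes$position,
               is_enhancer = TRUE, stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("EPRB_%05d",
                                  nrow(cl_probes) + seq_len(nrow(bg))),
               chrom = bg$chrom, position = bg$position,
               is_enhancer = TRUE, stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("EPRB_%05d",
                                  nrow(cl_probes) + nrow(bg) + seq_len(nrow(eip))),
               chrom = eip$chrom, position = eip$position,
               is_enhancer = TRUE, stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("PPRB_%05d", seq_len(nrow(prom_probes))),
               chrom = prom_probes$chrom, position = prom_probes$position,
               is_enhancer = FALSE, stringsAsFactors = FALSE))
  validate_probe_manifest(manifest)
  n_all_samples <- p$n_tumor + p$n_normal
  is_tum <- groups == "tumor"

  ## ---- beta matrix ----------------------------------------------------
  beta <- matrix(NA_real_, nrow(manifest), n_all_samples,
                 dimnames = list(manifest$probe_id, names(groups)))
  # background probes: bimodal logit-normal, no group effect
  bg_rows <- which(!(manifest$probe_id %in%
                       sprintf("EPRB_%05d", seq_len(nrow(cl_probes)))) &
                     !(manifest$probe_id %in%
                         sprintf("PPRB_%05d",
                                 which(prom_probes$gene %in% dpmg_idx))))
  mu <- ifelse(runif(length(bg_rows)) < 0.5, -1.5, 1.5) +
    rnorm(length(bg_rows), 0, 0.8)
  beta[bg_rows, ] <- plogis(mu + matrix(rnorm(length(bg_rows) * n_all_samples,
                                              0, 0.5),
                                        length(bg_rows)))
  # module latent factors (tumour samples)
  n_mod <- length(p$module_sizes)
  fmod <- matrix(rnorm(n_mod * p$n_tumor), n_mod, p$n_tumor,
                 dimnames = list(NULL, tumor_ids))
  # planted enhancer clusters
  cl_beta_true <- matrix(NA_real_, n_clusters, n_all_samples,
                         dimnames = list(NULL, names(groups)))
  for (i in seq_len(n_clusters)) {
    m_norm <- if (cl$direction[i] == "hypo") p$hypo_normal_mean else p$hyper_normal_mean
    m_tum <- m_norm + if (cl$direction[i] == "hypo") -p$delta_meth else p$delta_meth
    dev <- numeric(n_all_samples)
    dev[!is_tum] <- rnorm(p$n_normal, 0, p$region_sd_normal)
    g <- target_gene[i]
    mod <- if (g > 0L && cl$role[i] == "module")
      which(vapply(seq_len(n_mod), function(m)
        genes$gene_id[g] %in% unlist(module_members[[m]]), TRUE)) else integer(0)
    if (length(mod)) {
      dev[is_tum] <- -p$meth_factor_loading * fmod[mod, ] +
        rnorm(p$n_tumor, 0, p$region_sd_normal)
    } else if (g > 0L) {
      dev[is_tum] <- rnorm(p$n_tumor, 0, p$region_sd_tumor)
    } else {
      dev[is_tum] <- rnorm(p$n_tumor, 0, p$region_sd_normal)
    }
    truev <- clip01(ifelse(is_tum, m_tum, m_norm) + dev)
    cl_beta_true[i, ] <- truev
    rows <- which(cl_probes$cluster == i)
    for (r in rows)
      beta[r, ] <- clip01(truev + rnorm(n_all_samples, 0, p$probe_noise_sd))
  }
  # planted DPMG promoter probes: gene-level group shift
  dpmg_beta_true <- matrix(NA_real_, length(dpmg_idx), n_all_samples,
                           dimnames = list(genes$gene_id[dpmg_idx],
                                           names(groups)))
  for (j in seq_along(dpmg_idx)) {
    g <- dpmg_idx[j]
    hyper <- if (g %in% promreg_idx) TRUE else runif(1) < 0.5
    m_norm <- if (hyper) 0.40 else 0.60
    m_tum <- m_norm + if (hyper) p$delta_promoter else -p$delta_promoter
    dev <- numeric(n_all_samples)
    dev[!is_tum] <- rnorm(p$n_normal, 0, 0.08)
    dev[is_tum] <- rnorm(p$n_tumor, 0, 0.15)
    truev <- clip01(ifelse(is_tum, m_tum, m_norm) + dev)
    dpmg_beta_true[j, ] <- truev
    rows <- which(prom_probes$gene == g) + nrow(cl_probes) + nrow(bg) + nrow(eip)
    pid <- manifest$probe_id[rows]
    for (r in pid)
      beta[r, ] <- clip01(truev + rnorm(n_all_samples, 0, p$probe_noise_sd))
  }
  stopifnot(!anyNA(beta))

  ## ---- expression (tumour cohort) ------------------------------------
  base_log2 <- rnorm(n_genes, p$baseline_log2_mean, p$baseline_log2_sd)
  log2e <- matrix(rnorm(n_genes * p$n_tumor, 0, p$bg_expr_sd),
                  n_genes, p$n_tumor,
                  dimnames = list(genes$gene_id, tumor_ids)) + base_log2
  for (i in gi) {                     # enhancer-coupled targets
    g <- target_gene[i]
    slope <- if (cl$role[i] == "decoy") -p$coupling_slope else p$coupling_slope
    sig <- base_log2[g] + slope * cl_beta_true[i, tumor_ids]
    mod <- which(vapply(seq_len(n_mod), function(m)
      genes$gene_id[g] %in% unlist(module_members[[m]]), TRUE))
    if (length(mod)) sig <- sig + p$module_loading * fmod[mod, ]
    log2e[g, ] <- sig + rnorm(p$n_tumor, 0, p$expr_noise_sd)
  }
  for (j in seq_along(promreg_idx)) { # promoter-regulated genes
    g <- promreg_idx[j]
    log2e[g, ] <- base_log2[g] +
      p$coupling_slope * dpmg_beta_true[genes$gene_id[g], tumor_ids] +
      rnorm(p$n_tumor, 0, p$promoter_expr_noise_sd)
  }
  fpkm <- 2^log2e
  lnc_expr <- fpkm[genes$gene_type == "lncRNA", , drop = FALSE]
  mrna_expr <- fpkm[genes$gene_type == "mRNA", , drop = FALSE]

  ## ---- validation expression (independent tumour/normal cohort) ------
  val_ids <- c(sprintf("VT%03d", seq_len(p$n_val_tumor)),
               sprintf("VN%03d", seq_len(p$n_val_normal)))
  val_groups <- setNames(c(rep("tumor", p$n_val_tumor),
                           rep("normal", p$n_val_normal)), val_ids)
  val_log2 <- matrix(rnorm(n_genes * length(val_ids), 0, p$val_noise_sd),
                     n_genes, length(val_ids),
                     dimnames = list(genes$gene_id, val_ids)) + base_log2
  module_gene_ids <- unlist(lapply(module_members, unlist))
  val_log2[module_gene_ids, val_groups == "tumor"] <-
    val_log2[module_gene_ids, val_groups == "tumor"] + p$val_shift
  val_expr <- 2^val_log2

  ## ---- miRNA interactions --------------------------------------------
  mirnas <- sprintf("MIR_%03d", seq_len(p$n_miRNA))
  lnc_ids <- genes$gene_id[genes$gene_type == "lncRNA"]
  mrna_ids <- genes$gene_id[genes$gene_type == "mRNA"]
  A <- matrix(runif(length(lnc_ids) * p$n_miRNA) < p$mirna_bg_density,
              length(lnc_ids), p$n_miRNA, dimnames = list(lnc_ids, mirnas))
  B <- matrix(runif(p$n_miRNA * length(mrna_ids)) < p$mirna_bg_density,
              p$n_miRNA, length(mrna_ids), dimnames = list(mirnas, mrna_ids))
  mod_mirnas <- split(sample(mirnas, p$mirnas_per_module * n_mod),
                      rep(seq_len(n_mod), each = p$mirnas_per_module))
  for (m in seq_len(n_mod)) {
    A[module_members[[m]]$lncRNAs, mod_mirnas[[m]]] <- TRUE
    B[mod_mirnas[[m]], module_members[[m]]$mRNAs] <- TRUE
  }
  ai <- which(A, arr.ind = TRUE)
  lnc_mirna <- data.frame(lncRNA = rownames(A)[ai[, 1L]],
                          miRNA = colnames(A)[ai[, 2L]],
                          stringsAsFactors = FALSE)
  bi <- which(B, arr.ind = TRUE)
  mirna_mrna <- data.frame(miRNA = rownames(B)[bi[, 1L]],
                           mRNA = colnames(B)[bi[, 2L]],
                           stringsAsFactors = FALSE)

  ## ---- survival -------------------------------------------------------
  lp <- p$hazard_coef * fmod[p$prognostic_module, ]
  surv <- simulate_survival_times(lp, p$baseline_hazard, p$censor_rate)

  ## ---- drugs ----------------------------------------------------------
  drug_ids <- sprintf("DRUG_%02d", seq_len(p$n_drugs))
  mod_lncs <- unlist(lapply(module_members, `[[`, "lncRNAs"))
  hit_lncs <- sample(mod_lncs, p$n_drug_hits, replace = p$n_drug_hits > length(mod_lncs))
  hits <- unique(data.frame(drug = rep(drug_ids, length.out = p$n_drug_hits),
                            lncRNA = hit_lncs,
                            direction = "down", stringsAsFactors = FALSE))
  other_lncs <- setdiff(lnc_ids, mod_lncs)
  decoys <- data.frame(
    drug = sample(drug_ids, 6L, replace = TRUE),
    lncRNA = c(sample(mod_lncs, 3L), sample(other_lncs, 3L)),
    direction = c("up", "up", "up", "down", "down", "down"),
    stringsAsFactors = FALSE)
  drugs <- rbind(hits, decoys, hits[1L, ])   # one duplicate row on purpose
  rownames(drugs) <- NULL

  ## ---- planted region ids (via the region constructor) ---------------
  regions <- build_enhancer_regions(manifest, half_width = 500L)
  probe2region <- setNames(rep(regions$region_id, regions$n_probes),
                           unlist(regions$probe_ids))
  first_probe <- manifest$probe_id[match(paste(cl_probes$chrom,
                                               cl_probes$position),
                                         paste(manifest$chrom,
                                               manifest$position))]
  cl$region_id <- probe2region[first_probe[match(seq_len(n_clusters),
                                                 cl_probes$cluster)]]
  # each planted cluster must occupy its own region
  stopifnot(!anyNA(cl$region_id), !anyDuplicated(cl$region_id))

  links <- data.frame(region_id = cl$region_id[gi],
                      gene_id = genes$gene_id[target_gene[gi]],
                      gene_type = genes$gene_type[target_gene[gi]],
                      role = cl$role[gi],
                      stringsAsFactors = FALSE)
  ground_truth <- list(
    delta_meth = p$delta_meth,
    hypo_regions = cl$region_id[cl$direction == "hypo"],
    hyper_regions = cl$region_id[cl$direction == "hyper"],
    links = links[links$role != "decoy", ],
    decoy_links = links[links$role == "decoy", ],
    modules = module_members,
    prognostic_module = p$prognostic_module,
    hazard_coef = p$hazard_coef,
    module_factors = fmod,
    promoter_regulated_genes = genes$gene_id[promreg_idx],
    dpmg_genes = genes$gene_id[dpmg_idx],
    drug_hits = hits[, c("drug", "lncRNA")])

  ## ---- missingness ----------------------------------------------------
  # overload only background enhancer probes, far from anything planted
  high_rows <- sample(sprintf("EPRB_%05d", nrow(cl_probes) + seq_len(nrow(bg))),
                      p$n_high_missing)
  beta <- inject_missingness(beta, p$missing_fraction,
                             high_rows = high_rows,
                             high_fraction = p$high_missing_fraction)

  study <- list(manifest = manifest, genes = genes,
                beta = beta, sample_groups = groups,
                lnc_expr = lnc_expr, mrna_expr = mrna_expr,
                val_expr = val_expr, val_groups = val_groups,
                lnc_mirna = lnc_mirna, mirna_mrna = mirna_mrna,
                survival = surv, drugs = drugs,
                ground_truth = ground_truth, params = p, seed = seed)
  class(study) <- "emtrn_study"
  validate_ground_truth(study)
  study
}

# every planted id must exist in the generated tables
validate_ground_truth <- function(study) {
  gt <- study$ground_truth
  regions <- build_enhancer_regions(study$manifest)
  stopifnot(
    all(c(gt$hypo_regions, gt$hyper_regions) %in% regions$region_id),
    all(gt$links$gene_id %in% study$genes$gene_id),
    all(unlist(lapply(gt$modules, unlist)) %in% study$genes$gene_id),
    all(gt$drug_hits$lncRNA %in% study$genes$gene_id),
    all(gt$promoter_regulated_genes %in% study$genes$gene_id),
    all(study$survival$sample_id %in% names(study$sample_groups)))
  invisible(study)
}

#' @export
print.emtrn_study <- function(x, ...) {
  cat("emtrn synthetic study (seed ", x$seed, "): ",
      nrow(x$manifest), " probes, ",
      sum(x$sample_groups == "tumor"), " tumour / ",
      sum(x$sample_groups == "normal"), " normal samples, ",
      nrow(x$genes), " genes, ",
      length(unique(x$lnc_mirna$miRNA)), "+ miRNAs\n", sep = "")
  invisible(x)
}
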