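# DMER -> target gene linking: promoter-regulated exclusion list,
# distance-based candidates, negative-correlation screen.

# vectorised Pearson r of paired rows plus the two-sided p from the
# t transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df
paired_row_cor <- function(a, b) {
  n <- ncol(a)
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  sa <- sqrt(rowSums(ca^2))
  sb <- sqrt(rowSums(cb^2))
  r <- rowSums(ca * cb) / (sa * sb)       # NaN where a side is constant
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- r[ok]
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  p[ok][abs(rr) >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Genes whose expression is controlled by promoter methylation
#'
#' For each called DPMG, correlates its promoter beta with its expression
#' across the samples shared between the two matrices; a gene is retained
#' when the Pearson correlation is negative with p <= `p_cut`. The returned
#' set is used downstream as an exclusion list, so that enhancer-linked
#' genes are not confounded by promoter regulation.
#'
#' @param promoter_meth gene-level promoter beta matrix.
#' @param expression expression matrix (genes x samples) holding at least
#'   the DPMG genes present in both matrices.
#' @param dpmgs output of [call_dpmgs()]; rows with `direction != "ns"`
#'   are the DPMGs.
#' @param p_cut correlation p cut; default 0.05.
#' @return character vector of promoter-regulated gene ids; the full
#'   per-gene table is attached as attribute `table`.
#' @export
identify_promoter_regulated_genes <- function(promoter_meth, expression,
                                              dpmgs, p_cut = 0.05) {
  genes <- dpmgs$feature_id[dpmgs$direction != "ns"]
  genes <- intersect(genes, rownames(promoter_meth))
  genes <- intersect(genes, rownames(expression))
  shared <- intersect(colnames(promoter_meth), colnames(expression))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  if (!length(genes))
    return(structure(character(0), table = NULL))
  a <- promoter_meth[genes, shared, drop = FALSE]
  b <- expression[genes, shared, drop = FALSE]
  cc <- paired_row_cor(a, b)
  skipped <- is.na(cc$r)
  if (any(skipped))
    warning("constant methylation or expression for gene(s) ",
            paste(genes[skipped], collapse = ", "), "; skipped")
  keep <- !skipped & cc$r < 0 & cc$p <= p_cut
  tab <- data.frame(gene_id = genes, pcc = cc$r, p = cc$p,
                    retained = keep, stringsAsFactors = FALSE)
  structure(genes[keep], table = tab)
}

#' Candidate DMER-gene pairs by chromosome and distance
#'
#' Pairs every called DMER with every gene on the same chromosome whose TSS
#' lies within `max_distance` bp of the region centre (absolute distance,
#' strand ignored), excluding genes on the promoter-regulated exclusion
#' list. A gene may pair with many DMERs and vice versa.
#'
#' @param dmers region table (from [build_enhancer_regions()]) joined with a
#'   `direction` column; only rows with direction `hyper`/`hypo` are used.
#' @param genes gene model data.frame.
#' @param max_distance maximum centre-to-TSS distance in bp; default 1e6.
#' @param exclude_genes character vector of gene ids to exclude.
#' @return data.frame: `region_id`, `gene_id`, `gene_type`, `distance`,
#'   `direction`.
#' @export
candidate_pairs_by_distance <- function(dmers, genes, max_distance = 1e6,
                                        exclude_genes = character(0)) {
  d <- dmers[dmers$direction %in% c("hyper", "hypo"), , drop = FALSE]
  g <- genes[!(genes$gene_id %in% exclude_genes), , drop = FALSE]
  if (!nrow(d) || !nrow(g))
    return(data.frame(region_id = character(), gene_id = character(),
                      gene_type = character(), distance = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  out <- vector("list", length(unique(d$chrom)))
  names(out) <- unique(d$chrom)
  for (ch in unique(d$chrom)) {
    di <- d[d$chrom == ch, , drop = FALSE]
    gi <- g[g$chrom == ch, , drop = FALSE]
    if (!nrow(gi)) next
    dist <- abs(outer(di$center, gi$tss - 1L, "-"))   # centre vs 0-based TSS
    hit <- which(dist <= max_distance, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[ch]] <- data.frame(region_id = di$region_id[hit[, 1L]],
                            gene_id = gi$gene_id[hit[, 2L]],
                            gene_type = gi$gene_type[hit[, 2L]],
                            distance = dist[hit],
                            direction = di$direction[hit[, 1L]],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(region_id = character(), gene_id = character(),
                      gene_type = character(), distance = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  res <- res[order(res$region_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Screen DMER-gene candidates by negative correlation
#'
#' Pearson correlation between region beta and gene expression across the
#' tumour samples shared by the two matrices; a pair is kept when `r < 0`
#' and the two-sided p is `<= p_cut`. Pairs whose region or gene is absent
#' from the matrices, or with a constant vector, are skipped with a
#' warning.
#'
#' @param candidates data.frame from [candidate_pairs_by_distance()].
#' @param region_meth region-level beta matrix.
#' @param expression expression matrix covering the candidate genes
#'   (lncRNAs and mRNAs together).
#' @param p_cut correlation p cut; default 0.05.
#' @return `candidates` restricted to the retained pairs, with `pcc` and
#'   `p` columns added.
#' @export
screen_pairs_by_correlation <- function(candidates, region_meth, expression,
                                        p_cut = 0.05) {
  shared <- intersect(colnames(region_meth), colnames(expression))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  ok <- candidates$region_id %in% rownames(region_meth) &
    candidates$gene_id %in% rownames(expression)
  if (any(!ok))
    warning(sum(!ok), " candidate pair(s) with missing region or gene skipped")
  cand <- candidates[ok, , drop = FALSE]
  if (!nrow(cand)) {
    cand$pcc <- numeric(0); cand$p <- numeric(0)
    return(cand)
  }
  cc <- paired_row_cor(region_meth[cand$region_id, shared, drop = FALSE],
                       expression[cand$gene_id, shared, drop = FALSE])
  if (anyNA(cc$r))
    warning(sum(is.na(cc$r)), " pair(s) with constant vectors skipped")
  keep <- !is.na(cc$r) & cc$r < 0 & cc$p <= p_cut
  cand$pcc <- cc$r
  cand$p <- cc$p
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
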