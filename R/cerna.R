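# Shared-miRNA ceRNA screen, co-expression edges, EMTRN assembly.

#' Shared-miRNA hypergeometric screen for lncRNA-mRNA pairs
#'
#' Every lncRNA-mRNA pair sharing at least `min_shared` miRNA partners is
#' tested for over-representation of shared miRNAs: with a miRNA universe of
#' size `N` (the union of miRNAs in the two interaction tables), a lncRNA
#' with `K` partners, an mRNA with `n` partners and `k` shared, the p-value
#' is the upper tail `P(X >= k)` of Hypergeometric(N, K, n). p-values are
#' BH-adjusted across all tested pairs and pairs with FDR `<= fdr_cut` are
#' retained.
#'
#' @param lnc_mirna data.frame with columns `lncRNA`, `miRNA`.
#' @param mirna_mrna data.frame with columns `miRNA`, `mRNA`.
#' @param min_shared minimum shared-miRNA count to test; default 2.
#' @param fdr_cut BH FDR cut; default 0.05.
#' @param universe `"union"` (default) counts miRNAs appearing in either
#'   table; `"intersection"` only those appearing in both.
#' @return data.frame of retained pairs: `lncRNA`, `mRNA`, `n_lnc_mirna`,
#'   `n_mrna_mirna`, `n_shared`, `p`, `fdr`. The full tested table is
#'   attached as attribute `tested`.
#' @export
shared_mirna_significance <- function(lnc_mirna, mirna_mrna,
                                      min_shared = 2L, fdr_cut = 0.05,
                                      universe = c("union", "intersection")) {
  universe <- match.arg(universe)
  empty <- data.frame(lncRNA = character(), mRNA = character(),
                      n_lnc_mirna = integer(), n_mrna_mirna = integer(),
                      n_shared = integer(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(lnc_mirna) || !nrow(mirna_mrna)) {
    warning("empty interaction table; no ceRNA pairs tested")
    return(structure(empty, tested = empty))
  }
  mi <- switch(universe,
               union = union(lnc_mirna$miRNA, mirna_mrna$miRNA),
               intersection = intersect(lnc_mirna$miRNA, mirna_mrna$miRNA))
  lnc_mirna <- lnc_mirna[lnc_mirna$miRNA %in% mi, , drop = FALSE]
  mirna_mrna <- mirna_mrna[mirna_mrna$miRNA %in% mi, , drop = FALSE]
  lncs <- sort(unique(lnc_mirna$lncRNA))
  mrnas <- sort(unique(mirna_mrna$mRNA))
  N <- length(mi)
  A <- matrix(0L, length(lncs), N, dimnames = list(lncs, mi))
  A[cbind(match(lnc_mirna$lncRNA, lncs), match(lnc_mirna$miRNA, mi))] <- 1L
  B <- matrix(0L, length(mrnas), N, dimnames = list(mrnas, mi))
  B[cbind(match(mirna_mrna$mRNA, mrnas), match(mirna_mrna$miRNA, mi))] <- 1L
  shared <- tcrossprod(A, B)                   # lnc x mrna shared counts
  K <- rowSums(A)
  n <- rowSums(B)
  idx <- which(shared >= min_shared, arr.ind = TRUE)
  if (!nrow(idx)) return(structure(empty, tested = empty))
  k <- shared[idx]
  Ki <- K[idx[, 1L]]
  ni <- n[idx[, 2L]]
  p <- phyper(k - 1L, Ki, N - Ki, ni, lower.tail = FALSE)
  tested <- data.frame(lncRNA = lncs[idx[, 1L]], mRNA = mrnas[idx[, 2L]],
                       n_lnc_mirna = as.integer(Ki),
                       n_mrna_mirna = as.integer(ni),
                       n_shared = as.integer(k),
                       p = p, fdr = p.adjust(p, "BH"),
                       stringsAsFactors = FALSE)
  tested <- tested[order(tested$p, tested$lncRNA, tested$mRNA), , drop = FALSE]
  rownames(tested) <- NULL
  out <- tested[tested$fdr <= fdr_cut, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, tested = tested)
}

#' Restrict ceRNA pairs to DMER-linked genes
#'
#' Keeps a pair only when its lncRNA occurs in the screened DMER-lncRNA
#' pairs and its mRNA occurs in the screened DMER-mRNA pairs.
#'
#' @param pairs ceRNA pair table from [shared_mirna_significance()].
#' @param dmer_lnc_pairs,dmer_mrna_pairs screened pair tables from
#'   [screen_pairs_by_correlation()], split by gene type.
#' @return the filtered pair table.
#' @export
intersect_with_dmer_targets <- function(pairs, dmer_lnc_pairs, dmer_mrna_pairs) {
  keep <- pairs$lncRNA %in% dmer_lnc_pairs$gene_id &
    pairs$mRNA %in% dmer_mrna_pairs$gene_id
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-expression screen of candidate lncRNA-mRNA pairs
#'
#' Pearson correlation across the tumour samples shared by the two
#' expression matrices; an edge is kept when `r > pcc_cut` (strict) and the
#' two-sided p is `<= p_cut`.
#'
#' @param pairs candidate pair table with columns `lncRNA`, `mRNA`.
#' @param lnc_expr,mrna_expr expression matrices (genes x samples).
#' @param pcc_cut correlation threshold; default 0.5.
#' @param p_cut p cut; default 0.05.
#' @return data.frame of edges: `lncRNA`, `mRNA`, `pcc`, `p` (plus any
#'   input columns).
#' @export
coexpression_screen <- function(pairs, lnc_expr, mrna_expr,
                                pcc_cut = 0.5, p_cut = 0.05) {
  shared <- intersect(colnames(lnc_expr), colnames(mrna_expr))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  ok <- pairs$lncRNA %in% rownames(lnc_expr) &
    pairs$mRNA %in% rownames(mrna_expr)
  if (any(!ok))
    warning(sum(!ok), " pair(s) with missing expression skipped")
  pr <- pairs[ok, , drop = FALSE]
  if (!nrow(pr)) {
    pr$pcc <- numeric(0); pr$p <- numeric(0)
    return(pr)
  }
  cc <- paired_row_cor(lnc_expr[pr$lncRNA, shared, drop = FALSE],
                       mrna_expr[pr$mRNA, shared, drop = FALSE])
  if (anyNA(cc$r))
    warning(sum(is.na(cc$r)), " pair(s) with constant expression skipped")
  keep <- !is.na(cc$r) & cc$r > pcc_cut & cc$p <= p_cut
  pr$pcc <- cc$r
  pr$p <- cc$p
  out <- pr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

emtrn_network <- function(edges, node_type, hub_top_frac = 0.15) {
  ids <- unique(c(edges$lncRNA, edges$mRNA))
  deg <- table(factor(c(edges$lncRNA, edges$mRNA), levels = ids))
  nodes <- data.frame(id = ids,
                      type = unname(node_type[ids]),
                      degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  nodes$hub <- rep(FALSE, nrow(nodes))
  if (nrow(nodes)) {
    n_hub <- max(1L, ceiling(hub_top_frac * nrow(nodes)))
    thr <- sort(nodes$degree, decreasing = TRUE)[n_hub]
    nodes$hub <- nodes$degree >= thr
  }
  structure(list(nodes = nodes, edges = edges), class = "emtrn_network")
}

#' @export
print.emtrn_network <- function(x, ...) {
  cat("emtrn network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "lncRNA"), "lncRNA /",
      sum(x$nodes$type == "mRNA"), "mRNA ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Assemble the EMTRN and its direction-specific subnetworks
#'
#' Each node inherits the methylation direction(s) of the DMERs it is
#' linked to (`hyper`, `hypo`, or `mixed` when linked to both); an edge
#' belongs to the hypo subnetwork when both endpoints are hypo-associated,
#' to the hyper subnetwork when both are hyper-associated, and is labelled
#' `mixed` (full network only) otherwise. Node degree is computed per
#' network and nodes in the top `hub_top_frac` of degree are flagged as
#' hubs.
#'
#' @param edges screened edge table from [coexpression_screen()].
#' @param dmer_lnc_pairs,dmer_mrna_pairs screened DMER-gene pair tables
#'   carrying `gene_id` and `direction`.
#' @param hub_top_frac fraction of top-degree nodes flagged as hubs;
#'   default 0.15.
#' @return list with elements `full`, `hyper`, `hypo`, each an
#'   `emtrn_network` (list of `nodes` and `edges` data.frames); the full
#'   network's edges carry an `edge_direction` column.
#' @export
assemble_emtrn <- function(edges, dmer_lnc_pairs, dmer_mrna_pairs,
                           hub_top_frac = 0.15) {
  gene_dir <- function(pairs) {
    tapply(pairs$direction, pairs$gene_id, function(d) {
      u <- unique(d)
      if (length(u) == 1L) u else "mixed"
    })
  }
  dirs <- c(gene_dir(dmer_lnc_pairs), gene_dir(dmer_mrna_pairs))
  node_type <- c(setNames(rep("lncRNA", length(unique(edges$lncRNA))),
                          unique(edges$lncRNA)),
                 setNames(rep("mRNA", length(unique(edges$mRNA))),
                          unique(edges$mRNA)))
  if (nrow(edges)) {
    dl <- dirs[edges$lncRNA]
    dm <- dirs[edges$mRNA]
    if (anyNA(dl) || anyNA(dm))
      stop("edge endpoint without an associated DMER direction")
    edge_dir <- ifelse(dl == "hypo" & dm == "hypo", "hypo",
                       ifelse(dl == "hyper" & dm == "hyper", "hyper", "mixed"))
  } else {
    edge_dir <- character(0)
  }
  full_edges <- edges
  full_edges$edge_direction <- edge_dir
  full <- emtrn_network(full_edges, node_type, hub_top_frac)
  full$nodes$direction <- unname(dirs[full$nodes$id])
  hypo <- emtrn_network(edges[edge_dir == "hypo", , drop = FALSE],
                        node_type, hub_top_frac)
  hyper <- emtrn_network(edges[edge_dir == "hyper", , drop = FALSE],
                         node_type, hub_top_frac)
  list(full = full, hyper = hyper, hypo = hypo)
}
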