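# Biomarker evaluation (ROC AUC, tumour/normal expression comparison),
# generic gene-set over-representation, drug-lncRNA network assembly.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC is computed as the probability that a randomly chosen tumour sample
#' scores higher than a randomly chosen normal sample, ties counting one
#' half: via mid-ranks, `AUC = (sum of tumour ranks - n1(n1+1)/2) /
#' (n1 * n2)`.
#'
#' @param scores numeric score per sample.
#' @param labels `"tumor"`/`"normal"` per sample.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "tumor"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Module-level and per-gene diagnostic AUCs on a validation matrix
#'
#' The module-level score of a sample is the mean of its member genes'
#' z-scores (each gene standardised across all validation samples); its AUC
#' plus the per-gene AUCs are reported.
#'
#' @param expression validation matrix (genes x samples).
#' @param labels `"tumor"`/`"normal"` per column.
#' @param genes character vector of module gene ids.
#' @return list with `module_auc`, `gene_auc` (named numeric), and
#'   `missing` (genes absent from the matrix).
#' @export
module_auc <- function(expression, labels, genes) {
  present <- intersect(genes, rownames(expression))
  missing <- setdiff(genes, present)
  if (!length(present)) stop("no module gene present in the matrix")
  x <- expression[present, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1L, sd)
  score <- colMeans(z)
  list(module_auc = compute_auc(score, labels),
       gene_auc = setNames(
         vapply(present, function(g) compute_auc(x[g, ], labels), 0),
         present),
       missing = missing)
}

#' Tumour/normal expression comparison for a gene set
#'
#' Per gene: group medians, a two-sided Wilcoxon rank-sum test (exact when
#' the sample sizes permit and there are no ties), BH adjustment across the
#' queried genes, and a direction flag.
#'
#' @param expression validation matrix (genes x samples).
#' @param labels `"tumor"`/`"normal"` per column.
#' @param genes gene ids to compare.
#' @return data.frame: `gene_id`, `median_tumor`, `median_normal`, `p`,
#'   `adj_p`, `direction` (`up_in_tumor`/`down_in_tumor`/`none`), `tie`
#'   flag; genes absent from the matrix are reported with `missing = TRUE`.
#' @export
expression_group_stats <- function(expression, labels, genes) {
  pos <- labels == "tumor"
  if (sum(pos) < 2L || sum(!pos) < 2L) stop("need >= 2 samples per group")
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(expression))
      return(data.frame(gene_id = g, median_tumor = NA_real_,
                        median_normal = NA_real_, p = NA_real_,
                        direction = NA_character_, tie = NA,
                        missing = TRUE, stringsAsFactors = FALSE))
    xt <- expression[g, pos]; xn <- expression[g, !pos]
    if (length(unique(c(xt, xn))) == 1L) {
      p <- 1; tie <- TRUE
    } else {
      wt <- suppressWarnings(wilcox.test(xt, xn, alternative = "two.sided"))
      p <- wt$p.value; tie <- FALSE
    }
    mt <- median(xt); mn <- median(xn)
    dir <- if (mt > mn) "up_in_tumor" else if (mt < mn) "down_in_tumor" else "none"
    data.frame(gene_id = g, median_tumor = mt, median_normal = mn,
               p = p, direction = dir, tie = tie, missing = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  out$adj_p[!out$missing] <- p.adjust(out$p[!out$missing], "BH")
  out[, c("gene_id", "median_tumor", "median_normal", "p", "adj_p",
          "direction", "tie", "missing")]
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' For each set in the collection, the overlap with the query is tested
#' against the upper hypergeometric tail `P(X >= overlap)` with the
#' collection's universe as population. The query is first harmonised to
#' the universe; p-values are BH-adjusted across sets.
#'
#' @param query character vector of gene ids.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible gene ids; defaults to
#'   the union of the sets.
#' @param p_cut significance cut; default 0.01.
#' @return data.frame: `set`, `set_size`, `query_size`, `overlap`, `p`,
#'   `fdr`, `significant`.
#' @export
gene_set_ora <- function(query, sets, universe = NULL, p_cut = 0.01) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  sets <- lapply(sets, intersect, universe)
  query <- unique(intersect(query, universe))
  if (!length(query)) stop("empty query after harmonisation to the universe")
  N <- length(universe)
  q <- length(query)
  m <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
  out <- data.frame(set = names(sets), set_size = as.integer(m),
                    query_size = q, overlap = as.integer(k),
                    p = unname(p), fdr = unname(p.adjust(p, "BH")),
                    stringsAsFactors = FALSE)
  out$significant <- out$p <= p_cut
  rownames(out) <- NULL
  out[order(out$p, out$set), ]
}

#' Drug-lncRNA target network from the hypomethylation subnetwork
#'
#' Keeps drug associations that downregulate a lncRNA present in the
#' hypo-methylation regulatory network (those lncRNAs are the candidates
#' whose overexpression is driven by enhancer hypomethylation, so a
#' downregulating drug is a candidate therapeutic), de-duplicated.
#'
#' @param drugs data.frame with columns `drug`, `lncRNA`, `direction`
#'   (`down`/`up`).
#' @param hypo_network `emtrn_network` (the `hypo` element of
#'   [assemble_emtrn()]'s output).
#' @return `emtrn_network` whose edges are `drug`-`lncRNA` pairs and whose
#'   node types are `drug`/`lncRNA`.
#' @export
build_drug_network <- function(drugs, hypo_network) {
  stopifnot(all(c("drug", "lncRNA", "direction") %in% names(drugs)))
  lncs <- hypo_network$nodes$id[hypo_network$nodes$type == "lncRNA"]
  keep <- drugs$direction == "down" & drugs$lncRNA %in% lncs
  e <- unique(drugs[keep, c("drug", "lncRNA"), drop = FALSE])
  rownames(e) <- NULL
  ids <- unique(c(e$drug, e$lncRNA))
  nodes <- data.frame(id = ids,
                      type = ifelse(ids %in% e$drug, "drug", "lncRNA"),
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(e$drug, e$lncRNA), levels = ids))
  nodes$degree <- as.integer(deg)
  nodes$hub <- FALSE
  structure(list(nodes = nodes, edges = e), class = "emtrn_network")
}
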