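# Maximal biclique enumeration on a bipartite lncRNA-mRNA graph.
#
# Maximal bicliques of a bipartite graph correspond one-to-one to the
# "closed" lncRNA subsets X: with Y the common neighbourhood of X and X'
# the common neighbourhood of Y, X is closed iff X' = X. The close-by-one
# scheme below enumerates every closed set exactly once by extending the
# current closed set with one lncRNA at a time and discarding extensions
# whose closure adds a lncRNA with a smaller index than the generator
# (canonicity test).

#' Enumerate maximal bicliques of a bipartite lncRNA-mRNA network
#'
#' Finds every maximal complete-bipartite subgraph (biclique) whose lncRNA
#' side has at least `min_lnc` members and whose mRNA side has at least
#' `min_mrna` members. A biclique is maximal when no further lncRNA or mRNA
#' is connected to all vertices of the opposite side.
#'
#' @param edges data.frame with columns `lncRNA` and `mRNA`; the two id
#'   sets must be disjoint (a shared id means a non-bipartite input and is
#'   an error).
#' @param min_lnc,min_mrna minimum side sizes; default 2 each.
#' @return data.frame with one row per module, ordered lexicographically by
#'   member ids: `module_id`, list columns `lncRNAs` and `mRNAs` (sorted
#'   character vectors), `n_lnc`, `n_mrna`.
#' @export
enumerate_maximal_bicliques <- function(edges, min_lnc = 2L, min_mrna = 2L) {
  stopifnot(all(c("lncRNA", "mRNA") %in% names(edges)))
  L <- sort(unique(as.character(edges$lncRNA)))
  R <- sort(unique(as.character(edges$mRNA)))
  both <- intersect(L, R)
  if (length(both))
    stop("input is not bipartite: id(s) on both sides: ",
         paste(head(both, 5L), collapse = ", "))
  empty <- data.frame(module_id = character(), n_lnc = integer(),
                      n_mrna = integer(), stringsAsFactors = FALSE)
  empty$lncRNAs <- list(); empty$mRNAs <- list()
  if (!nrow(edges)) return(empty[, c("module_id", "lncRNAs", "mRNAs",
                                     "n_lnc", "n_mrna")])
  nL <- length(L); nR <- length(R)
  B <- matrix(FALSE, nL, nR)
  B[cbind(match(edges$lncRNA, L), match(edges$mRNA, R))] <- TRUE
  rs <- rowSums(B)
  res_l <- list(); res_r <- list(); nres <- 0L
  closure <- function(y) which(rowSums(B[, y, drop = FALSE]) == length(y))
  recurse <- function(x, y, last) {
    if (length(x) >= min_lnc && length(y) >= min_mrna) {
      nres <<- nres + 1L
      res_l[[nres]] <<- x
      res_r[[nres]] <<- y
    }
    for (j in seq_len(nL)) {
      if (j <= last || j %in% x) next
      ynew <- y[B[j, y]]
      if (length(ynew) < min_mrna) next   # Y only shrinks below this node
      xnew <- closure(ynew)
      if (any(xnew < j & !(xnew %in% x))) next   # canonicity
      recurse(xnew, ynew, j)
    }
  }
  x0 <- which(rs == nR)                  # closure of the empty lncRNA set
  recurse(x0, seq_len(nR), 0L)
  if (!nres) return(empty[, c("module_id", "lncRNAs", "mRNAs",
                              "n_lnc", "n_mrna")])
  lnc_sets <- lapply(res_l, function(i) L[i])
  mrna_sets <- lapply(res_r, function(i) R[i])
  key <- vapply(seq_len(nres), function(i)
    paste(paste(lnc_sets[[i]], collapse = ","),
          paste(mrna_sets[[i]], collapse = ","), sep = "|"), "")
  ord <- order(key)
  out <- data.frame(module_id = sprintf("MOD_%04d", seq_len(nres)),
                    n_lnc = lengths(lnc_sets)[ord],
                    n_mrna = lengths(mrna_sets)[ord],
                    stringsAsFactors = FALSE)
  out$lncRNAs <- lnc_sets[ord]
  out$mRNAs <- mrna_sets[ord]
  out[, c("module_id", "lncRNAs", "mRNAs", "n_lnc", "n_mrna")]
}

#' Verify that a module is a complete and maximal biclique
#'
#' Independent post-hoc check used by the screening pipeline and the test
#' suite: confirms every cross pair is an edge (completeness) and that no
#' outside vertex is connected to the whole opposite side (maximality).
#'
#' @param module one row of the [enumerate_maximal_bicliques()] output (or
#'   a list with `lncRNAs`, `mRNAs`).
#' @param edges the bipartite edge table the module was mined from.
#' @return TRUE, or a character string describing the violation.
#' @export
check_biclique <- function(module, edges) {
  ls <- module$lncRNAs[[1L]]; rs <- module$mRNAs[[1L]]
  ekey <- paste(edges$lncRNA, edges$mRNA)
  want <- as.vector(outer(ls, rs, paste))
  if (!all(want %in% ekey)) return("incomplete: missing cross edge")
  for (l in setdiff(unique(edges$lncRNA), ls))
    if (all(paste(l, rs) %in% ekey)) return(paste("not maximal: can add", l))
  for (r in setdiff(unique(edges$mRNA), rs))
    if (all(paste(ls, r) %in% ekey)) return(paste("not maximal: can add", r))
  TRUE
}
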