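# Independent oracles and fixture builders shared across the suite.
# Every oracle is written from the definition of the quantity, independent
# of the implementation path it checks.

# --- interval merging: per-base bitmap -------------------------------------
# paints each half-open probe window onto a bitmap at half-base resolution
# (odd cells carry bases, even cells carry the fences between bases) and
# reads off the painted runs: windows that merely touch leave their shared
# fence unpainted and stay separate, overlapping windows share base cells
# and merge (0-based half-open output)
oracle_regions_bitmap <- function(manifest, half_width = 500L) {
  m <- manifest[manifest$is_enhancer, , drop = FALSE]
  out <- list()
  for (ch in sort(unique(m$chrom))) {
    pos0 <- m$position[m$chrom == ch] - 1L
    lo <- max(0L, min(pos0) - half_width)
    hi <- max(pos0) + half_width
    bits <- logical(2L * (hi - lo))
    for (p in pos0) {
      s <- max(0L, p - half_width) - lo
      e <- p + half_width - lo
      bits[(2L * s + 1L):(2L * e - 1L)] <- TRUE
    }
    r <- rle(bits)
    cend <- cumsum(r$lengths)
    cstart <- cend - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch,
                              start = (cstart[keep] - 1L) %/% 2L + lo,
                              end = (cend[keep] + 1L) %/% 2L + lo,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

random_manifest <- function(n_probes, n_chrom = 3L, span = 20000L) {
  data.frame(probe_id = sprintf("P%04d", seq_len(n_probes)),
             chrom = sample(paste0("chr", seq_len(n_chrom)), n_probes,
                            replace = TRUE),
             position = sample.int(span, n_probes, replace = TRUE) + 600L,
             is_enhancer = TRUE, stringsAsFactors = FALSE)
}

# --- hypergeometric upper tail by combinatorial enumeration ----------------
# P(X >= k) for X ~ Hypergeometric(N, K, n), summing the counting formula
# term by term
oracle_hyper_upper <- function(N, K, n, k) {
  js <- seq(max(k, 0L, K + n - N), min(K, n))
  if (!length(js) || k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# --- Benjamini-Hochberg step-up by the definition --------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# --- pooled two-sample t from the textbook formula -------------------------
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# --- maximal bicliques by brute force over all vertex-subset pairs ---------
oracle_bicliques_brute <- function(edges, min_l = 2L, min_r = 2L) {
  L <- sort(unique(edges$lncRNA)); R <- sort(unique(edges$mRNA))
  has <- outer(L, R, function(a, b) paste(a, b) %in% paste(edges$lncRNA, edges$mRNA))
  subsets <- function(n) lapply(seq_len(2^n) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L))
  res <- list()
  for (ls in subsets(length(L))) {
    if (length(ls) < min_l) next
    for (rs in subsets(length(R))) {
      if (length(rs) < min_r) next
      if (!all(has[ls, rs])) next
      # maximal: no vertex outside connected to the whole opposite side
      ext_l <- any(vapply(setdiff(seq_along(L), ls),
                          function(l) all(has[l, rs]), TRUE))
      ext_r <- any(vapply(setdiff(seq_along(R), rs),
                          function(r) all(has[ls, r]), TRUE))
      if (ext_l || ext_r) next
      res[[length(res) + 1L]] <- list(lncRNAs = L[ls], mRNAs = R[rs])
    }
  }
  res
}

biclique_keys <- function(lnc_sets, mrna_sets) {
  sort(vapply(seq_along(lnc_sets), function(i)
    paste(paste(sort(lnc_sets[[i]]), collapse = ","),
          paste(sort(mrna_sets[[i]]), collapse = ","), sep = "|"), ""))
}

random_bipartite <- function(nl, nr, density) {
  L <- sprintf("l%d", seq_len(nl)); R <- sprintf("m%d", seq_len(nr))
  all <- expand.grid(lncRNA = L, mRNA = R, stringsAsFactors = FALSE)
  all[runif(nrow(all)) < density, , drop = FALSE]
}

# --- Cox partial log-likelihood (Breslow ties), written from scratch -------
oracle_cox_loglik <- function(beta, time, event, x) {
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    dead <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5) {
  optimize(function(b) oracle_cox_loglik(b, time, event, cbind(x)),
           c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

oracle_cox_score <- function(beta, time, event, x) {
  # numeric gradient of the hand-written partial log-likelihood
  eps <- 1e-6
  vapply(seq_along(beta), function(j) {
    bp <- bm <- beta
    bp[j] <- bp[j] + eps; bm[j] <- bm[j] - eps
    (oracle_cox_loglik(bp, time, event, x) -
       oracle_cox_loglik(bm, time, event, x)) / (2 * eps)
  }, 0)
}

# --- two-group log-rank by summing O - E and the hypergeometric variance ---
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- sort(unique(group))[1L]
  OA <- 0; EA <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    OA <- OA + d1
    EA <- EA + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (OA - EA)^2 / V
}

# --- AUC by explicit pair counting -----------------------------------------
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels == "tumor"]; sn <- scores[labels == "normal"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- edge tables realising a lncRNA with K partners and an mRNA with n
# partners sharing exactly k miRNAs inside a universe of N (a dummy hub
# lncRNA pins the universe without affecting the tested pair) ---------------
mk_cerna_tables <- function(N, K, n, k) {
  mi <- sprintf("mi%02d", seq_len(N))
  lnc <- data.frame(lncRNA = "L1", miRNA = mi[seq_len(K)],
                    stringsAsFactors = FALSE)
  mr <- data.frame(miRNA = mi[c(seq_len(k), K + seq_len(n - k))],
                   mRNA = "M1", stringsAsFactors = FALSE)
  hub <- data.frame(lncRNA = "HUB", miRNA = mi, stringsAsFactors = FALSE)
  list(lnc = rbind(lnc, hub), mr = mr)
}

# --- small, fast synthetic study for property tests ------------------------
small_sim_params <- function(...) {
  emtrn_sim_params(
    n_chrom = 2L, chrom_length = 1.2e7,
    n_background_probes = 300L,
    n_lncRNA = 30L, n_mRNA = 60L, n_miRNA = 60L,
    n_tumor = 24L, n_normal = 12L,
    n_val_tumor = 16L, n_val_normal = 8L,
    ...)
}
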