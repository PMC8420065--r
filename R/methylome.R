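# Probe QC, imputation, enhancer-region / promoter construction and
# moderated differential methylation testing.

#' Remove probes with excessive missingness
#'
#' Probes whose fraction of missing samples is strictly greater than
#' `max_fraction` are removed (a probe missing in exactly 30% of samples is
#' retained at the default cut).
#'
#' @param values numeric matrix, probes x samples, `NA` = missing.
#' @param max_fraction maximum tolerated missing fraction; default 0.30.
#' @return the filtered matrix, with attribute `removed` holding the removed
#'   probe ids and their missing fractions.
#' @export
filter_probes_by_missingness <- function(values, max_fraction = 0.30) {
  stopifnot(is.matrix(values), ncol(values) >= 1L)
  frac <- rowMeans(is.na(values))
  drop <- frac > max_fraction
  if (all(drop)) warning("all probes removed by missingness filter")
  out <- values[!drop, , drop = FALSE]
  attr(out, "removed") <- data.frame(probe_id = rownames(values)[drop],
                                     missing_fraction = frac[drop],
                                     row.names = NULL,
                                     stringsAsFactors = FALSE)
  out
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' For each missing cell, the k probes (rows) nearest to the target probe
#' are found among the probes that observe that sample, using Euclidean
#' distance over the columns observed in both rows scaled by the number of
#' shared columns (i.e. root mean squared difference); the missing value is
#' the unweighted mean of those neighbours' values in that sample, clipped
#' to \[0, 1\]. Observed cells are never changed. If no other probe shares
#' any observed column with the target, the probe's own observed mean is
#' used and a warning is raised.
#'
#' @param values numeric matrix, probes x samples, `NA` = missing; every
#'   probe must retain at least one observed value.
#' @param k number of neighbours; default 10.
#' @return the completed matrix.
#' @export
knn_impute <- function(values, k = 10L) {
  stopifnot(is.matrix(values), k >= 1L)
  if (!anyNA(values)) return(values)
  if (any(rowSums(!is.na(values)) == 0L))
    stop("probes with no observed value cannot be imputed; filter them first")
  obs <- !is.na(values)
  x0 <- values
  x0[!obs] <- 0
  w <- obs * 1
  # pairwise mean squared difference over shared observed columns
  shared <- tcrossprod(w)
  s1 <- tcrossprod(x0^2, w)
  cross <- tcrossprod(x0)
  d2 <- (s1 + t(s1) - 2 * cross) / shared   # NaN where shared == 0
  diag(d2) <- Inf
  out <- values
  fallback <- character(0)
  for (i in which(rowSums(!obs) > 0L)) {
    di <- d2[i, ]
    for (jc in which(!obs[i, ])) {
      cand <- which(obs[, jc] & is.finite(di))
      if (!length(cand)) {
        out[i, jc] <- mean(values[i, ], na.rm = TRUE)
        fallback <- c(fallback, rownames(values)[i])
        next
      }
      nb <- cand[order(di[cand])][seq_len(min(k, length(cand)))]
      out[i, jc] <- mean(values[nb, jc])
    }
  }
  if (length(fallback))
    warning("no neighbour shared an observed column for probe(s) ",
            paste(unique(fallback), collapse = ", "),
            "; probe-wise mean used")
  out[] <- pmin(pmax(out, 0), 1)
  out[obs] <- values[obs]
  out
}

#' Construct enhancer regions from enhancer probes
#'
#' Each enhancer probe contributes a window of `half_width` bp directly
#' upstream and downstream of its CpG coordinate, i.e. the 0-based
#' half-open interval `[pos - half_width, pos + half_width)`. Windows on
#' the same chromosome whose intersection is non-empty are merged
#' transitively into larger intervals; windows that merely touch
#' (bookended) are kept separate, which preserves the dominant
#' `2 * half_width` region-length class. Region ids are assigned in
#' (chrom, start) order and every probe belongs to exactly one region.
#'
#' @param manifest probe manifest data.frame (see
#'   [read_probe_manifest()]); only rows with `is_enhancer == TRUE` are
#'   used.
#' @param half_width window half-width in bp; default 500.
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `center` (floor of the interval midpoint),
#'   `n_probes`, and a list column `probe_ids`.
#' @export
build_enhancer_regions <- function(manifest, half_width = 500L) {
  m <- manifest[manifest$is_enhancer, , drop = FALSE]
  if (!nrow(m)) stop("no enhancer probes in manifest")
  pos0 <- m$position - 1L              # 0-based CpG coordinate
  start <- pos0 - half_width
  if (any(start < 0L)) {
    warning(sum(start < 0L), " window(s) clipped at position 0")
    start <- pmax(start, 0L)
  }
  end <- pos0 + half_width
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))  # 1-based closed
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- red[order(as.character(GenomicRanges::seqnames(red)),
                   GenomicRanges::start(red))]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(m$chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L)),
    red)
  stopifnot(length(hits) == nrow(m))   # every probe in exactly one region
  rid <- sprintf("ENH_%06d", seq_along(red))
  s0 <- GenomicRanges::start(red) - 1L
  e0 <- GenomicRanges::end(red)
  probe_ids <- split(m$probe_id, rid[S4Vectors::subjectHits(hits)])
  out <- data.frame(region_id = rid,
                    chrom = as.character(GenomicRanges::seqnames(red)),
                    start = s0, end = e0,
                    center = (s0 + e0) %/% 2L,
                    stringsAsFactors = FALSE)
  out$probe_ids <- unname(probe_ids[out$region_id])
  out$n_probes <- lengths(out$probe_ids)
  out
}

#' Average probe methylation within enhancer regions
#'
#' @param values complete (post-imputation) probe-level beta matrix.
#' @param regions region table from [build_enhancer_regions()].
#' @return region-level beta matrix (regions x samples); a region's value
#'   is the arithmetic mean of its member probes. Regions with no member
#'   probe present in `values` are absent from the output.
#' @export
summarize_region_methylation <- function(values, regions) {
  unknown <- setdiff(unlist(regions$probe_ids), rownames(values))
  if (length(unknown))
    stop("region member probe(s) absent from matrix: ",
         paste(head(unknown, 5L), collapse = ", "))
  keep <- regions$n_probes > 0L
  out <- rowsum_means(values, regions$probe_ids[keep])
  rownames(out) <- regions$region_id[keep]
  out
}

# mean of member rows per group; returns length(groups) x ncol(values)
rowsum_means <- function(values, groups) {
  out <- matrix(NA_real_, length(groups), ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (i in seq_along(groups))
    out[i, ] <- colMeans(values[groups[[i]], , drop = FALSE])
  out
}

#' Map non-enhancer probes to gene promoters
#'
#' The promoter is the strand-aware stretch of `upstream` bp ending at the
#' TSS: for a `+` strand gene the 0-based half-open interval
#' `[tss0 - upstream, tss0)` and for a `-` strand gene `[tss0, tss0 +
#' upstream)`, where `tss0` is the 0-based TSS. Probes flagged as enhancer
#' probes are excluded, as are probes falling into the promoters of two or
#' more genes.
#'
#' @param manifest probe manifest data.frame.
#' @param genes gene model data.frame (see [read_gene_models()]).
#' @param upstream promoter length in bp; default 2000.
#' @return data.frame with columns `gene_id`, `probe_id`.
#' @export
map_promoter_probes <- function(manifest, genes, upstream = 2000L) {
  p <- manifest[!manifest$is_enhancer, , drop = FALSE]
  if (!nrow(p) || !nrow(genes))
    return(data.frame(gene_id = character(), probe_id = character(),
                      stringsAsFactors = FALSE))
  tss0 <- genes$tss - 1L
  pstart <- ifelse(genes$strand == "+", tss0 - upstream, tss0)
  pend <- ifelse(genes$strand == "+", tss0, tss0 + upstream)
  pstart <- pmax(pstart, 0L)
  ok <- pend > pstart
  prom <- GenomicRanges::GRanges(
    genes$chrom[ok], IRanges::IRanges(pstart[ok] + 1L, pend[ok]))
  pg <- GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(p$position, p$position))
  hits <- GenomicRanges::findOverlaps(pg, prom)
  if (!length(hits))
    return(data.frame(gene_id = character(), probe_id = character(),
                      stringsAsFactors = FALSE))
  qh <- S4Vectors::queryHits(hits)
  multi <- unique(qh[duplicated(qh)])     # probes in >= 2 promoters
  keep <- !(qh %in% multi)
  data.frame(gene_id = genes$gene_id[ok][S4Vectors::subjectHits(hits)][keep],
             probe_id = p$probe_id[qh][keep],
             stringsAsFactors = FALSE)
}

#' Average promoter-probe methylation per gene
#'
#' @param values complete probe-level beta matrix.
#' @param mapping data.frame from [map_promoter_probes()].
#' @return gene-level beta matrix; genes with no mapped probe are absent.
#' @export
summarize_promoter_methylation <- function(values, mapping) {
  mapping <- mapping[mapping$probe_id %in% rownames(values), , drop = FALSE]
  if (!nrow(mapping)) stop("no promoter probes present in matrix")
  by_gene <- split(mapping$probe_id, mapping$gene_id)
  out <- rowsum_means(values, by_gene)
  rownames(out) <- names(by_gene)
  out
}

# Newton inversion of the trigamma function (monotone decreasing on (0,
# Inf)); used by the empirical-Bayes variance prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Moderated two-group differential test for methylation features
#'
#' Fits, per feature, the two-group linear model on beta values (the
#' coefficient is the tumour mean minus the normal mean, reported in the
#' `log2fc` column following the linear-model convention on non-logged
#' methylation input) and moderates the pooled residual variance with an
#' empirical-Bayes scaled inverse-chi-square prior: the prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by moment-matching
#' a scaled F distribution to the observed sample variances (Smyth-type
#' closed forms on log variances), and the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)`. The moderated t has `d0 + d` degrees of
#' freedom. p-values are BH-adjusted across all features in the input.
#'
#' @param values feature x sample beta matrix, complete.
#' @param groups character/factor of `"tumor"` / `"normal"` per column (in
#'   column order, or named by column).
#' @param d0_override optionally force the prior degrees of freedom:
#'   `0` reproduces the ordinary pooled two-sample t, `Inf` gives the
#'   fully-shrunk (z-like) statistic.
#' @return data.frame with one row per feature: `feature_id`,
#'   `mean_tumor`, `mean_normal`, `delta_median` (tumour minus normal
#'   medians), `log2fc` (the group-difference coefficient), `t`, `p`,
#'   `adj_p`, `zero_variance` flag. Attributes `d0` and `s0_sq` report the
#'   estimated prior.
#' @export
fit_group_difference <- function(values, groups, d0_override = NULL) {
  stopifnot(is.matrix(values))
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  groups <- as.character(groups)
  if (!all(groups %in% c("tumor", "normal")))
    stop("groups must be 'tumor' or 'normal'")
  if (anyNA(values)) stop("matrix must be complete (impute first)")
  it <- groups == "tumor"; ino <- !it
  n1 <- sum(it); n2 <- sum(ino)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  mt <- rowMeans(values[, it, drop = FALSE])
  mn <- rowMeans(values[, ino, drop = FALSE])
  coef <- mt - mn
  v1 <- apply(values[, it, drop = FALSE], 1L, var)
  v2 <- apply(values[, ino, drop = FALSE], 1L, var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  zerovar <- s2 <= .Machine$double.eps
  # empirical-Bayes prior by moment matching on log sample variances;
  # zero-variance features carry no information about the prior
  est <- s2[!zerovar]
  if (length(est) >= 2L) {
    z <- log(est)
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- mean((e - emean)^2) * length(e) / (length(e) - 1L)
    evar <- evar - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    d0 <- 0
    s0_sq <- NA_real_
  }
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (d0 == 0) s0_sq <- 0
    stopifnot(d0 == 0 || is.finite(s0_sq) || is.infinite(d0))
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, coef / se, NA_real_)
  p <- ifelse(is.na(tstat), 1,
              2 * pt(-abs(tstat), df = df_total))
  # zero variance in both groups: the statistic is undefined
  tstat[zerovar] <- NA_real_
  p[zerovar] <- 1
  dmed <- apply(values[, it, drop = FALSE], 1L, median) -
    apply(values[, ino, drop = FALSE], 1L, median)
  out <- data.frame(feature_id = rownames(values),
                    mean_tumor = mt, mean_normal = mn,
                    delta_median = dmed,
                    log2fc = coef, t = tstat, p = p,
                    adj_p = p.adjust(p, method = "BH"),
                    zero_variance = zerovar,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Call differentially methylated enhancer regions (DMERs)
#'
#' A region is `hyper` if its group-difference coefficient is `>= lfc` with
#' BH-adjusted p `<= adj_p`, `hypo` if the coefficient is `<= -lfc` with
#' adjusted p `<= adj_p`, else `ns`.
#'
#' @param results region-level output of [fit_group_difference()].
#' @param lfc minimum absolute coefficient; default 0.01.
#' @param adj_p adjusted-p cut; default 0.05.
#' @return `results` with a `direction` column.
#' @export
call_dmers <- function(results, lfc = 0.01, adj_p = 0.05) {
  dir <- rep("ns", nrow(results))
  sig <- results$adj_p <= adj_p & !results$zero_variance
  dir[sig & results$log2fc >= lfc] <- "hyper"
  dir[sig & results$log2fc <= -lfc] <- "hypo"
  results$direction <- dir
  results
}

#' Call differential promoter methylation genes (DPMGs)
#'
#' A gene is called when its BH-adjusted p is `<= adj_p` and the absolute
#' tumour-normal median beta difference is `>= delta`; direction follows
#' the sign of the median difference.
#'
#' @param results promoter-gene-level output of [fit_group_difference()].
#' @param delta minimum absolute median difference; default 0.1.
#' @param adj_p adjusted-p cut; default 0.05.
#' @return `results` with a `direction` column (`hyper`/`hypo`/`ns`).
#' @export
call_dpmgs <- function(results, delta = 0.1, adj_p = 0.05) {
  dir <- rep("ns", nrow(results))
  sig <- results$adj_p <= adj_p & abs(results$delta_median) >= delta &
    !results$zero_variance
  dir[sig & results$delta_median > 0] <- "hyper"
  dir[sig & results$delta_median < 0] <- "hypo"
  results$direction <- dir
  results
}
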