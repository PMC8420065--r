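mk <- function(v, ids = NULL, samples = NULL) {
  m <- do.call(rbind, v)
  rownames(m) <- if (is.null(ids)) sprintf("p%d", seq_len(nrow(m))) else ids
  colnames(m) <- if (is.null(samples)) sprintf("s%d", seq_len(ncol(m))) else samples
  m
}

test_that("missingness filter removes strictly above the threshold", {
  m <- mk(list(c(rep(NA, 4), runif(6)),    # 0.40 -> removed
               c(rep(NA, 3), runif(7)),    # 0.30 -> retained (strict)
               runif(10)))
  out <- filter_probes_by_missingness(m, 0.30)
  expect_equal(rownames(out), c("p2", "p3"))
  expect_equal(attr(out, "removed")$probe_id, "p1")
  expect_equal(attr(out, "removed")$missing_fraction, 0.4)

  full <- mk(list(runif(5), runif(5)))
  expect_equal(filter_probes_by_missingness(full), full, ignore_attr = TRUE)
})

test_that("kNN imputation follows the nearest-row contract", {
  m <- mk(list(c(0.1, 0.2, NA), c(0.1, 0.2, 0.3), c(0.9, 0.9, 0.9)),
          ids = c("A", "B", "C"))
  out <- knn_impute(m, k = 1)
  expect_equal(out["A", "s3"], 0.3)          # nearest row is B
  expect_false(anyNA(out))
  expect_equal(out["B", ], m["B", ])         # observed cells unchanged

  # k >= number of other probes: mean over all probes observing the column
  out2 <- knn_impute(m, k = 10)
  expect_equal(out2["A", "s3"], mean(c(0.3, 0.9)))

  comp <- mk(list(runif(4), runif(4)))
  expect_identical(knn_impute(comp, 3), comp)

  # imputed values are clipped into the beta range
  m2 <- mk(list(c(0.0, 0.0, NA), c(0.0, 0.0, 0.0)))
  expect_true(all(knn_impute(m2, 1) >= 0 & knn_impute(m2, 1) <= 1))
})

test_that("enhancer region construction merges overlapping, not bookended, windows", {
  man <- function(pos, chrom = "chr1")
    data.frame(probe_id = sprintf("cg%02d", seq_along(pos)), chrom = chrom,
               position = pos, is_enhancer = TRUE, stringsAsFactors = FALSE)

  r1 <- build_enhancer_regions(man(1000L))  # isolated probe
  expect_equal(r1$start, 499L)              # 0-based: [999-500, 999+500)
  expect_equal(r1$end, 1499L)
  expect_equal(r1$end - r1$start, 1000L)

  r2 <- build_enhancer_regions(man(c(1000L, 1800L)))  # overlapping -> merged
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(499L, 2299L))
  expect_equal(r2$n_probes, 2L)

  r3 <- build_enhancer_regions(man(c(1000L, 2000L)))  # bookended -> separate
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$start, c(499L, 1499L))
  expect_equal(r3$end, c(1499L, 2499L))

  # ids follow (chrom, start) order
  m2 <- rbind(man(5000L, "chr2"), man(100000L, "chr1"))
  m2$probe_id <- c("cgA", "cgB")
  r4 <- build_enhancer_regions(m2)
  expect_equal(r4$chrom, c("chr1", "chr2"))
  expect_equal(r4$region_id, c("ENH_000001", "ENH_000002"))

  expect_warning(build_enhancer_regions(man(100L)), "clipped")
})

test_that("region construction equals the per-base bitmap oracle on random manifests", {
  set.seed(42)
  for (i in 1:150) {
    man <- random_manifest(sample(1:50, 1))
    got <- build_enhancer_regions(man)
    want <- oracle_regions_bitmap(man)
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
    # conservation + disjointness
    expect_equal(sum(got$n_probes), sum(man$is_enhancer))
    for (ch in unique(got$chrom)) {
      g <- got[got$chrom == ch, ]
      if (nrow(g) > 1)
        expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
  # idempotent / order-invariant
  man <- random_manifest(30)
  shuf <- man[sample(nrow(man)), ]
  expect_equal(build_enhancer_regions(man)[, c("chrom", "start", "end")],
               build_enhancer_regions(shuf)[, c("chrom", "start", "end")])
})

test_that("region methylation is the member-probe mean", {
  man <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                    position = c(1000L, 1400L), is_enhancer = TRUE,
                    stringsAsFactors = FALSE)
  reg <- build_enhancer_regions(man)
  vals <- mk(list(c(0.2, 0.5), c(0.4, 0.7)), ids = c("a", "b"))
  out <- summarize_region_methylation(vals, reg)
  expect_equal(unname(out[1, ]), c(0.3, 0.6))

  # single-probe region: identity; probe order: symmetric
  reg1 <- build_enhancer_regions(man[1, ])
  expect_equal(unname(summarize_region_methylation(vals, reg1)[1, ]),
               unname(vals["a", ]))
  reg$probe_ids <- list(c("b", "a"))
  expect_equal(summarize_region_methylation(vals, reg), out)

  reg$probe_ids <- list(c("a", "zz"))
  expect_error(summarize_region_methylation(vals, reg), "zz")
})

test_that("promoter mapping is strand-aware and applies both exclusions", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      gene_type = c("mRNA", "mRNA", "lncRNA"),
                      chrom = "chr1", strand = c("+", "+", "-"),
                      tss = c(10000L, 10400L, 50000L),
                      stringsAsFactors = FALSE)
  man <- data.frame(
    probe_id = c("in_plus", "enh_in_prom", "multi", "in_minus", "outside"),
    chrom = "chr1",
    position = c(9500L,      9600L,        9900L,   51000L,     30000L),
    is_enhancer = c(FALSE,   TRUE,         FALSE,   FALSE,      FALSE),
    stringsAsFactors = FALSE)
  mp <- map_promoter_probes(man, genes)
  # in_plus (9500) is upstream of G1 only (G2 promoter starts at 8400 too —
  # both promoters overlap 9500? G2 promoter is [8399,10399): contains 9499);
  # so in_plus maps to two genes and is excluded; multi likewise.
  expect_false("enh_in_prom" %in% mp$probe_id)   # enhancer probes ignored
  expect_true("in_minus" %in% mp$probe_id)       # - strand: [tss0, tss0+2000)
  expect_equal(mp$gene_id[mp$probe_id == "in_minus"], "G3")
  expect_false("outside" %in% mp$probe_id)
  expect_false("multi" %in% mp$probe_id)         # in both G1 and G2 promoters

  # with the second gene far away, in_plus maps uniquely to G1
  genes2 <- genes; genes2$tss[2] <- 200000L
  mp2 <- map_promoter_probes(man, genes2)
  expect_equal(mp2$gene_id[mp2$probe_id == "in_plus"], "G1")
})

test_that("promoter methylation averages mapped probes per gene", {
  vals <- mk(list(c(0.1, 0.5), c(0.3, 0.7), c(0.9, 0.9)),
             ids = c("pa", "pb", "pc"))
  mapping <- data.frame(gene_id = c("G1", "G1", "G2"),
                        probe_id = c("pa", "pb", "pc"),
                        stringsAsFactors = FALSE)
  out <- summarize_promoter_methylation(vals, mapping)
  expect_equal(unname(out["G1", ]), c(0.2, 0.6))
  expect_equal(unname(out["G2", ]), unname(vals["pc", ]))  # single probe
  expect_false("G3" %in% rownames(out))                    # unmapped absent
})

test_that("moderated test: limits, equal means, zero variance, BH", {
  set.seed(3)
  n1 <- 10; n2 <- 8
  vals <- matrix(runif(50 * (n1 + n2), 0.3, 0.7), 50)
  rownames(vals) <- sprintf("f%02d", 1:50)
  colnames(vals) <- c(sprintf("t%02d", 1:n1), sprintf("n%02d", 1:n2))
  groups <- setNames(c(rep("tumor", n1), rep("normal", n2)), colnames(vals))

  # d0 -> 0 recovers the ordinary pooled two-sample t
  r0 <- fit_group_difference(vals, groups, d0_override = 0)
  want <- apply(vals, 1, function(x) oracle_pooled_t(x[1:n1], x[n1 + 1:n2]))
  expect_lt(max(abs(r0$t - want)), 1e-10)

  # d0 -> Inf shrinks every variance to the prior (z-like statistic)
  rI <- fit_group_difference(vals, groups, d0_override = Inf)
  expect_true(all(is.finite(rI$t)))
  se <- sqrt(attr(rI, "s0_sq") * (1 / n1 + 1 / n2))
  expect_equal(rI$t, rI$log2fc / se, tolerance = 1e-12)

  # identical group means -> coef 0, t 0, p 1
  vals2 <- vals
  vals2[1, ] <- c(0.2, 0.4, rep(0.3, n1 - 2), 0.2, 0.4, rep(0.3, n2 - 2))
  r2 <- fit_group_difference(vals2, groups)
  expect_equal(r2$log2fc[1], 0)
  expect_equal(r2$t[1], 0)
  expect_equal(r2$p[1], 1)

  # zero variance in both groups -> flagged, p = 1
  vals3 <- vals; vals3[2, ] <- 0.5
  r3 <- fit_group_difference(vals3, groups)
  expect_true(r3$zero_variance[2])
  expect_equal(r3$p[2], 1)
  expect_true(is.na(r3$t[2]))

  # BH matches the step-up definition
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(9)
  p <- runif(40)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  expect_equal(r0$adj_p, oracle_bh(r0$p))
})

test_that("moderated test agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(11)
  sds <- sqrt(0.01 * stats::rf(300, 8, 8))
  vals <- t(sapply(sds, function(s) rnorm(20, 0.5, s)))
  dimnames(vals) <- list(sprintf("f%03d", 1:300),
                         c(sprintf("t%02d", 1:10), sprintf("n%02d", 1:10)))
  groups <- setNames(rep(c("tumor", "normal"), each = 10), colnames(vals))
  res <- fit_group_difference(vals, groups)
  fit <- limma::eBayes(limma::lmFit(vals, cbind(1, groups == "tumor")))
  expect_equal(attr(res, "d0"), unname(fit$df.prior), tolerance = 1e-8)
  expect_equal(attr(res, "s0_sq"), unname(fit$s2.prior), tolerance = 1e-8)
  expect_lt(max(abs(res$t - fit$t[, 2])), 1e-10)
})

test_that("DMER and DPMG calls apply effect-size and significance gates", {
  res <- data.frame(feature_id = c("r1", "r2", "r3", "r4"),
                    delta_median = c(0.15, 0.05, -0.30, 0.2),
                    log2fc = c(0.05, 0.005, -0.20, 0.2),
                    adj_p = c(0.01, 0.001, 0.04, 0.2),
                    zero_variance = FALSE, stringsAsFactors = FALSE)
  dm <- call_dmers(res)
  expect_equal(dm$direction, c("hyper", "ns", "hypo", "ns"))

  dp <- call_dpmgs(res)
  expect_equal(dp$direction, c("hyper", "ns", "hypo", "ns"))
  # effect-size gate alone is not enough
  expect_equal(call_dpmgs(data.frame(feature_id = "x", delta_median = 0.05,
                                     log2fc = 0.05, adj_p = 1e-4,
                                     zero_variance = FALSE))$direction, "ns")
})
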