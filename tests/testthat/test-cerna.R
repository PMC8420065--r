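test_that("shared-miRNA hypergeometric p matches the worked example", {
  tb <- mk_cerna_tables(N = 10, K = 4, n = 5, k = 3)
  got <- shared_mirna_significance(tb$lnc, tb$mr, min_shared = 2,
                                   fdr_cut = 1)
  row <- got[got$lncRNA == "L1" & got$mRNA == "M1", ]
  expect_equal(row$n_shared, 3L)
  expect_equal(row$p, 66 / 252, tolerance = 1e-12)

  # saturated universe: K = N -> p = 1
  tb2 <- mk_cerna_tables(N = 6, K = 6, n = 4, k = 4)
  got2 <- shared_mirna_significance(tb2$lnc[tb2$lnc$lncRNA == "L1", ],
                                    tb2$mr, min_shared = 2, fdr_cut = 1)
  expect_equal(got2$p[got2$lncRNA == "L1"], 1)

  # a single shared miRNA is below the default testing floor
  tb3 <- mk_cerna_tables(N = 10, K = 4, n = 5, k = 1)
  got3 <- shared_mirna_significance(tb3$lnc, tb3$mr, fdr_cut = 1)
  expect_false(any(got3$lncRNA == "L1" & got3$mRNA == "M1"))

  expect_warning(
    shared_mirna_significance(tb3$lnc[0, ], tb3$mr), "empty")
})

test_that("hypergeometric p matches exhaustive enumeration on a dense grid", {
  for (N in c(5L, 8L, 12L)) {
    for (K in 1:N) for (n in 1:N) {
      for (k in seq(max(1L, K + n - N), min(K, n))) {
        tb <- mk_cerna_tables(N, K, n, k)
        got <- shared_mirna_significance(tb$lnc, tb$mr, min_shared = k,
                                         fdr_cut = 1)
        row <- got[got$lncRNA == "L1" & got$mRNA == "M1", ]
        expect_equal(row$p, oracle_hyper_upper(N, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("ceRNA pairs are restricted to DMER-linked endpoints", {
  pairs <- data.frame(lncRNA = c("L1", "L2", "L1"),
                      mRNA = c("M1", "M1", "M9"),
                      stringsAsFactors = FALSE)
  dlnc <- data.frame(gene_id = "L1", direction = "hypo",
                     stringsAsFactors = FALSE)
  dmrna <- data.frame(gene_id = "M1", direction = "hypo",
                      stringsAsFactors = FALSE)
  got <- intersect_with_dmer_targets(pairs, dlnc, dmrna)
  expect_equal(nrow(got), 1L)
  expect_equal(got$lncRNA, "L1")
  expect_equal(got$mRNA, "M1")
  expect_equal(nrow(intersect_with_dmer_targets(pairs, dlnc[0, ], dmrna)), 0L)
})

test_that("co-expression screen applies the strict PCC and p gates", {
  set.seed(8)
  n <- 10
  samples <- sprintf("s%d", 1:n)
  base <- rnorm(n)
  corvec <- function(x, r) {
    e <- residuals(lm(rnorm(length(x)) ~ x))
    r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  }
  lnc <- rbind(L1 = base, L2 = base, L3 = base)
  colnames(lnc) <- samples
  mrna <- rbind(M1 = base,                       # identical: r = 1
                M2 = corvec(base, 0.5),          # exactly at the cut
                M3 = corvec(base, 0.9))
  colnames(mrna) <- samples
  pairs <- data.frame(lncRNA = c("L1", "L2", "L3"),
                      mRNA = c("M1", "M2", "M3"), stringsAsFactors = FALSE)
  got <- coexpression_screen(pairs, lnc, mrna)
  expect_true("M1" %in% got$mRNA)
  expect_equal(got$pcc[got$mRNA == "M1"], 1)
  expect_false("M2" %in% got$mRNA)               # r = 0.5 exactly: dropped
  expect_true("M3" %in% got$mRNA)
  expect_equal(got$p[got$mRNA == "M3"],
               cor.test(base, mrna["M3", ])$p.value, tolerance = 1e-12)
})

test_that("EMTRN assembly splits by direction and conserves edges", {
  edges <- data.frame(lncRNA = c("L1", "L1", "L2", "L2", "L3"),
                      mRNA = c("M1", "M2", "M1", "M2", "M3"),
                      pcc = 0.9, p = 1e-4, stringsAsFactors = FALSE)
  dlnc <- data.frame(gene_id = c("L1", "L2", "L3"),
                     direction = c("hypo", "hypo", "hyper"),
                     stringsAsFactors = FALSE)
  dmrna <- data.frame(gene_id = c("M1", "M2", "M3"),
                      direction = c("hypo", "hypo", "hypo"),
                      stringsAsFactors = FALSE)
  nets <- assemble_emtrn(edges, dlnc, dmrna)
  # 2 hypo lncRNAs x 2 hypo mRNAs fully connected -> degrees all 2
  hypo <- nets$hypo
  expect_equal(nrow(hypo$edges), 4L)
  expect_setequal(hypo$nodes$degree, 2L)
  # the L3-M3 edge is hyper x hypo -> mixed: in the full network only
  expect_equal(nrow(nets$hyper$edges), 0L)
  full <- nets$full
  expect_equal(sum(full$edges$edge_direction == "mixed"), 1L)
  expect_equal(sum(full$edges$edge_direction == "hypo") +
                 sum(full$edges$edge_direction == "hyper") +
                 sum(full$edges$edge_direction == "mixed"), nrow(edges))
  # empty input gives three empty networks
  nets0 <- assemble_emtrn(edges[0, ], dlnc, dmrna)
  expect_equal(vapply(nets0, function(n) nrow(n$edges), 0L),
               c(full = 0L, hyper = 0L, hypo = 0L))
})

test_that("hub flags mark the top of the degree distribution", {
  edges <- data.frame(
    lncRNA = c(rep("L1", 6), "L2", "L3"),
    mRNA = c(sprintf("M%d", 1:6), "M1", "M2"),
    stringsAsFactors = FALSE)
  dlnc <- data.frame(gene_id = c("L1", "L2", "L3"), direction = "hypo",
                     stringsAsFactors = FALSE)
  dmrna <- data.frame(gene_id = sprintf("M%d", 1:6), direction = "hypo",
                      stringsAsFactors = FALSE)
  nets <- assemble_emtrn(edges, dlnc, dmrna)
  nodes <- nets$hypo$nodes
  # 9 nodes -> ceiling(0.15 * 9) = 2, threshold is the 2nd-largest degree
  # (2); ties at the threshold are included
  expect_true(nodes$hub[nodes$id == "L1"])      # degree 6
  expect_true(nodes$hub[nodes$id == "M1"])      # degree 2
  expect_true(nodes$hub[nodes$id == "M2"])      # degree 2 (tie)
  expect_equal(sum(nodes$hub), 3L)
  expect_false(any(nodes$hub[nodes$degree == 1]))
})
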