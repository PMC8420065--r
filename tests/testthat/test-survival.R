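test_that("sample splitting gives the prescribed sizes deterministically", {
  s10 <- sprintf("s%02d", 1:10)
  part <- split_samples(s10, seed = 1)
  expect_equal(sum(part == "train"), 5L)
  expect_equal(sum(part == "test"), 5L)
  expect_identical(part, split_samples(s10, seed = 1))
  part9 <- split_samples(s10[1:9], seed = 3)
  expect_equal(sum(part9 == "train"), 5L)   # ceiling(9/2)
  expect_equal(sum(part9 == "test"), 4L)
  expect_error(split_samples(s10[1:3], 1), "4")
})

test_that("Cox fit matches the hand-written partial-likelihood maximiser", {
  # 4-subject worked example: all events, binary covariate
  time <- 1:4; event <- rep(1L, 4); x <- c(1, 0, 1, 0)
  expr <- matrix(x, 1, dimnames = list("g1", sprintf("s%d", 1:4)))
  surv <- data.frame(sample_id = sprintf("s%d", 1:4), time = time,
                     event = event, stringsAsFactors = FALSE)
  fit <- fit_cox(expr, surv)
  bhat <- oracle_cox_grid(time, event, x)
  expect_equal(unname(fit$coef), bhat, tolerance = 1e-3)
  expect_equal(unname(fit$coef), 0.9406, tolerance = 1e-3)
  # the score of the hand-written partial likelihood vanishes at the MLE
  expect_lt(abs(oracle_cox_score(fit$coef, time, event, cbind(x))), 1e-6)

  # constant covariate is degenerate
  expr2 <- rbind(expr, g2 = rep(1, 4))
  expect_error(fit_cox(expr2, surv), "constant")
})

test_that("Cox fit is approximately unbiased and null-calibrated", {
  set.seed(13)
  # null covariate: estimates concentrate near zero
  near0 <- vapply(1:30, function(i) {
    n <- 400
    x <- rnorm(n)
    tt <- rexp(n, 0.1)
    expr <- matrix(x, 1, dimnames = list("g", sprintf("s%d", 1:n)))
    sv <- data.frame(sample_id = sprintf("s%d", 1:n), time = tt, event = 1L)
    unname(fit_cox(expr, sv)$coef)
  }, 0)
  expect_gte(mean(abs(near0) < 0.15), 0.9)
  expect_lt(abs(mean(near0)), 0.05)
})

test_that("risk scores, cutoff and the tie rule follow the contract", {
  expr <- matrix(c(2, 1, 3, 2, 1, 4, 2.6, 1.0), 2,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  beta <- c(g1 = 0.5, g2 = -1.2)
  sc <- risk_scores_and_split(beta, expr, train_ids = sprintf("s%d", 1:4))
  expect_equal(sc$score[1], 0.5 * 2 - 1.2 * 1)   # -0.2
  # training scores: cutoff is their median; strictly-above -> high
  scores <- sc$score
  expect_equal(sc$group, ifelse(scores > median(scores), "high", "low"))
  # a sample exactly at the cutoff lands in the low-risk group
  expr2 <- matrix(c(1, 2, 3, 4, 2.5), 1,
                  dimnames = list("g", sprintf("s%d", 1:5)))
  sc2 <- risk_scores_and_split(c(g = 1), expr2, sprintf("s%d", 1:4))
  expect_equal(sc2$group[sc2$sample_id == "s5"], "low")
  expect_equal(sc2$group, c("low", "low", "high", "high", "low"))
})

test_that("log-rank matches the hand-summed worked example and oracle", {
  time <- 1:4; event <- rep(1L, 4); group <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, 2.882353, tolerance = 1e-6)
  expect_equal(lr$chisq, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-9)
  expect_equal(lr$p, pchisq(2.882353, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  set.seed(21)
  for (i in 1:15) {
    n <- 40
    tt <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.8)
    gg <- sample(c("A", "B"), n, replace = TRUE)
    expect_equal(logrank_test(tt, ev, gg)$chisq,
                 oracle_logrank_chisq(tt, ev, gg), tolerance = 1e-8)
  }

  # undefined cases report p = 1 with a flag
  expect_equal(logrank_test(1:4, rep(0L, 4), group)$flag, "no_events")
  expect_equal(logrank_test(1:4, event, rep("A", 4))$p, 1)
})

test_that("log-rank has power under strong separation", {
  set.seed(31)
  hits <- vapply(1:25, function(i) {
    n <- 200
    g <- rep(c("A", "B"), each = n / 2)
    tt <- rexp(n, 0.01 * ifelse(g == "A", 3, 1))   # hazard ratio 3
    logrank_test(tt, rep(1L, n), g)$p <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("module screen separates a planted prognostic module from null modules", {
  set.seed(17)
  retained_planted <- c(); retained_null <- c()
  for (seed in 1:12) {
    st <- simulate_study(small_sim_params(n_tumor = 60L), seed = seed + 100)
    gt <- st$ground_truth
    pm <- gt$modules[[gt$prognostic_module]]
    null_mod <- gt$modules[[2L]]   # factor-driven but survival-independent
    mods <- data.frame(module_id = c("P", "N"),
                       n_lnc = c(length(pm$lncRNAs), length(null_mod$lncRNAs)),
                       n_mrna = c(length(pm$mRNAs), length(null_mod$mRNAs)),
                       stringsAsFactors = FALSE)
    mods$lncRNAs <- list(pm$lncRNAs, null_mod$lncRNAs)
    mods$mRNAs <- list(pm$mRNAs, null_mod$mRNAs)
    expr <- rbind(st$lnc_expr, st$mrna_expr)
    scr <- screen_prognostic_modules(mods, expr, st$survival, seed = seed)
    retained_planted <- c(retained_planted, scr$retained[1])
    retained_null <- c(retained_null, scr$retained[2])
  }
  # the planted module is retained far above the null rate; a module whose
  # genes are independent of survival is retained about as often as two
  # independent 5% tests allow
  expect_gte(mean(retained_planted), 0.3)
  expect_lte(mean(retained_null), 0.2)
  expect_gt(mean(retained_planted), mean(retained_null))
})

test_that("screen handles degenerate modules gracefully", {
  st <- simulate_study(small_sim_params(), seed = 3)
  expr <- rbind(st$lnc_expr, st$mrna_expr)
  mods <- data.frame(module_id = c("BAD", "MISS"), n_lnc = 1L, n_mrna = 1L,
                     stringsAsFactors = FALSE)
  mods$lncRNAs <- list("LNC_0001", "NOT_A_GENE")
  mods$mRNAs <- list("MRNA_0001", "MRNA_0001")
  expr["LNC_0001", ] <- 1          # constant covariate -> unfittable
  scr <- screen_prognostic_modules(mods, expr, st$survival, seed = 1)
  expect_match(scr$flag[1], "unfittable")
  expect_equal(scr$flag[2], "missing_expression")
  expect_false(any(scr$retained))
  empty <- screen_prognostic_modules(mods[0, ], expr, st$survival, seed = 1)
  expect_equal(nrow(empty), 0L)
})
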