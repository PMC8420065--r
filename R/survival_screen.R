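# Train/test prognostic screening of biclique modules: joint Cox fit,
# risk-score dichotomisation at the training median, log-rank in both
# partitions.

#' Random half split of samples into training and test sets
#'
#' Uniform random permutation; the first `ceiling(n/2)` samples form the
#' training set, the rest the test set (equal sizes for even n).
#'
#' @param samples character vector of sample ids.
#' @param seed integer seed.
#' @return named character vector (`"train"`/`"test"`) indexed by sample id.
#' @export
split_samples <- function(samples, seed) {
  n <- length(samples)
  if (n < 4L) stop("need >= 4 samples to split")
  set.seed(seed)
  perm <- sample(samples)
  part <- setNames(rep("test", n), perm)
  part[seq_len(ceiling(n / 2))] <- "train"
  part[samples]
}

#' Joint Cox proportional-hazards fit for a module's genes
#'
#' Maximises the Cox partial likelihood with Breslow tie handling
#' (Newton-Raphson, coefficient tolerance 1e-9, at most 50 iterations) for
#' the module genes jointly. Degenerate inputs (constant covariate,
#' collinear-singular design) are an error; a monotone likelihood (no
#' finite maximiser, coefficients diverging) is flagged.
#'
#' @param expression genes x samples matrix restricted to the training
#'   samples (rows are module genes).
#' @param surv data.frame with columns `sample_id`, `time`, `event`
#'   covering the expression columns.
#' @param standardize centre/scale each gene before fitting; default FALSE.
#' @return list with `coef` (named numeric), `converged`, `monotone`
#'   flags, and the `fit` object.
#' @export
fit_cox <- function(expression, surv, standardize = FALSE) {
  stopifnot(is.matrix(expression))
  surv <- surv[match(colnames(expression), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$time)) stop("survival records missing for some samples")
  if (sum(surv$event) < 1L) stop("need >= 1 event to fit")
  x <- t(expression)
  if (standardize) x <- scale(x)
  sds <- apply(x, 2L, sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("degenerate covariate (constant across samples): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (anyNA(beta)) stop("singular design: coefficients not estimable")
  names(beta) <- rownames(expression)
  if (any(abs(beta) > 15)) monotone <- TRUE
  list(coef = beta,
       converged = !monotone && fit$iter < 50L,
       monotone = monotone,
       fit = fit)
}

#' Risk scores and high/low grouping from a fitted module
#'
#' The per-sample risk score is the linear predictor `sum(beta_i * X_i)`
#' over module genes. The cutoff is the median of the *training* scores;
#' samples strictly above the cutoff are `high` risk, all others
#' (including scores exactly at the cutoff) `low`. The same cutoff is
#' applied to training and test samples.
#'
#' @param coefficients named numeric vector of Cox coefficients (per gene).
#' @param expression genes x samples matrix over all samples to score.
#' @param train_ids character vector of training sample ids.
#' @return data.frame: `sample_id`, `score`, `group`, `partition`.
#' @export
risk_scores_and_split <- function(coefficients, expression, train_ids) {
  genes <- names(coefficients)
  stopifnot(all(genes %in% rownames(expression)))
  score <- as.vector(crossprod(expression[genes, , drop = FALSE],
                               coefficients))
  names(score) <- colnames(expression)
  cutoff <- median(score[train_ids])
  data.frame(sample_id = colnames(expression),
             score = unname(score),
             group = ifelse(score > cutoff, "high", "low"),
             partition = ifelse(colnames(expression) %in% train_ids,
                                "train", "test"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with the hypergeometric variance at each
#' event time, referred to a chi-square with 1 df.
#'
#' @param time,event numeric follow-up times and 0/1 event flags.
#' @param group two-level grouping vector.
#' @return list with `chisq`, `p`, and `flag` (`"no_events"` /
#'   `"one_group"` when the test is undefined and `p = 1` is reported).
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) < 2L)
    return(list(chisq = NA_real_, p = 1, flag = "one_group"))
  if (sum(event) == 0L)
    return(list(chisq = NA_real_, p = 1, flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
       flag = NA_character_)
}

#' Screen biclique modules for prognostic value
#'
#' Per module: joint Cox fit on the training partition, risk scores for all
#' samples, dichotomisation at the training median, and log-rank tests in
#' the training and test partitions separately. A module is retained when
#' the log-rank p is `<= p_cut` in *both* partitions. Modules whose Cox
#' fit is degenerate or monotone are excluded and flagged. No
#' multiple-testing correction is applied across modules.
#'
#' @param modules module table from [enumerate_maximal_bicliques()].
#' @param expression genes x tumour-samples matrix covering the module
#'   genes (lncRNAs and mRNAs together).
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param seed integer seed for the train/test split (one split shared by
#'   all modules).
#' @param p_cut log-rank p cut; default 0.05.
#' @param standardize standardize covariates before the Cox fit.
#' @return data.frame with one row per module: sizes, fitted coefficients
#'   (list column `coef`), training-median `cutoff`, `chisq_train`,
#'   `p_train`, `chisq_test`, `p_test`, `retained`, `flag`; attribute
#'   `partition` holds the split.
#' @export
screen_prognostic_modules <- function(modules, expression, surv, seed,
                                      p_cut = 0.05, standardize = FALSE) {
  samples <- intersect(colnames(expression), surv$sample_id)
  expression <- expression[, samples, drop = FALSE]
  surv <- surv[match(samples, surv$sample_id), , drop = FALSE]
  part <- split_samples(samples, seed)
  train_ids <- names(part)[part == "train"]
  test_ids <- names(part)[part == "test"]
  rows <- vector("list", nrow(modules))
  for (i in seq_len(nrow(modules))) {
    genes <- c(modules$lncRNAs[[i]], modules$mRNAs[[i]])
    row <- data.frame(module_id = modules$module_id[i],
                      n_lnc = modules$n_lnc[i], n_mrna = modules$n_mrna[i],
                      cutoff = NA_real_,
                      chisq_train = NA_real_, p_train = NA_real_,
                      chisq_test = NA_real_, p_test = NA_real_,
                      retained = FALSE, flag = NA_character_,
                      stringsAsFactors = FALSE)
    row$coef <- list(NULL)
    if (!all(genes %in% rownames(expression))) {
      row$flag <- "missing_expression"
      rows[[i]] <- row; next
    }
    fit <- tryCatch(
      fit_cox(expression[genes, train_ids, drop = FALSE],
              surv, standardize = standardize),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row$flag <- paste("unfittable:", conditionMessage(fit))
      rows[[i]] <- row; next
    }
    if (fit$monotone) {
      row$flag <- "monotone_likelihood"
      rows[[i]] <- row; next
    }
    sc <- risk_scores_and_split(fit$coef, expression[genes, , drop = FALSE],
                                train_ids)
    row$coef <- list(fit$coef)
    row$cutoff <- median(sc$score[sc$partition == "train"])
    for (pt in c("train", "test")) {
      ids <- if (pt == "train") train_ids else test_ids
      ii <- match(ids, surv$sample_id)
      lr <- logrank_test(surv$time[ii], surv$event[ii],
                         sc$group[match(ids, sc$sample_id)])
      row[[paste0("chisq_", pt)]] <- lr$chisq
      row[[paste0("p_", pt)]] <- lr$p
    }
    row$retained <- !is.na(row$p_train) && !is.na(row$p_test) &&
      row$p_train <= p_cut && row$p_test <= p_cut
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(module_id = character(), n_lnc = integer(),
                      n_mrna = integer(), cutoff = numeric(),
                      chisq_train = numeric(), p_train = numeric(),
                      chisq_test = numeric(), p_test = numeric(),
                      retained = logical(), flag = character(),
                      stringsAsFactors = FALSE)
    out$coef <- list()
  }
  attr(out, "partition") <- part
  out
}
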