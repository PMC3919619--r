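# Agreement/correlation metrics, role swapping, confusion metrics and the
# exact statistical tests.

fake_truth <- function(regulator, genes, ratios, significant = TRUE) {
  data.frame(regulator = regulator, gene = genes, log_ratio = ratios,
             p = ifelse(significant, 0.001, 0.5),
             significant = significant,
             direction = ifelse(!significant, "none",
                                ifelse(ratios > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

test_that("sign agreement scores activator/repressor roles against deletions", {
  ## one activator prediction whose target drops on deletion: agreement 1
  e <- data.frame(regulator = "R", target = "g1", beta = 1.5)
  tr <- fake_truth("R", "g1", -2)
  expect_equal(sign_agreement(e, tr)$agreement, 1)

  ## correlation of ratios with -beta: (-2, 1, -1) vs -(2, -1, 1) => r = 1
  e3 <- data.frame(regulator = "R", target = c("g1", "g2", "g3"),
                   beta = c(2, -1, 1))
  tr3 <- fake_truth("R", c("g1", "g2", "g3"), c(-2, 1, -1))
  out <- sign_agreement(e3, tr3)
  expect_equal(out$correlation, 1, tolerance = 1e-12)
  expect_equal(out$agreement, 1)

  ## randomized deletion responses give ~50% agreement
  set.seed(81)
  agreements <- replicate(50, {
    e100 <- data.frame(regulator = "R", target = sprintf("g%03d", 1:100),
                       beta = sample(c(-1, 1), 100, TRUE))
    tr100 <- fake_truth("R", sprintf("g%03d", 1:100),
                        sample(c(-1, 1), 100, TRUE))
    sign_agreement(e100, tr100)$agreement
  })
  expect_gt(mean(agreements), 0.4)
  expect_lt(mean(agreements), 0.6)

  empty <- sign_agreement(e, fake_truth("other", "g9", 1))
  expect_identical(empty$n, 0L)
})

test_that("role swapping fixes significantly anti-correlated regulators", {
  ## all-activator predictions, every target rises on deletion
  e <- data.frame(regulator = "R", target = sprintf("g%d", 1:8),
                  beta = c(2, 1.5, 1, 2.5, 1.2, 1.8, 2.2, 1.1))
  tr <- fake_truth("R", sprintf("g%d", 1:8), e$beta + rnorm(8, 0, 0.05))
  fx <- fixed_metrics(e, tr)
  expect_lt(fx$agreement, 0.2)
  expect_identical(fx$swapped, "R")
  expect_equal(fx$agreement_fix, 1)

  ## nothing anti-correlated: fix metrics equal plain metrics
  tr_ok <- fake_truth("R", sprintf("g%d", 1:8), -e$beta + rnorm(8, 0, 0.05))
  fx_ok <- fixed_metrics(e, tr_ok)
  expect_length(fx_ok$swapped, 0)
  expect_equal(fx_ok$agreement_fix, fx_ok$agreement)

  ## mixed case against hand enumeration: R1 is anti-correlated and swaps
  ## (0/4 -> 4/4 agreements); R2 is fine and keeps its 4/4
  e8 <- data.frame(regulator = rep(c("R1", "R2"), each = 4),
                   target = sprintf("g%d", 1:8),
                   beta = c(1, 2, 3, 4, 1, -1, 2, -2))
  tr8 <- rbind(fake_truth("R1", sprintf("g%d", 1:4), c(1, 2, 3, 4.2)),
               fake_truth("R2", sprintf("g%d", 5:8), c(-1, 1, -2, 2.2)))
  fx8 <- fixed_metrics(e8, tr8)
  expect_identical(fx8$swapped, "R1")
  expect_equal(fx8$agreement, 4 / 8)
  expect_equal(fx8$agreement_fix, 8 / 8)
})

test_that("full-equation prediction metrics behave at the extremes", {
  ## exact linear system: predictions match actuals in sign everywhere
  progs <- list(t1 = make_program("t1", c(A = 2)),
                t2 = make_program("t2", c(A = -1, B = 0.5)))
  regv <- c(A = -4, B = 0)
  actual <- c(t1 = -8, t2 = 4)
  pm <- prediction_metrics(progs, regv, actual)
  expect_equal(pm$prediction_agreement, 1)

  ## zero predictions match nothing
  progs0 <- list(t1 = make_program("t1", c(A = 0.5)))
  pm0 <- prediction_metrics(progs0, c(A = 0), c(t1 = 2))
  expect_equal(pm0$prediction_agreement, 0)

  ## independent recomputation to machine precision
  set.seed(82)
  regs <- sprintf("r%d", 1:5)
  progs_n <- lapply(setNames(sprintf("t%d", 1:10), sprintf("t%d", 1:10)),
                    function(g) {
    terms <- setNames(rnorm(2), sample(regs, 2))
    make_program(g, terms, intercept = rnorm(1))
  })
  rv <- setNames(rnorm(5), regs)
  act <- setNames(rnorm(10), names(progs_n))
  pm_n <- prediction_metrics(progs_n, rv, act)
  manual_pred <- vapply(progs_n, function(p)
    p$intercept + sum(p$terms * rv[names(p$terms)]), numeric(1))
  expect_equal(pm_n$prediction_correlation, cor(manual_pred, act),
               tolerance = 1e-12)
  expect_equal(pm_n$prediction_agreement,
               mean(sign(manual_pred) == sign(act) & sign(act) != 0),
               tolerance = 1e-12)
})

test_that("confusion metrics match their closed forms", {
  ## direct formula check: TP=3 FP=1 FN=2 TN=14
  expect_equal(mcc_score(3, 1, 2, 14), 40 / sqrt(4800), tolerance = 1e-12)
  expect_equal(f1_score(3, 1, 2), 2 * 3 / (2 * 3 + 1 + 2), tolerance = 1e-12)

  ## perfect gene-level predictions
  tr <- fake_truth("R", sprintf("g%d", 1:6), c(1, -1, 2, 0.5, -2, 1),
                   significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  e <- data.frame(regulator = "R", target = sprintf("g%d", 1:3),
                  beta = c(1, 2, 3))
  out <- gene_level_confusion(e, tr)
  expect_equal(out$mcc, 1)
  expect_equal(out$f1, 1)
  expect_equal(out$auc, 1)

  ## random scores at prevalence 0.1 give AUC ~ 0.5
  set.seed(83)
  aucs <- replicate(50, {
    labels <- runif(200) < 0.1
    auc_score(rnorm(200), labels)
  })
  expect_gt(mean(aucs, na.rm = TRUE), 0.45)
  expect_lt(mean(aucs, na.rm = TRUE), 0.55)

  ## AUC is invariant under strictly monotone re-scoring
  sc <- rnorm(100)
  lb <- runif(100) < 0.3
  expect_equal(auc_score(sc, lb), auc_score(exp(sc), lb), tolerance = 1e-12)

  ## degenerate single-class truth
  expect_warning(m0 <- mcc_score(0, 0, 0, 10), "degenerate")
  expect_equal(m0, 0)
})

test_that("cluster-level confusion reduces to gene level for singletons", {
  genes <- sprintf("g%d", 1:8)
  tr <- fake_truth("R", genes, c(2, -2, 1, 0.1, 0.1, 0.1, 0.1, 0.1),
                   significant = c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  e <- data.frame(regulator = "R", target = genes[c(1, 2, 5)],
                  beta = c(1, -1, 0.5))
  gene_out <- gene_level_confusion(e, tr, universe = genes)

  enr <- data.frame(regulator = "R", cluster = genes,
                    p = ifelse(genes %in% e$target, 0.001, 0.9),
                    called = genes %in% e$target)
  truth_calls <- data.frame(regulator = "R", cluster = genes,
                            significant = tr$significant)
  cl_out <- cluster_level_confusion(enr, truth_calls)
  expect_equal(cl_out$mcc, gene_out$mcc, tolerance = 1e-12)
  expect_equal(cl_out$f1, gene_out$f1, tolerance = 1e-12)

  ## no enriched pairs at all: F1 = 0
  enr0 <- enr
  enr0$called <- FALSE
  expect_warning(cl0 <- cluster_level_confusion(enr0, truth_calls))
  expect_equal(cl0$f1, 0)
})

test_that("rank tests agree with exact enumeration", {
  expect_equal(compare_metric_sets(c(1, 2, 3), c(1, 2, 3),
                                   "wilcoxon-signed-rank"), 1)
  ## Mann-Whitney U = 0 for fully separated triples: exact two-sided
  ## p = 2 / choose(6, 3) = 0.1
  expect_equal(compare_metric_sets(c(1, 2, 3), c(4, 5, 6), "mann-whitney"),
               0.1, tolerance = 1e-12)
  expect_error(compare_metric_sets(1:3, 1:4, "wilcoxon-signed-rank"),
               class = "egrinet_contract_error")

  ## power: clearly shifted Gaussians are detected
  set.seed(84)
  detected <- replicate(100, {
    compare_metric_sets(rnorm(30), rnorm(30, mean = 2),
                        "mann-whitney") < 0.01
  })
  expect_gte(mean(detected), 0.95)
})

test_that("the exact binomial test sums outcomes no likelier than observed", {
  expect_equal(binomial_fraction_test(3, 10, 0.5), 0.34375,
               tolerance = 1e-12)
  ## oracle for the same case: enumeration of the outcome probabilities
  probs <- dbinom(0:10, 10, 0.5)
  expect_equal(sum(probs[probs <= dbinom(3, 10, 0.5) + 1e-12]), 0.34375,
               tolerance = 1e-12)
  expect_equal(binomial_fraction_test(5, 10, 0.5), 1)
  expect_equal(binomial_fraction_test(0, 20, 0.5), 2 * 2^-20,
               tolerance = 1e-9)
  expect_error(binomial_fraction_test(11, 10, 0.5),
               class = "egrinet_contract_error")
  expect_error(binomial_fraction_test(1, 10, 1),
               class = "egrinet_contract_error")
})
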