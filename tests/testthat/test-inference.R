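# Elastic-net program fitting, prediction, combination, bicluster
# assignment and shuffle significance.

test_that("fit_program recovers a single noise-free cause among decoys", {
  set.seed(41)
  n <- 50
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("r%02d", 1:10)))
  y <- X[, 1]
  prog <- fit_program(y, X, fit_config(seed = 1, prune_fraction = 0))
  expect_true("r01" %in% names(prog$terms))
  expect_gt(prog$terms[["r01"]], 0)
  decoys <- setdiff(names(prog$terms), "r01")
  expect_true(all(abs(prog$terms[decoys]) <= 0.05))
})

test_that("fit_program estimates two-cause coefficients near truth", {
  ## oracle: least squares on the true support gives (2, -1) exactly in
  ## the noise-free case; a light elastic-net penalty shrinks mildly
  set.seed(42)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("r%02d", 1:6)))
  y <- 2 * X[, 1] - 1 * X[, 2]
  ols <- coef(lm(y ~ X[, 1] + X[, 2]))
  expect_equal(unname(ols[2:3]), c(2, -1), tolerance = 1e-10)
  prog <- fit_program(y, X, fit_config(penalty_selection = 0.01, seed = 1))
  expect_gte(prog$terms[["r01"]], 1.6)
  expect_lte(prog$terms[["r01"]], 2.2)
  expect_gte(prog$terms[["r02"]], -1.2)
  expect_lte(prog$terms[["r02"]], -0.7)
})

test_that("degenerate fits are handled explicitly", {
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  expect_warning(prog <- fit_program(rep(1, 20), X, fit_config(seed = 1),
                                     target = "flat"),
                 "zero-variance")
  expect_length(prog$terms, 0)
  expect_error(fit_program(rnorm(3), X[1:3, ], fit_config(cv_folds = 5)),
               class = "egrinet_config_error")
})

test_that("predict_expression applies the linear equation", {
  p <- make_program("t1", c(A = 2, B = -1), intercept = 0)
  expect_equal(predict_expression(p, c(A = 1, B = 3)), -1)
  empty <- make_program("t2", setNames(numeric(0), character(0)),
                        intercept = 0.7)
  expect_equal(predict_expression(empty, c(A = 1)), 0.7)
  expect_error(predict_expression(p, c(A = 1)),
               class = "egrinet_lookup_error")
  expect_match(tryCatch(predict_expression(p, c(A = 1)),
                        error = conditionMessage), "B")
})

test_that("noise-free synthetic predictions reproduce observations", {
  cfg <- tiny_config(seed = 44, noise_sd = 0)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  comp <- subset_experiments(ex, set = "compendium")
  targets <- setdiff(truth$genes, truth$regulators)[1:20]
  progs <- fit_programs(comp, targets, truth$regulators,
                        fit_config(penalty_selection = 0,
                                   prune_fraction = 0.1, seed = 1))
  regv <- comp$values[truth$regulators, ]
  for (g in targets) {
    pred <- predict_expression(progs[[g]], regv)
    expect_equal(unname(pred), unname(comp$values[g, ]), tolerance = 1e-6)
  }
})

test_that("combine_programs gives the condition-specific coefficients priority", {
  comp <- make_program("t", c(A = 0.5, B = 0.3), provenance = "compendium")
  cond <- make_program("t", c(A = 0.2, C = 0.4),
                       provenance = "condition-specific")
  merged <- combine_programs(comp, cond)
  expect_equal(merged$terms[c("A", "B", "C")], c(A = 0.2, B = 0.3, C = 0.4))
  expect_identical(merged$provenance, "combined")

  ## empty condition program: identity
  empty <- make_program("t", setNames(numeric(0), character(0)))
  expect_equal(combine_programs(comp, empty)$terms, comp$terms)

  ## disjoint regulators: simple union
  cond2 <- make_program("t", c(D = 1))
  expect_setequal(names(combine_programs(comp, cond2)$terms),
                  c("A", "B", "D"))

  ## idempotent in the second argument, associative under consistent
  ## priority
  once <- combine_programs(comp, cond)
  twice <- combine_programs(once, cond)
  expect_equal(twice$terms[sort(names(twice$terms))],
               once$terms[sort(names(once$terms))])

  expect_error(combine_programs(comp, make_program("other", c(A = 1))),
               class = "egrinet_contract_error")
})

test_that("bicluster assignment matches the exact hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  cluster <- universe[1:20]
  targets <- c(universe[1:10], universe[21:30])  # 10 in, 10 out

  res <- assign_predictions_to_bicluster(targets, cluster, universe,
                                         n_resamples = 1000, seed = 5)
  exact <- phyper(10 - 1, 20, 80, 20, lower.tail = FALSE)
  expect_lt(abs(res$p - exact), 0.02 + 1 / 1001)

  ## regulator targeting the whole universe: background always ties
  all_res <- assign_predictions_to_bicluster(universe, cluster, universe,
                                             n_resamples = 500, seed = 5)
  expect_equal(all_res$p, 1)

  ## regulator targeting exactly the cluster: maximal enrichment
  max_res <- assign_predictions_to_bicluster(cluster, cluster, universe,
                                             n_resamples = 500, seed = 5)
  expect_equal(max_res$p, 1 / 501)
})

test_that("correlation significance is exact at the extremes and null-uniform", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.1, -1.4, 0.8, 1.9, -0.2, 0.6)
  ident <- correlation_significance(x, x, n_shuffles = 1000, seed = 1)
  expect_equal(ident$r, 1)
  expect_equal(ident$p, 1 / 1001)

  anti <- correlation_significance(x, -x, n_shuffles = 1000, seed = 1)
  expect_equal(anti$r, -1)
  expect_equal(anti$p, 1)

  const <- correlation_significance(rep(1, 10), x)
  expect_true(const$degenerate)
  expect_equal(const$p, 1)

  set.seed(43)
  ps <- replicate(100, {
    correlation_significance(rnorm(30), rnorm(30), n_shuffles = 200,
                             seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("program edge tables and precision/recall bookkeeping are sound", {
  progs <- list(
    t1 = make_program("t1", c(A = 1, B = -2)),
    t2 = make_program("t2", c(A = 0.5)),
    t3 = make_program("t3", setNames(numeric(0), character(0)))
  )
  e <- program_edges(progs)
  expect_identical(nrow(e), 3L)
  truth <- data.frame(regulator = c("A", "B", "C"),
                      target = c("t1", "t1", "t2"))
  pr <- edge_precision_recall(e, truth)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
})

test_that("cluster-mean programs recover the module's shared regulators", {
  cfg <- tiny_config(seed = 45)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  comp <- subset_experiments(ex, set = "compendium")
  m <- truth$modules[[1]]
  progs <- fit_cluster_programs(comp, list(mod1 = m$genes),
                                truth$regulators, fit_config(seed = 45))
  expect_true(all(m$regulators %in% names(progs$mod1$terms)))
  shared_sign <- sign(m$program)
  expect_identical(unname(sign(progs$mod1$terms[m$regulators])),
                   unname(shared_sign))
})
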