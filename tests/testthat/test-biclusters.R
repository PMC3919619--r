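# Clustering, coherence testing against variance backgrounds, condition
# assignment and annotation enrichment.

test_that("clustering recovers well-separated planted modules", {
  cfg <- medium_config(seed = 21)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  zn <- zscore_normalize(ex)
  ## restrict to the genes of two modules: a clean two-group problem
  m1 <- truth$modules[[1]]$genes
  m2 <- truth$modules[[3]]$genes
  sub <- zn$values[c(m1, m2), ]
  cl <- cluster_genes(sub, k = 2, seed = 4)
  labels <- rep(names(cl), lengths(cl))[order(unlist(cl))]
  names(labels) <- sort(unlist(cl))
  ari <- rand_index_adjusted(labels[c(m1, m2)],
                             rep(c("a", "b"), c(length(m1), length(m2))))
  expect_gte(ari, 0.9)

  expect_identical(cluster_genes(sub, k = 2, seed = 4), cl)  # deterministic
  expect_identical(cluster_genes(sub, k = 1),
                   list(c001 = sort(rownames(sub))))
  expect_error(cluster_genes(sub, k = nrow(sub) + 1),
               class = "egrinet_config_error")
})

test_that("experiment coherence p-values hit their degenerate bounds", {
  set.seed(31)
  values <- matrix(rnorm(200 * 12), 200, 12,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("e%02d", 1:12)))
  bg <- variance_background(values, sizes = 8, n_resamples = 500, seed = 1)

  ## identical profiles: variance 0, below every background draw
  ident <- values
  ident[1:8, ] <- rep(ident[1, ], each = 8)
  coh0 <- experiment_coherence(rownames(values)[1:8], ident, bg)
  expect_equal(coh0$p, rep(1 / 501, 12), tolerance = 1e-12)
  expect_true(all(coh0$coherent))

  ## variance above every background draw
  blown <- values
  blown[9:16, ] <- blown[9:16, ] * 50
  coh1 <- experiment_coherence(rownames(values)[9:16], blown, bg)
  expect_equal(coh1$p, rep(1, 12), tolerance = 1e-12)

  expect_error(experiment_coherence(rownames(values)[1:5], values, bg),
               class = "egrinet_state_error")
})

test_that("coherence p-values are uniform under the null", {
  set.seed(32)
  values <- matrix(rnorm(300 * 4), 300, 4,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("e%d", 1:4)))
  bg <- variance_background(values, sizes = 10, n_resamples = 400, seed = 2)
  ps <- replicate(50, {
    experiment_coherence(sample(rownames(values), 10), values, bg)$p
  })
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("coherence type-I error is calibrated at alpha = 0.05", {
  set.seed(33)
  values <- matrix(rnorm(400 * 5), 400, 5,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("e%d", 1:5)))
  bg <- variance_background(values, sizes = 12, n_resamples = 400, seed = 3)
  flags <- replicate(100, {
    experiment_coherence(sample(rownames(values), 12), values, bg)$coherent
  })
  rate <- mean(flags)  # 500 null experiment-level tests
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("condition coherence follows the strict majority rule", {
  coherent <- setNames(c(rep(TRUE, 10), rep(FALSE, 9)),
                       sprintf("e%02d", 1:19))
  expect_true(condition_coherence(coherent, names(coherent)))  # 10 > 9.5

  half <- setNames(rep(c(TRUE, FALSE), 5), sprintf("e%02d", 1:10))
  expect_false(condition_coherence(half, names(half)))  # exactly half

  none <- setNames(rep(FALSE, 7), sprintf("e%02d", 1:7))
  expect_false(condition_coherence(none, names(none)))

  ## monotone: turning an incoherent experiment coherent never flips
  ## a coherent condition to incoherent
  set.seed(34)
  for (i in 1:25) {
    flags <- setNames(sample(c(TRUE, FALSE), 11, TRUE), sprintf("e%02d", 1:11))
    before <- condition_coherence(flags, names(flags))
    j <- sample(which(!flags), 1)
    flags[j] <- TRUE
    if (before) expect_true(condition_coherence(flags, names(flags)))
  }
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  ## oracle: P(overlap >= k) by direct combinatorial counting
  brute_tail <- function(k, cluster_n, annot_n, universe_n) {
    total <- choose(universe_n, cluster_n)
    sum(vapply(k:min(cluster_n, annot_n), function(i)
      choose(annot_n, i) * choose(universe_n - annot_n, cluster_n - i),
      numeric(1))) / total
  }
  universe <- sprintf("u%02d", 1:20)
  annot <- universe[1:10]
  cluster <- universe[c(1:4, 15)]  # overlap 4
  expect_equal(annotation_enrichment(cluster, annot, universe),
               brute_tail(4, 5, 10, 20), tolerance = 1e-12)

  set.seed(35)
  for (i in 1:20) {
    n_u <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(n_u))
    an <- sample(uni, sample(2:(n_u - 2), 1))
    cl <- sample(uni, sample(2:(n_u - 2), 1))
    k <- length(intersect(an, cl))
    expect_equal(annotation_enrichment(cl, an, uni),
                 brute_tail(k, length(cl), length(an), n_u),
                 tolerance = 1e-12)
  }

  ## disjoint cluster: upper tail from overlap 0 is 1
  expect_equal(annotation_enrichment(universe[15:18], universe[1:5],
                                     universe), 1)
  expect_error(annotation_enrichment(universe[1:3], universe[1:5],
                                     character()),
               class = "egrinet_config_error")
})

test_that("strong annotation enrichment reaches the reported magnitude", {
  ## 16 of 29 cluster genes annotated, against an 87-gene annotation in a
  ## ~6000-gene universe: far below 1e-4
  universe <- sprintf("y%04d", 1:6000)
  annot <- universe[1:87]
  cluster <- c(universe[1:16], universe[100:112])  # 29 genes, 16 annotated
  expect_lte(annotation_enrichment(cluster, annot, universe), 1e-4)
})

test_that("bicluster assembly wires coherence, conditions and enrichment", {
  cfg <- medium_config(seed = 22)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  zn <- zscore_normalize(ex)
  m1 <- truth$modules[[1]]
  clusters <- list(mod = m1$genes,
                   rand = sample(truth$genes, 10))
  bic <- make_biclusters(clusters, zn, truth$annotation_sets,
                         n_resamples = 300, seed = 9)
  ## the annotated module is coherent under the bulk of the named
  ## conditions and enriched for the engineered annotation
  expect_gte(sum(bic$mod$condition_coherence[c("LS", "EO", "LO")]), 2)
  named <- zn$meta$experiment[zn$meta$condition %in% c("LS", "EO", "LO")]
  expect_gt(mean(bic$mod$coherence$coherent[
    bic$mod$coherence$experiment %in% named]), 0.6)
  enr <- bic$mod$enrichment
  expect_lt(enr$p[enr$annotation == "peroxisome_like"], 1e-6)
  ## condition flags derive from the per-experiment flags by majority
  meta <- zn$meta
  for (cc in c("LS", "EO", "LO")) {
    manual <- condition_coherence(
      setNames(bic$rand$coherence$coherent, bic$rand$coherence$experiment),
      meta$experiment[meta$condition == cc])
    expect_identical(unname(bic$rand$condition_coherence[cc]), manual)
  }
})
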