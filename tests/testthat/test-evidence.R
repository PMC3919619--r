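# Evidence streams: deletion DE, cluster calls, shattering, binding
# assignment, and their degenerate cases.

test_that("deletion DE follows the fitted two-tailed normal", {
  set.seed(51)
  prof <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  ## a value exactly at the fitted mean has p ~ 1
  prof2 <- prof
  prof2["g001"] <- mean(prof2)
  prof2["g001"] <- mean(prof2)  # fixed point after refit
  de2 <- deletion_de(prof2)
  expect_gt(de2$p[de2$gene == "g001"], 0.99)
  ## a value at mean +/- 1.96 sd has p ~ 0.05 (oracle: normal CDF)
  prof3 <- prof
  prof3["g001"] <- mean(prof3) + qnorm(0.975) * pop_sd(prof3)
  de3 <- deletion_de(prof3)
  expect_equal(de3$p[de3$gene == "g001"],
               2 * pnorm(-abs((prof3[["g001"]] - mean(prof3)) /
                                pop_sd(prof3))),
               tolerance = 1e-12)
  expect_equal(de3$p[de3$gene == "g001"], 0.05, tolerance = 0.1)

  ## symmetric values around the mean get equal p, opposite directions
  prof4 <- prof - mean(prof)
  prof4 <- prof4 - mean(prof4)
  prof4["g001"] <- 2.5
  prof4["g002"] <- -2.5
  prof4 <- prof4 - mean(prof4)
  de4 <- deletion_de(prof4)
  i <- match(c("g001", "g002"), de4$gene)
  expect_equal(de4$p[i[1]], de4$p[i[2]], tolerance = 0.02)
  expect_identical(de4$direction[i], c("repression", "activation"))

  expect_error(deletion_de(prof[1:10]), class = "egrinet_contract_error")
  expect_error(deletion_de(setNames(rep(1, 50), sprintf("g%02d", 1:50))),
               class = "egrinet_contract_error")
})

test_that("deletion cluster calls reuse the hypergeometric machinery", {
  universe <- sprintf("g%02d", 1:20)
  cluster <- universe[1:6]
  ## DE set identical to the cluster: minimal possible p
  p_min <- deletion_cluster_call(cluster, cluster, universe)
  expect_equal(p_min, 1 / choose(20, 6), tolerance = 1e-12)
  ## disjoint DE set: p = 1
  expect_equal(deletion_cluster_call(universe[7:12], cluster, universe), 1)
  ## parity with the enrichment op on a small instance
  de_set <- universe[c(1:3, 10:12)]
  expect_equal(deletion_cluster_call(de_set, cluster, universe),
               annotation_enrichment(cluster, de_set, universe),
               tolerance = 1e-15)
})

test_that("shattering triggers on variance excess only", {
  wt <- c(0.2, 0.3, 0.25, 0.4, 0.35, 0.3, 0.28, 0.33, 0.26, 0.31)
  ## constant deletion values: variance 0, below everything
  flat <- shattering_test(rep(1, 8), wt)
  expect_false(flat$shattered)
  expect_equal(flat$p, 1)
  ## variance above every wild-type observation
  blown <- shattering_test(c(-5, 5, -4, 4, -6, 6, -3, 3), wt)
  expect_true(blown$shattered)
  expect_equal(blown$p, 1 / (length(wt) + 1))
  expect_error(shattering_test(rnorm(5), wt[1:3]),
               class = "egrinet_background_error")
})

test_that("deleting a module's regulator shatters its cluster; nulls do not", {
  cfg <- medium_config(seed = 52)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  cond_raw <- subset_experiments(ex, set = "condition")
  m <- truth$modules[[1]]  # annotated: active in all named conditions
  wt <- cluster_wildtype_variances(m$genes, cond_raw)
  r <- m$regulators[1]
  hits <- vapply(c("LS", "EO", "LO"), function(cc) {
    del <- simulate_deletion(truth, r, cc, cfg)
    shattering_test(del$values[m$genes, 1], wt)$shattered
  }, TRUE)
  expect_true(any(hits))

  ## a regulator with no edge into the module leaves it intact
  clean <- truth$regulators[colSums(truth$coefficients[m$genes, ] != 0) == 0]
  del0 <- simulate_deletion(truth, clean[1], "EO", cfg)
  expect_false(shattering_test(del0$values[m$genes, 1], wt)$shattered)
})

test_that("binding events map to promoter windows strand-awarely", {
  gm <- data.frame(gene = c("gPlus", "gMinus"),
                   chrom = c("chr1", "chr1"),
                   strand = c("+", "-"),
                   tss = c(5000L, 20000L))
  ev <- data.frame(
    tf = c("tf1", "tf1", "tf1", "tf1", "tf1", "tf2"),
    chrom = "chr1",
    position = c(4600L,   # 400 bp upstream of gPlus: in window
                 3999L,   # 1001 bp upstream: out
                 5100L,   # exactly +100 downstream: in
                 20500L,  # 500 bp upstream of the minus-strand gene: in
                 21101L,  # 1101 bp upstream of gMinus: out
                 4600L),
    p_value = c(0.03, 0.001, 0.001, 0.02, 0.001, 0.5))
  out <- assign_binding(ev, gm)
  plus <- out[out$gene == "gPlus" & out$regulator == "tf1", ]
  ## two in-window events for (tf1, gPlus): the lowest p is kept
  expect_identical(nrow(plus), 1L)
  expect_equal(plus$p, 0.001)
  expect_identical(plus$strength, "strong")
  minus <- out[out$gene == "gMinus", ]
  expect_equal(minus$p, 0.02)
  expect_identical(minus$strength, "weak")
  expect_false(any(out$p == 0.5 & out$gene == "gMinus"))

  ## divergent pair sharing a region: the event assigns to both genes
  gm2 <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    strand = c("-", "+"), tss = c(1000L, 1500L))
  ev2 <- data.frame(tf = "tf1", chrom = "chr1", position = 1200L,
                    p_value = 0.005)
  out2 <- assign_binding(ev2, gm2)
  expect_setequal(out2$gene, c("gA", "gB"))

  ev_bad <- data.frame(tf = "tf1", chrom = "chr1", position = NA,
                       p_value = 0.1)
  expect_error(assign_binding(ev_bad, gm), class = "egrinet_parse_error")
})

test_that("cluster binding score calls match full enumeration", {
  universe <- sprintf("g%02d", 1:15)
  cluster <- universe[1:3]
  binding_p <- setNames(c(1e-6, 1e-5, 1e-4, 0.5, 0.9), universe[1:5])

  call <- binding_cluster_call(cluster, binding_p, universe,
                               n_resamples = 2000, seed = 3)
  ## oracle: enumerate all choose(15, 3) = 455 gene sets
  scores <- setNames(rep(0, 15), universe)
  scores[names(binding_p)] <- -log10(binding_p)
  combos <- combn(15, 3)
  bg <- apply(combos, 2, function(i) sum(scores[i]))
  exact_call <- mean(bg < call$score) > 0.95
  expect_identical(call$regulated, exact_call)
  expect_true(call$regulated)  # the three best-bound genes

  ## no bound genes: score 0, tie against assignment
  none <- binding_cluster_call(universe[10:12],
                               setNames(numeric(0), character(0)),
                               universe[10:15], n_resamples = 500, seed = 1)
  expect_equal(none$score, 0)
  expect_false(none$regulated)
})

test_that("de-novo motif assignments expand to cluster genes", {
  clusters <- list(c1 = sprintf("g%02d", 1:8), c2 = sprintf("g%02d", 9:12))
  df <- data.frame(regulator = c("tfA", "tfA", "tfB", "tfA"),
                   cluster = c("c1", "c2", "c1", "c1"),
                   p = c(0.01, 0.06, 0.04, 0.01))
  edges <- import_denovo_assignments(df, clusters)
  ## 0.06 filtered; duplicate (tfA, c1) rows collapse; 8 + 8 edges
  expect_identical(nrow(edges), 16L)
  expect_identical(sum(edges$regulator == "tfA"), 8L)
  expect_true(all(edges$stream == "denovo-motif"))
  expect_false(any(duplicated(paste(edges$regulator, edges$target))))

  expect_error(import_denovo_assignments(
    data.frame(regulator = "tfA", cluster = "nope", p = 0.01), clusters),
    class = "egrinet_parse_error")
})

test_that("evidence integration enforces the two-stream rule", {
  e <- rbind(
    evidence_edges("tfA", "g1", "binding", 0.001),
    evidence_edges("tfA", "g1", "deletion-DE", 0.01,
                   direction = "activation", condition = "LO"),
    evidence_edges("tfA", "g2", "binding", 0.001),
    evidence_edges("tfB", "g3", "shattering", 0.002, condition = "LO"),
    evidence_edges("tfB", "g3", "known-motif", 0.004),
    evidence_edges("tfB", "g3", "denovo-motif", 0.0001)
  )
  net <- integrate_evidence(e, min_streams = 2)
  keys <- paste(net$regulator, net$target)
  expect_true("tfA g1" %in% keys)   # binding + deletion-DE
  expect_false("tfA g2" %in% keys)  # binding alone
  expect_true("tfB g3" %in% keys)   # three streams
  expect_identical(net$direction[net$regulator == "tfA"], "activation")
  expect_gte(min(net$n_streams), 2L)

  ## stronger support gives larger weight
  e2 <- rbind(
    evidence_edges("tfC", "g4", "binding", 1e-6),
    evidence_edges("tfC", "g4", "known-motif", 1e-6),
    evidence_edges("tfC", "g5", "binding", 0.04),
    evidence_edges("tfC", "g5", "known-motif", 0.04)
  )
  net2 <- integrate_evidence(e2)
  expect_gt(net2$weight[net2$target == "g4"],
            net2$weight[net2$target == "g5"])

  ## invariant to input edge order
  shuffled <- e[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(integrate_evidence(shuffled, min_streams = 2), net)
})
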