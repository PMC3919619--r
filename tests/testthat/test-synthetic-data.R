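# The synthetic regulatory system: determinism, contracts, and the
# statistical structure the pipeline assumes.

test_that("ground truth is deterministic and honours the configuration", {
  cfg <- tiny_config(seed = 42)
  t1 <- generate_ground_truth(cfg)
  t2 <- generate_ground_truth(cfg)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- generate_ground_truth(tiny_config(seed = 43))
  expect_false(identical(t1$edges, t3$edges))

  sizes <- vapply(t1$modules, function(m) length(m$genes), 1L)
  expect_true(all(sizes >= cfg$module_size_range[1] &
                    sizes <= cfg$module_size_range[2]))
  expect_length(t1$regulators, cfg$n_regulators)
  expect_true(all(t1$edges$regulator %in% t1$regulators))
  expect_true(all(unlist(lapply(t1$programs, names)) %in% t1$regulators))
  ## every module's program has at least one nonzero coefficient
  expect_true(all(vapply(t1$modules, function(m)
    any(m$program != 0), TRUE)))
  ## planted sites stay inside the promoter window
  expect_true(all(t1$planted_sites$offset >= -cfg$promoter_upstream))
  expect_true(all(t1$planted_sites$offset + cfg$motif_length <=
                    cfg$promoter_downstream))
  ## the engineered annotation overlaps the annotated modules
  perox <- t1$annotation_sets$peroxisome_like
  expect_true(all(t1$modules[[1]]$genes %in% perox))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes",
               class = "egrinet_config_error")
  expect_error(sim_config(module_size_range = c(40, 10)),
               "module_size_range", class = "egrinet_config_error")
  expect_error(sim_config(noise_sd = -1), "noise_sd",
               class = "egrinet_config_error")
  expect_error(sim_config(n_genes = 50, n_regulators = 60),
               "n_regulators", class = "egrinet_config_error")
  expect_error(sim_config(motif_length = 5000), "motif_length",
               class = "egrinet_config_error")
})

test_that("expression realizes programs exactly at zero noise", {
  cfg <- tiny_config(seed = 7, noise_sd = 0)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  X <- ex$values[truth$regulators, ]
  Y <- truth$coefficients %*% X
  targets <- setdiff(truth$genes, truth$regulators)
  expect_equal(ex$values[targets, ], Y[targets, ], tolerance = 1e-12)
  ## column counts: compendium plus the configured blocks
  expect_identical(sum(ex$meta$set == "compendium"),
                   cfg$n_compendium_experiments)
  expect_identical(sum(ex$meta$set == "condition"), 22L)
})

test_that("modules are coherent exactly in their active conditions", {
  cfg <- medium_config(seed = 5)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  zn <- zscore_normalize(ex)
  ## the annotated module is active under all named blocks; compare its
  ## within-experiment variance to random gene sets (direct computation)
  m <- truth$modules[[1]]
  act <- ex$meta$experiment[ex$meta$condition %in% m$conditions]
  inact <- ex$meta$experiment[!ex$meta$condition %in% m$conditions]
  v_act <- apply(zn$values[m$genes, act], 2, var)
  v_inact <- apply(zn$values[m$genes, inact], 2, var)
  set.seed(99)
  bg <- replicate(300, apply(zn$values[
    sample(truth$genes, length(m$genes)), ], 2, var))
  thr5 <- apply(bg, 1, quantile, 0.05)  # per-experiment 5th percentile
  ## coherent (below the random 5th percentile) in the clear majority of
  ## active-condition experiments, and not so elsewhere
  expect_gt(mean(v_act < thr5[act]), 0.6)
  expect_lt(mean(v_inact < thr5[inact]), 0.5)
  expect_gt(mean(v_act < thr5[act]), mean(v_inact < thr5[inact]) + 0.25)
})

test_that("deletion profiles propagate knockout effects with the right signs", {
  cfg <- tiny_config(seed = 3)
  truth <- generate_ground_truth(cfg)
  r <- truth$modules[[1]]$regulators[1]
  cond <- truth$modules[[1]]$conditions[1]
  del <- simulate_deletion(truth, r, cond)
  expect_identical(unname(del$profile[r, 1]), cfg$knockout_value)

  ## targets shift opposite to sign(beta) (knockout drives activity low)
  targets <- truth$edges[truth$edges$regulator == r, ]
  strong <- targets[abs(targets$beta) > 1, ]
  shift_dir <- sign(del$profile[strong$target, 1])
  x_wt <- truth$reg_levels[r, cond]
  expected_dir <- sign(strong$beta * (cfg$knockout_value - x_wt))
  expect_gt(mean(shift_dir == expected_dir), 0.9)

  expect_error(simulate_deletion(truth, "not-a-gene", cond),
               class = "egrinet_lookup_error")
})

test_that("non-target deletion responses are centred at zero", {
  cfg <- tiny_config(seed = 8)
  truth <- generate_ground_truth(cfg)
  r <- truth$regulators[2]
  non_targets <- setdiff(truth$genes,
                         c(truth$true_binding[[r]], truth$regulators))
  del <- simulate_deletion(truth, r, "LS", n_replicates = 100)
  means <- rowMeans(del$profile[non_targets, ])
  ## analytic expectation 0; the mean of 100 replicates has sd noise_sd/10
  expect_lt(abs(means[[1]]), 3 * cfg$noise_sd / sqrt(100))
  expect_true(all(abs(means) < 4.5 * cfg$noise_sd / sqrt(100)))
})

test_that("promoters carry planted sites and calibrated binding p-values", {
  cfg0 <- tiny_config(seed = 9, corruption = 0)
  truth <- generate_ground_truth(cfg0)
  sim <- simulate_binding_and_promoters(truth, cfg0)
  expect_true(all(nchar(sim$promoters) ==
                    cfg0$promoter_upstream + cfg0$promoter_downstream))
  ## zero corruption: every planted site spells the consensus exactly
  site <- truth$planted_sites[1:25, ]
  for (i in seq_len(nrow(site))) {
    cons <- pwm_consensus(truth$motif_library[[site$regulator[i]]])
    start <- site$offset[i] + cfg0$promoter_upstream + 1L
    expect_identical(substr(sim$promoters[[site$gene[i]]], start,
                            start + nchar(cons) - 1L), cons)
  }
  ## true-target events have low p, decoys are uniform
  only_true <- simulate_binding_and_promoters(truth, cfg0,
                                              decoys_per_regulator = 0)
  expect_lt(median(only_true$events$p_value), 0.01)
  true_keys <- paste(only_true$events$tf, only_true$events$position)
  decoy_p <- sim$events$p_value[!paste(sim$events$tf, sim$events$position)
                                %in% true_keys]
  expect_gt(median(decoy_p), 0.35)
  expect_lt(median(decoy_p), 0.65)
})
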