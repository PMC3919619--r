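# Multi-seed recovery benchmarks over the synthetic study conditions.

#' Run the full analysis over several seeds and tabulate recovery
#'
#' Executes [egrin_analysis()] once per seed under the study conditions
#' (the [sim_config()] defaults unless overridden) and collects the
#' evaluation quantities: edge precision/recall at Level 1, after the
#' Level-2 filters, and for the integrated >= 2-stream network; gene- and
#' cluster-level classifier metrics; sign-agreement metrics; the rank of
#' the annotated module's true regulator; and the shattering detections.
#'
#' @param seeds integer vector of simulation seeds.
#' @param config_fn function(seed) returning the [sim_config()] to run.
#' @param ... further arguments passed to [egrin_analysis()].
#' @param verbose print one line per completed seed.
#' @return data frame with one row per seed.
#' @export
egrin_benchmark <- function(seeds = 1:10,
                            config_fn = function(s) sim_config(seed = s),
                            ..., verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    cfg <- config_fn(s)
    res <- egrin_analysis(cfg, fit = fit_config(seed = s), ...)
    ev <- res$evaluation
    if (verbose)
      message(sprintf("seed %d: level1 P/R %.2f/%.2f integrated P %.2f rank %d",
                      s, ev$level1_precision, ev$level1_recall,
                      ev$integrated_precision, ev$best_primary_rank))
    data.frame(
      seed = s,
      level1_precision = ev$level1_precision,
      level1_recall = ev$level1_recall,
      filtered_precision = ev$filtered_precision,
      filtered_recall = ev$filtered_recall,
      integrated_precision = ev$integrated_precision,
      integrated_recall = ev$integrated_recall,
      n_integrated = ev$n_integrated,
      gene_mcc = ev$gene_mcc, gene_f1 = ev$gene_f1, gene_auc = ev$gene_auc,
      cluster_mcc = ev$cluster_mcc, cluster_f1 = ev$cluster_f1,
      cluster_auc = ev$cluster_auc,
      agreement = ev$agreement, correlation = ev$correlation,
      agreement_fix = ev$agreement_fix,
      correlation_fix = ev$correlation_fix,
      best_primary_rank = ev$best_primary_rank,
      shattering_true_detected = ev$shattering_true_detected,
      shattering_null_first = ev$shattering_null_first,
      shattering_null_rate = ev$shattering_null_rate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise-free identity check
#'
#' Under the idealized system (no expression noise, no site corruption, no
#' indirect knockout heterogeneity), fits every program with a light fixed
#' penalty and verifies exact recovery: every true edge recovered with the
#' right sign, predictions reproducing observations, and deletion
#' responses predicted with perfect sign agreement.
#'
#' @param seed simulation seed.
#' @param n_genes,n_regulators,n_modules scaled-down system size (the
#'   identity is exact at any size).
#' @return list with `sign_recovery` (fraction of true edges recovered
#'   with the correct sign), `max_prediction_error`, and
#'   `prediction_agreement` on a regulator deletion.
#' @export
noise_free_check <- function(seed = 1L, n_genes = 300L, n_regulators = 20L,
                             n_modules = 8L) {
  cfg <- sim_config(n_genes = n_genes, n_regulators = n_regulators,
                    n_modules = n_modules, module_size_range = c(6, 12),
                    n_compendium_experiments = 100,
                    noise_sd = 0, corruption = 0, deletion_indirect = 0,
                    seed = seed)
  truth <- generate_ground_truth(cfg)
  ex <- simulate_expression(truth, cfg)
  comp <- subset_experiments(ex, set = "compendium")
  targets <- setdiff(truth$genes, truth$regulators)
  progs <- fit_programs(comp, targets, truth$regulators,
                        fit_config(penalty_selection = 0,
                                   prune_fraction = 0.1, seed = seed))
  edges <- program_edges(progs)

  ## every true edge present with the true coefficient's sign
  key <- paste(edges$regulator, edges$target)
  tkey <- paste(truth$edges$regulator, truth$edges$target)
  found <- match(tkey, key)
  sign_ok <- !is.na(found) &
    sign(edges$beta[found]) == sign(truth$edges$beta)
  ## predictions reproduce observations
  regv <- comp$values[truth$regulators, ]
  errs <- vapply(targets, function(g)
    max(abs(predict_expression(progs[[g]], regv) - comp$values[g, ])),
    numeric(1))
  ## deletion responses predicted through the full equations
  r <- truth$modules[[1]]$regulators[1]
  del <- simulate_deletion(truth, r, truth$modules[[1]]$conditions[1], cfg)
  targets_r <- truth$true_binding[[r]]
  pm <- prediction_metrics(progs[targets_r],
                           del$profile[truth$regulators, 1],
                           del$profile[targets_r, 1])
  list(sign_recovery = mean(sign_ok),
       max_prediction_error = max(errs),
       prediction_agreement = pm$prediction_agreement)
}
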