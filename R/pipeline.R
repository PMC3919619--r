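# Three-level pipeline orchestration over the synthetic system.
#
# Level 1: normalize -> cluster -> coherence -> compendium programs -> rank.
# Level 2: significance / accuracy / coherence filters -> condition-specific
#          programs -> condition-priority combination -> re-rank.
# Level 3: deletion, shattering, binding and motif evidence for the probed
#          regulators -> >= 2-stream integration -> gene-level network.

#' Vectorized shuffle significance for many (predicted, observed) rows
#'
#' Same definition as [correlation_significance()], sharing one set of
#' experiment shuffles across all rows (the background shuffles experiments,
#' not genes).
#' @noRd
correlation_significance_rows <- function(pred, obs, n_shuffles = 1000L,
                                          seed = 1L) {
  n <- ncol(pred)
  zp <- pred - rowMeans(pred)
  zo <- obs - rowMeans(obs)
  sp <- sqrt(rowSums(zp^2))
  so <- sqrt(rowSums(zo^2))
  degenerate <- sp == 0 | so == 0
  sp[sp == 0] <- 1; so[so == 0] <- 1
  zp <- zp / sp; zo <- zo / so
  r <- rowSums(zp * zo)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) sample.int(n), integer(n))
  })
  exceed <- integer(nrow(pred))
  for (i in seq_len(n_shuffles)) {
    exceed <- exceed + (rowSums(zp * zo[, perms[, i], drop = FALSE]) >= r)
  }
  p <- empirical_p(exceed, n_shuffles)
  r[degenerate] <- NA_real_
  p[degenerate] <- 1
  data.frame(target = rownames(pred), r = r, p = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Predicted values for a program set over a set of experiments
#' @noRd
predict_program_matrix <- function(programs, regulator_values) {
  t(vapply(programs, function(p)
    predict_expression(p, regulator_values),
    numeric(ncol(regulator_values))))
}

#' Bicluster-regulation p-values for many (regulator, cluster) pairs
#' @noRd
regulation_p_table <- function(programs, clusters, universe,
                               n_resamples = 1000L, seed = 1L,
                               cutoff = 0.05) {
  edges <- program_edges(programs)
  targets_by_reg <- split(edges$target, edges$regulator)
  grid <- expand.grid(regulator = names(targets_by_reg),
                      cluster = names(clusters), stringsAsFactors = FALSE)
  if (nrow(grid) == 0L)
    return(data.frame(regulator = character(), cluster = character(),
                      p = numeric(), called = logical()))
  ## same construction as assign_predictions_to_bicluster, drawing all
  ## backgrounds from one seeded stream in a fixed pair order
  grid <- grid[order(grid$regulator, grid$cluster), ]
  N <- length(universe)
  grid$p <- withr::with_seed(derive_seed(seed, 7000L), {
    vapply(seq_len(nrow(grid)), function(i) {
      tg <- intersect(targets_by_reg[[grid$regulator[i]]], universe)
      cl <- intersect(clusters[[grid$cluster[i]]], universe)
      observed <- length(intersect(tg, cl))
      draws <- rhyper(n_resamples, length(tg), N - length(tg), length(cl))
      empirical_p(sum(draws >= observed), n_resamples)
    }, numeric(1))
  })
  grid$called <- grid$p <= cutoff
  rownames(grid) <- NULL
  grid
}

#' Run the full three-level analysis on a synthetic system
#'
#' Generates the ground truth and every input, runs the three levels, and
#' evaluates all results against the truth. This is the engine behind the
#' analysis drivers, the acceptance benchmarks and [run_pipeline()].
#'
#' @param config an [sim_config()]; its seed pins the whole run.
#' @param fit an [fit_config()] for the program fits.
#' @param alpha FDR / call level used throughout.
#' @param coherence_resamples,assign_resamples empirical background sizes.
#' @param k number of clusters; the default adds ~20% slack clusters over
#'   the planted module count so genes outside any co-regulated module can
#'   settle into their own (incoherent) clusters instead of polluting
#'   module clusters.
#' @param min_streams integration support threshold.
#' @param n_null_probes negative-control regulators carried through the
#'   Level-3 experiments.
#' @param annotation annotation set to rank regulators for.
#' @return a list of all intermediate objects and evaluation results (see
#'   the `evaluation` element for the headline numbers).
#' @export
egrin_analysis <- function(config = sim_config(),
                           fit = fit_config(seed = config$seed),
                           alpha = 0.05,
                           coherence_resamples = 1000L,
                           assign_resamples = 1000L,
                           k = config$n_modules + ceiling(config$n_modules / 5),
                           min_streams = 2L,
                           n_null_probes = 3L,
                           annotation = "peroxisome_like") {
  truth <- generate_ground_truth(config)
  exprs <- simulate_expression(truth, config)
  znorm <- zscore_normalize(exprs)
  comp <- subset_experiments(znorm, set = "compendium")
  cond <- subset_experiments(znorm, set = "condition")
  named_conditions <- truth$named_conditions
  targets <- setdiff(truth$genes, truth$regulators)

  ## ---- Level 1 -------------------------------------------------------
  programs_comp <- fit_programs(comp, targets, truth$regulators, fit,
                                provenance = "compendium")
  edges_comp <- program_edges(programs_comp)

  clusters <- refine_clusters(
    cluster_genes(znorm, k, seed = derive_seed(config$seed, 50L)), znorm)
  biclusters <- make_biclusters(clusters, znorm, truth$annotation_sets,
                                n_resamples = coherence_resamples,
                                alpha = alpha,
                                seed = derive_seed(config$seed, 51L))
  coherence_counts <- vapply(biclusters, function(b)
    sum(b$condition_coherence[named_conditions]), 1L)

  enrichment <- annotation_enrichment_table(
    clusters, truth$annotation_sets[annotation], rownames(znorm$values))
  enriched_clusters <- enrichment$cluster[enrichment$p_adjusted <= alpha]

  regulation_p1 <- regulation_p_table(programs_comp, clusters, targets,
                                      assign_resamples,
                                      seed = derive_seed(config$seed, 52L),
                                      cutoff = alpha)
  rank1 <- score_regulators(regulation_p1, enriched_clusters,
                            coherence_counts, truth$regulators,
                            cutoff = alpha)

  ## ---- Level 2 -------------------------------------------------------
  sig_model <- fit_change_model(cond$values, "normal-fit")
  changing <- tryCatch(
    filter_to_changing(cond, truth$regulators, sig_model, alpha),
    egrinet_empty_error = function(e)
      list(targets = character(), regulators = character(), flags = NULL))

  ## filter 2 machinery: prediction accuracy on the condition experiments
  reg_cond <- cond$values[truth$regulators, , drop = FALSE]
  nonempty <- names(Filter(function(p) length(p$terms) > 0, programs_comp))
  accuracy <- if (length(nonempty) > 0) {
    pred <- predict_program_matrix(programs_comp[nonempty], reg_cond)
    correlation_significance_rows(pred,
                                  cond$values[nonempty, , drop = FALSE],
                                  n_shuffles = 1000L,
                                  seed = derive_seed(config$seed, 53L))
  } else data.frame(target = character(), r = numeric(), p = numeric(),
                    degenerate = logical())
  accurate_targets <- accuracy$target[accuracy$p <= alpha]

  ## filter 1: keep significantly changing targets; the regulator-side
  ## restriction acts where the condition data are refit (programs_cond),
  ## not as surgery on the compendium programs, whose coefficients the
  ## combination keeps wherever no condition coefficient exists
  f1 <- programs_comp[intersect(names(programs_comp), changing$targets)]
  ## filter 2: keep accurately predicted targets
  f12 <- f1[intersect(names(f1), accurate_targets)]
  ## filter 3: targets inside condition-coherent clusters
  coherent_cluster_ids <- names(biclusters)[vapply(biclusters, function(b)
    any(b$condition_coherence[named_conditions]), TRUE)]
  coherent_genes <- unique(unlist(clusters[coherent_cluster_ids]))
  f123 <- f12[intersect(names(f12), coherent_genes)]

  cond_targets <- intersect(changing$targets, targets)
  programs_cond <- if (length(cond_targets) > 0 &&
                       length(changing$regulators) >= 2L) {
    fit_programs(cond, cond_targets, changing$regulators, fit,
                 provenance = "condition-specific")
  } else {
    structure(list(), class = "egrin_program_set")
  }
  combined <- combine_program_sets(f123, programs_cond)
  edges_combined <- program_edges(combined)
  edges_filtered <- program_edges(f123)

  ## the Level-2 ranking sees only condition-relevant factors: the
  ## changing-genes filter removes non-changing regulators from this
  ## analysis (the combined programs below still carry their compendium
  ## coefficients for the gene-level evidence)
  combined_ranked <- lapply(combined, function(p) {
    keep <- names(p$terms) %in% changing$regulators
    new_program(p$target, p$terms[keep], p$intercept, p$provenance)
  })
  regulation_p2 <- regulation_p_table(combined_ranked, clusters, targets,
                                      assign_resamples,
                                      seed = derive_seed(config$seed, 54L),
                                      cutoff = alpha)
  rank2 <- score_regulators(regulation_p2, enriched_clusters,
                            coherence_counts, truth$regulators,
                            cutoff = alpha)

  ## ---- Level 3 -------------------------------------------------------
  annotated <- Filter(function(m) isTRUE(m$annotated), truth$modules)
  true_primaries <- unique(vapply(annotated, function(m) m$regulators[1], ""))
  top5 <- head(rank2$regulator, 5L)
  zero_score <- rank2$regulator[rank2$score == 0]
  null_pool <- setdiff(if (length(zero_score) > 0) zero_score
                       else rev(rank2$regulator),
                       unique(unlist(lapply(annotated, `[[`, "regulators"))))
  null_probes <- head(null_pool, n_null_probes)
  probes <- unique(c(top5, true_primaries, null_probes))

  cond_raw <- subset_experiments(exprs, set = "condition")
  deletions <- list()
  de_tables <- list()
  evidence <- list()
  for (r in probes) {
    per_cond <- list()
    for (cc in named_conditions) {
      del <- simulate_deletion(truth, r, cc, config)
      deletions[[paste(r, cc, sep = ".")]] <- del
      de <- deletion_de(del)
      per_cond[[cc]] <- de
      sig <- de[p.adjust(de$p, "BH") <= alpha, , drop = FALSE]
      if (nrow(sig) > 0) {
        evidence[[length(evidence) + 1L]] <- evidence_edges(
          r, sig$gene, "deletion-DE", sig$p, direction = sig$direction,
          strength = ifelse(sig$p <= 0.01, "strong", "weak"),
          condition = cc)
      }
    }
    ## per regulator: a gene's deletion response is its strongest across
    ## the profiled conditions
    all_cond <- do.call(rbind, per_cond)
    best <- all_cond[order(all_cond$gene, all_cond$p), ]
    de_tables[[r]] <- best[!duplicated(best$gene), ]
  }
  truth_table <- deletion_truth_table(de_tables, alpha)

  ## shattering (computed on the raw ratio scale); the wild-type variance
  ## background always covers exactly the genes scored in the deletion
  wt_vars <- lapply(clusters, cluster_wildtype_variances, exprs = cond_raw)
  shatter_calls <- list()
  for (r in probes) {
    for (cc in named_conditions) {
      del <- deletions[[paste(r, cc, sep = ".")]]
      for (cl in names(clusters)) {
        ## only a cluster that is coherent under this condition in the
        ## wild type can lose that coherence to a deletion
        if (!isTRUE(biclusters[[cl]]$condition_coherence[cc])) next
        genes_cl <- setdiff(clusters[[cl]], r)
        if (length(genes_cl) < 2L) next
        wv <- if (r %in% clusters[[cl]])
          cluster_wildtype_variances(genes_cl, cond_raw) else wt_vars[[cl]]
        st <- shattering_test(del$values[genes_cl, 1L], wv)
        shatter_calls[[length(shatter_calls) + 1L]] <- data.frame(
          regulator = r, cluster = cl, condition = cc, p = st$p,
          shattered = st$shattered, stringsAsFactors = FALSE)
        if (st$shattered) {
          ## a gene in several shattered clusters keeps its minimum p
          ## downstream (integration takes the per-stream minimum)
          evidence[[length(evidence) + 1L]] <- evidence_edges(
            r, genes_cl, "shattering", st$p, condition = cc)
        }
      }
    }
  }
  shatter_calls <- if (length(shatter_calls) > 0) do.call(rbind, shatter_calls)
    else data.frame(regulator = character(), cluster = character(),
                    condition = character(), p = numeric(),
                    shattered = logical())

  ## direct evidence: binding, known motifs, imported de-novo motifs
  binding_sim <- simulate_binding_and_promoters(truth, config,
                                                regulators = probes)
  bound <- assign_binding(binding_sim$events, binding_sim$gene_models,
                          upstream = config$promoter_upstream,
                          downstream = config$promoter_downstream)
  if (nrow(bound) > 0) {
    evidence[[length(evidence) + 1L]] <- evidence_edges(
      bound$regulator, bound$gene, "binding", bound$p,
      strength = bound$strength)
  }
  prom_codes <- promoter_codes(binding_sim$promoters)
  for (r in probes) {
    calls <- scan_promoters(binding_sim$promoters, binding_sim$pwms[[r]],
                            codes = prom_codes)
    hit <- calls[calls$called, , drop = FALSE]
    if (nrow(hit) > 0) {
      evidence[[length(evidence) + 1L]] <- evidence_edges(
        r, hit$gene, "known-motif", hit$p)
    }
  }
  denovo <- simulate_denovo_assignments(truth, clusters, probes,
                                        seed = derive_seed(config$seed, 55L))
  denovo_edges <- import_denovo_assignments(denovo, clusters,
                                            cutoff = alpha)
  if (nrow(denovo_edges) > 0)
    evidence[[length(evidence) + 1L]] <- denovo_edges

  ## influence stream: combined programs for the probed regulators,
  ## weighted by the target's prediction-accuracy p
  acc_p <- setNames(accuracy$p, accuracy$target)
  infl <- edges_combined[edges_combined$regulator %in% probes, , drop = FALSE]
  if (nrow(infl) > 0) {
    p_infl <- acc_p[infl$target]
    p_infl[is.na(p_infl)] <- 1
    evidence[[length(evidence) + 1L]] <- evidence_edges(
      infl$regulator, infl$target, "influence", as.numeric(p_infl),
      direction = ifelse(infl$beta > 0, "activation", "repression"))
  }

  evidence <- do.call(rbind, evidence)
  network <- integrate_evidence(evidence, min_streams = min_streams)

  ## ---- Evaluation ----------------------------------------------------
  truth_probe_edges <- truth$edges[truth$edges$regulator %in% probes, ]
  net_pairs <- unique(network[, c("regulator", "target")])
  integrated_pr <- edge_precision_recall(net_pairs, truth_probe_edges)
  level1_pr <- edge_precision_recall(edges_comp, truth$edges)
  filtered_pr <- edge_precision_recall(edges_filtered, truth$edges)

  ## the gene- vs cluster-level classifier comparison evaluates the plain
  ## inference output (Level 1), aggregated or not — the condition filters
  ## are a separate axis and are scored by the precision comparison above
  na_conf <- list(mcc = NA_real_, f1 = NA_real_, auc = NA_real_,
                  tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  gene_conf <- tryCatch(
    gene_level_confusion(
      edges_comp[edges_comp$regulator %in% probes, ], truth_table,
      universe = intersect(changing$targets, targets)),
    egrinet_error = function(e) na_conf)

  truth_calls <- expand.grid(regulator = probes, cluster = names(clusters),
                             stringsAsFactors = FALSE)
  truth_calls$p <- vapply(seq_len(nrow(truth_calls)), function(i) {
    sig <- truth_table$gene[truth_table$regulator ==
                              truth_calls$regulator[i] &
                              truth_table$significant]
    deletion_cluster_call(sig, clusters[[truth_calls$cluster[i]]],
                          targets)
  }, numeric(1))
  truth_calls$significant <- p.adjust(truth_calls$p, "BH") <= alpha
  ## both sides of the cluster-level confusion are FDR-adjusted over the
  ## same (probe, cluster) family
  rp_probes <- regulation_p1[regulation_p1$regulator %in% probes, ]
  rp_probes$called <- p.adjust(rp_probes$p, "BH") <= alpha
  cluster_conf <- tryCatch(
    cluster_level_confusion(
      rp_probes, truth_calls[, c("regulator", "cluster", "significant")]),
    egrinet_error = function(e) na_conf)

  sign_metrics <- fixed_metrics(
    edges_combined[edges_combined$regulator %in% probes, ], truth_table,
    alpha = alpha)

  ## true-regulator recovery
  primary_ranks <- rank2$rank[match(true_primaries, rank2$regulator)]

  ## shattering detection on the clusters matching the annotated modules;
  ## the false-positive rate is measured only on verified-clean probes
  ## (no true edge into the matched cluster)
  shatter_eval <- shattering_recovery(annotated, clusters, shatter_calls,
                                      null_probes, truth)

  evaluation <- list(
    level1_precision = level1_pr$precision,
    level1_recall = level1_pr$recall,
    filtered_precision = filtered_pr$precision,
    filtered_recall = filtered_pr$recall,
    integrated_precision = integrated_pr$precision,
    integrated_recall = integrated_pr$recall,
    n_integrated = nrow(net_pairs),
    gene_mcc = gene_conf$mcc, gene_f1 = gene_conf$f1,
    gene_auc = gene_conf$auc,
    cluster_mcc = cluster_conf$mcc, cluster_f1 = cluster_conf$f1,
    cluster_auc = cluster_conf$auc,
    agreement = sign_metrics$agreement,
    correlation = sign_metrics$correlation,
    agreement_fix = sign_metrics$agreement_fix,
    correlation_fix = sign_metrics$correlation_fix,
    best_primary_rank = min(primary_ranks),
    primary_ranks = primary_ranks,
    shattering_true_detected = shatter_eval$true_detected,
    shattering_null_rate = shatter_eval$null_rate,
    shattering_null_first = shatter_eval$null_first
  )

  list(truth = truth, exprs = exprs, znorm = znorm,
       programs_comp = programs_comp, programs_cond = programs_cond,
       combined = combined, clusters = clusters, biclusters = biclusters,
       enrichment = enrichment, enriched_clusters = enriched_clusters,
       regulation_p1 = regulation_p1, regulation_p2 = regulation_p2,
       rank1 = rank1, rank2 = rank2, changing = changing,
       accuracy = accuracy, sig_model = sig_model,
       probes = probes, null_probes = null_probes,
       true_primaries = true_primaries,
       deletions = deletions, truth_table = truth_table,
       shatter_calls = shatter_calls, binding_sim = binding_sim,
       evidence = evidence, network = network,
       evaluation = evaluation, config = config, fit = fit)
}

#' Shattering recovery on annotated modules
#'
#' `true_detected`: did the primary regulator's deletion shatter the
#' cluster matching its module in at least one condition? `null_rate`:
#' per-test shattering frequency over (null probe, condition, matched
#' cluster) combinations. `null_first`: outcome of the single first null
#' test (one probe, one condition, one cluster).
#' @noRd
shattering_recovery <- function(annotated, clusters, shatter_calls,
                                null_probes, truth) {
  if (length(annotated) == 0L || nrow(shatter_calls) == 0L)
    return(list(true_detected = NA, null_rate = NA, null_first = NA))
  ## cluster best matching each annotated module
  match_cluster <- vapply(annotated, function(m) {
    ov <- vapply(clusters, function(g) length(intersect(g, m$genes)), 1L)
    names(clusters)[which.max(ov)]
  }, "")
  true_detected <- any(vapply(seq_along(annotated), function(i) {
    r <- annotated[[i]]$regulators[1]
    any(shatter_calls$shattered[shatter_calls$regulator == r &
                                  shatter_calls$cluster == match_cluster[i]])
  }, TRUE))
  ## a probe is clean for a cluster when it truly regulates none of its
  ## genes (zero-score probes can still be private regulators)
  clean <- vapply(seq_len(nrow(shatter_calls)), function(i) {
    r <- shatter_calls$regulator[i]
    cl <- shatter_calls$cluster[i]
    r %in% null_probes && cl %in% match_cluster &&
      !any(clusters[[cl]] %in% truth$true_binding[[r]])
  }, TRUE)
  null_tests <- shatter_calls[clean, , drop = FALSE]
  list(true_detected = true_detected,
       null_rate = if (nrow(null_tests) > 0) mean(null_tests$shattered)
                   else NA,
       null_first = if (nrow(null_tests) > 0) null_tests$shattered[1]
                    else NA)
}

#' Emulated de-novo motif assignments
#'
#' Stands in for an external de-novo motif discovery run: clusters
#' dominated by a regulator's true binding targets receive a low p row for
#' that regulator; every other (regulator, cluster) pair occasionally
#' appears as a uniform-p decoy row. The output is the TSV-shaped table
#' [import_denovo_assignments()] consumes.
#'
#' @param truth `egrin_truth`.
#' @param clusters named list of gene sets.
#' @param regulators regulators the discovery step covered.
#' @param seed seed.
#' @param dominance fraction of a cluster that must be true targets.
#' @return data frame: regulator, cluster, p.
#' @export
simulate_denovo_assignments <- function(truth, clusters, regulators,
                                        seed = 1L, dominance = 0.5) {
  withr::with_seed(seed, {
    rows <- list()
    for (r in regulators) {
      tg <- truth$true_binding[[r]]
      for (cl in names(clusters)) {
        frac <- length(intersect(tg, clusters[[cl]])) /
          length(clusters[[cl]])
        if (frac >= dominance) {
          rows[[length(rows) + 1L]] <- data.frame(
            regulator = r, cluster = cl, p = rbeta(1, 1, 50),
            stringsAsFactors = FALSE)
        } else if (runif(1) < 0.05) {
          rows[[length(rows) + 1L]] <- data.frame(
            regulator = r, cluster = cl, p = runif(1),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L)
      return(data.frame(regulator = character(), cluster = character(),
                        p = numeric()))
    do.call(rbind, rows)
  })
}

#' Pipeline configuration
#'
#' @param sim an [sim_config()].
#' @param out_dir run directory every artifact is written into.
#' @param alpha FDR / call level used throughout.
#' @param coherence_resamples,assign_resamples empirical background sizes.
#' @param fit an [fit_config()].
#' @param min_streams integration support threshold.
#' @param feedback after Level 3, append the condition-specific and
#'   deletion experiments to the compendium and refit the compendium
#'   programs (the model-improvement feedback loop).
#' @return a `egrin_pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir,
                            alpha = 0.05, coherence_resamples = 1000L,
                            assign_resamples = 1000L,
                            fit = fit_config(seed = sim$seed),
                            min_streams = 2L, feedback = FALSE) {
  structure(list(sim = sim, out_dir = out_dir, alpha = alpha,
                 coherence_resamples = as.integer(coherence_resamples),
                 assign_resamples = as.integer(assign_resamples),
                 fit = fit, min_streams = as.integer(min_streams),
                 feedback = feedback),
            class = "egrin_pipeline_config")
}

#' Run the pipeline and write a reproducible run directory
#'
#' Executes [egrin_analysis()] under the given configuration, writes every
#' artifact (inputs, programs, clusters, coherence report, rankings,
#' evidence, integrated network, evaluation metrics) into `out_dir`, and
#' records a machine-readable manifest with the configuration, seeds,
#' per-stage row counts and file checksums. Re-running with an identical
#' configuration reproduces the manifest byte for byte.
#'
#' @param config an [pipeline_config()].
#' @return the analysis result list, invisibly, with `manifest` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "egrin_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- egrin_analysis(config$sim, fit = config$fit, alpha = config$alpha,
                        coherence_resamples = config$coherence_resamples,
                        assign_resamples = config$assign_resamples,
                        min_streams = config$min_streams)
  out <- config$out_dir
  paths <- simulate_to_dir(res$truth, res$exprs, res$binding_sim, out)

  write_program_tsv(res$programs_comp,
                    file.path(out, "programs_compendium.tsv"))
  if (length(res$programs_cond) > 0)
    write_program_tsv(res$programs_cond,
                      file.path(out, "programs_condition.tsv"))
  if (length(res$combined) > 0)
    write_program_tsv(res$combined, file.path(out, "programs_combined.tsv"))
  write_cluster_tsv(res$clusters, file.path(out, "clusters.tsv"))

  coh <- do.call(rbind, lapply(res$biclusters, function(b) {
    d <- b$coherence
    d$cluster_id <- b$id
    d[, c("cluster_id", "experiment", "p", "coherent")]
  }))
  write.table(coh, file.path(out, "coherence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$rank1, file.path(out, "ranking_level1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$rank2, file.path(out, "ranking_level2.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev <- res$evidence
  ev$p <- fmt_num(ev$p)
  write.table(ev, file.path(out, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_network_sif(res$network, file.path(out, "network.sif"),
                    file.path(out, "network_attributes.json"))
  jsonlite::write_json(res$evaluation,
                       file.path(out, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  programs_final <- res$combined
  if (isTRUE(config$feedback)) {
    ## fold the new experiments back into the compendium and refit
    del_profiles <- do.call(cbind, lapply(res$deletions, function(d)
      d$profile[, 1L]))
    colnames(del_profiles) <- names(res$deletions)
    aug <- cbind(res$exprs$values, del_profiles)
    aug_z <- zscore_normalize(aug)
    targets <- setdiff(res$truth$genes, res$truth$regulators)
    programs_final <- fit_programs(aug_z, targets, res$truth$regulators,
                                   config$fit, provenance = "compendium")
    write_program_tsv(programs_final,
                      file.path(out, "programs_feedback.tsv"))
  }

  files <- sort(list.files(out, recursive = TRUE))
  manifest <- list(
    package = "egrinet",
    version = as.character(utils::packageVersion("egrinet")),
    seed = config$sim$seed,
    config = config$sim[setdiff(names(config$sim), "condition_blocks")],
    condition_blocks = lapply(config$sim$condition_blocks, function(b)
      list(label = b$label, n = b$n)),
    parameters = list(alpha = config$alpha,
                      coherence_resamples = config$coherence_resamples,
                      assign_resamples = config$assign_resamples,
                      mixing = config$fit$mixing,
                      cv_folds = config$fit$cv_folds,
                      min_streams = config$min_streams,
                      feedback = config$feedback),
    stage_counts = list(
      experiments = ncol(res$exprs$values),
      compendium_programs = length(res$programs_comp),
      compendium_edges = sum(vapply(res$programs_comp,
                                    function(p) length(p$terms), 1L)),
      clusters = length(res$clusters),
      changing_genes = length(res$changing$targets),
      condition_programs = length(res$programs_cond),
      combined_edges = nrow(program_edges(programs_final)),
      evidence_edges = nrow(res$evidence),
      integrated_edges = nrow(res$network),
      probes = length(res$probes)
    ),
    checksums = as.list(setNames(
      as.character(tools::md5sum(file.path(out, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$programs_final <- programs_final
  invisible(res)
}
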