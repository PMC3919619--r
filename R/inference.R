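# Elastic-net regulatory program inference and combination.
#
# A regulatory program is the sparse linear equation
#   y = intercept + sum_j beta_j * x_j
# predicting a target's (or a cluster mean's) expression from candidate
# regulator expression. Regulators with positive coefficients are read as
# activators, negative as repressors. Fits are static regressions across
# experiments: the temporal decay term is fixed at zero and no interaction
# ("and") terms are formed.

#' Fit configuration for regulatory program inference
#'
#' @param mixing elastic-net mixing parameter in (0, 1] (1 = lasso).
#' @param penalty_selection `"cv-min"`, `"cv-1se"`, or a fixed non-negative
#'   penalty value.
#' @param cv_folds number of cross-validation folds.
#' @param prune_fraction after shrinkage, terms whose coefficient magnitude
#'   falls below this fraction of the program's largest coefficient are
#'   treated as zero. Cross-validated penalties deliberately under-shrink
#'   (they optimize prediction, not support recovery), leaving a fringe of
#'   near-zero nuisance coefficients; pruning removes it. Set to 0 to keep
#'   every nonzero coefficient.
#' @param gate_alpha FDR level for the significance-of-change gate (used by
#'   pipeline drivers; `NULL` disables gating).
#' @param seed seed controlling fold assignment.
#' @return an object of class `egrin_fit_config`.
#' @export
fit_config <- function(mixing = 0.5, penalty_selection = "cv-min",
                       cv_folds = 5L, prune_fraction = 0.2,
                       gate_alpha = 0.05, seed = 1L) {
  if (!is.numeric(mixing) || mixing <= 0 || mixing > 1)
    egr_stop("mixing must be in (0, 1]", "egrinet_config_error")
  if (is.character(penalty_selection)) {
    penalty_selection <- match.arg(penalty_selection, c("cv-min", "cv-1se"))
  } else if (!is.numeric(penalty_selection) || penalty_selection < 0) {
    egr_stop("penalty_selection must be 'cv-min', 'cv-1se' or a fixed value",
             "egrinet_config_error")
  }
  if (!is.numeric(prune_fraction) || prune_fraction < 0 ||
      prune_fraction >= 1)
    egr_stop("prune_fraction must be in [0, 1)", "egrinet_config_error")
  structure(list(mixing = mixing, penalty_selection = penalty_selection,
                 cv_folds = as.integer(cv_folds),
                 prune_fraction = prune_fraction, gate_alpha = gate_alpha,
                 decay_constant = 0, interaction_terms = FALSE,
                 seed = as.integer(seed)),
            class = "egrin_fit_config")
}

#' Fit one regulatory program
#'
#' Solves the elastic-net problem for a single target over the candidate
#' regulator profiles and stores the regulators with nonzero coefficients.
#' The target is excluded from its own candidate set. A zero-variance target
#' yields an empty program with a warning.
#'
#' @param target_profile numeric vector over experiments.
#' @param regulator_profiles experiments x regulators numeric matrix with
#'   regulator ids as column names.
#' @param config an [fit_config()].
#' @param target id of the target (used to exclude self-regulation).
#' @param provenance label stored on the program
#'   (`"compendium"`/`"condition-specific"`/`"combined"`).
#' @return an object of class `egrin_program`: list with `target`, `terms`
#'   (named nonzero coefficients), `intercept`, `provenance`.
#' @export
fit_program <- function(target_profile, regulator_profiles, config = fit_config(),
                        target = "target", provenance = "compendium") {
  n <- length(target_profile)
  if (nrow(regulator_profiles) != n)
    egr_stop("target and regulator profiles cover different experiments",
             "egrinet_contract_error")
  if (n < config$cv_folds)
    egr_stop("fewer experiments than cross-validation folds",
             "egrinet_config_error")
  keep <- setdiff(colnames(regulator_profiles), target)
  X <- regulator_profiles[, keep, drop = FALSE]
  if (var(target_profile) == 0 || ncol(X) < 2L) {
    if (var(target_profile) == 0)
      warning(sprintf("zero-variance target '%s': empty program", target))
    return(new_program(target, numeric(0), mean(target_profile), provenance))
  }
  lambda <- select_penalty(target_profile, X, config)
  ## tight convergence on the final single-penalty fit: at (near-)zero
  ## penalty the solution must reproduce noise-free data exactly
  fit <- glmnet::glmnet(X, target_profile, alpha = config$mixing,
                        lambda = lambda, standardize = TRUE,
                        thresh = 1e-16, maxit = 1e7)
  beta <- as.numeric(coef(fit))
  names(beta) <- c("(Intercept)", colnames(X))
  terms <- beta[-1L][beta[-1L] != 0]
  if (length(terms) > 0 && config$prune_fraction > 0) {
    terms <- terms[abs(terms) >= config$prune_fraction * max(abs(terms))]
  }
  new_program(target, terms, beta[[1L]], provenance)
}

new_program <- function(target, terms, intercept, provenance) {
  structure(list(target = target, terms = terms, intercept = intercept,
                 provenance = provenance),
            class = "egrin_program")
}

#' Cross-validated penalty over a shared path
#'
#' Lean k-fold CV: one path fit per fold with manual prediction, mean
#' squared error per penalty, ties resolved toward the larger penalty
#' (the sparser model).
#' @noRd
select_penalty <- function(y, X, config) {
  if (is.numeric(config$penalty_selection)) return(config$penalty_selection)
  path <- glmnet::glmnet(X, y, alpha = config$mixing, nlambda = 15,
                         lambda.min.ratio = 0.05, standardize = TRUE)
  lam <- path$lambda
  foldid <- withr::with_seed(config$seed,
                             sample(rep_len(seq_len(config$cv_folds),
                                            length(y))))
  fold_mse <- matrix(NA_real_, config$cv_folds, length(lam))
  for (f in seq_len(config$cv_folds)) {
    test <- foldid == f
    fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                          alpha = config$mixing, lambda = lam,
                          standardize = TRUE)
    k <- length(fit$lambda)
    pred <- as.matrix(X[test, , drop = FALSE] %*% fit$beta) +
      rep(fit$a0, each = sum(test))
    fold_mse[f, seq_len(k)] <- colMeans((y[test] - pred)^2)
  }
  cvm <- colMeans(fold_mse)
  ok <- which(!is.na(cvm))
  i_min <- ok[which.min(cvm[ok])]  # lambda is decreasing: first = sparser
  if (identical(config$penalty_selection, "cv-1se")) {
    cvse <- apply(fold_mse, 2L, sd) / sqrt(config$cv_folds)
    within <- ok[cvm[ok] <= cvm[i_min] + cvse[i_min]]
    return(lam[min(within)])
  }
  lam[i_min]
}

#' @export
print.egrin_program <- function(x, ...) {
  cat(sprintf("program for %s (%s): %d term(s)\n",
              x$target, x$provenance, length(x$terms)))
  if (length(x$terms) > 0) {
    print(round(sort(x$terms, decreasing = TRUE), 3))
  }
  invisible(x)
}

#' Fit regulatory programs for many targets
#'
#' @param exprs `egrin_expression` or genes x experiments matrix.
#' @param targets target gene (or cluster-mean row) ids to fit.
#' @param regulators candidate regulator ids (rows of `exprs`).
#' @param config an [fit_config()].
#' @param provenance provenance label for all fitted programs.
#' @return named list of `egrin_program`s (class `egrin_program_set`).
#' @export
fit_programs <- function(exprs, targets, regulators, config = fit_config(),
                         provenance = "compendium") {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  missing <- setdiff(c(targets, regulators), rownames(values))
  if (length(missing) > 0)
    egr_stop(sprintf("unknown gene '%s'", missing[1]), "egrinet_lookup_error")
  X <- t(values[regulators, , drop = FALSE])
  out <- lapply(setNames(targets, targets), function(g) {
    withCallingHandlers(
      fit_program(values[g, ], X, config, target = g,
                  provenance = provenance),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  class(out) <- c("egrin_program_set", class(out))
  out
}

#' Predict a target's expression from a program
#'
#' @param program an `egrin_program`.
#' @param regulator_values named numeric vector (one experiment) or a
#'   regulators x experiments matrix.
#' @return predicted value(s): `intercept + sum_j beta_j x_j`.
#' @export
predict_expression <- function(program, regulator_values) {
  regs <- names(program$terms)
  if (length(regs) == 0L) {
    n_out <- if (is.matrix(regulator_values)) ncol(regulator_values) else 1L
    return(rep(program$intercept, n_out))
  }
  if (is.matrix(regulator_values)) {
    missing <- setdiff(regs, rownames(regulator_values))
    if (length(missing) > 0)
      egr_stop(sprintf("missing regulator value for '%s'", missing[1]),
               "egrinet_lookup_error")
    return(program$intercept +
             as.numeric(program$terms %*%
                          regulator_values[regs, , drop = FALSE]))
  }
  missing <- setdiff(regs, names(regulator_values))
  if (length(missing) > 0)
    egr_stop(sprintf("missing regulator value for '%s'", missing[1]),
             "egrinet_lookup_error")
  program$intercept + sum(program$terms * regulator_values[regs])
}

#' Combine a compendium with a condition-specific program
#'
#' Merges the two coefficient maps over the union of their regulators;
#' wherever both programs carry a coefficient for the same regulator, the
#' condition-specific one is used, so that a small number of targeted
#' experiments is not drowned out by the compendium.
#'
#' @param compendium,condition `egrin_program`s for the same target.
#' @return an `egrin_program` with provenance `"combined"`.
#' @export
combine_programs <- function(compendium, condition) {
  if (!identical(compendium$target, condition$target))
    egr_stop("cannot combine programs for different targets",
             "egrinet_contract_error")
  terms <- compendium$terms
  terms[names(condition$terms)] <- condition$terms
  intercept <- if (length(condition$terms) > 0) condition$intercept
               else compendium$intercept
  new_program(compendium$target, terms, intercept, "combined")
}

#' Combine two program sets target-wise
#'
#' Targets present in only one set are carried over unchanged (their
#' provenance is preserved); shared targets are merged with
#' [combine_programs()].
#'
#' @param compendium,condition named lists of `egrin_program`s.
#' @return named `egrin_program_set` over the union of targets.
#' @export
combine_program_sets <- function(compendium, condition) {
  targets <- union(names(compendium), names(condition))
  out <- lapply(setNames(targets, targets), function(g) {
    if (is.null(condition[[g]])) compendium[[g]]
    else if (is.null(compendium[[g]])) condition[[g]]
    else combine_programs(compendium[[g]], condition[[g]])
  })
  class(out) <- c("egrin_program_set", class(out))
  out
}

#' Flatten a program set into an edge table
#'
#' @param programs named list of `egrin_program`s.
#' @return data frame with columns regulator, target, beta, provenance.
#' @export
program_edges <- function(programs) {
  rows <- lapply(programs, function(p) {
    if (length(p$terms) == 0L) return(NULL)
    data.frame(regulator = names(p$terms), target = p$target,
               beta = as.numeric(p$terms), provenance = p$provenance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(regulator = character(), target = character(),
                      beta = numeric(), provenance = character())
  rownames(out) <- NULL
  out
}

#' Edge-level precision and recall against a true edge set
#'
#' @param predicted,truth data frames with regulator and target columns.
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`.
#' @export
edge_precision_recall <- function(predicted, truth) {
  pkey <- paste(predicted$regulator, predicted$target)
  tkey <- paste(truth$regulator, truth$target)
  tp <- sum(pkey %in% tkey)
  list(precision = if (length(pkey) > 0) tp / length(pkey) else NA_real_,
       recall = if (length(tkey) > 0) tp / length(tkey) else NA_real_,
       n_predicted = length(pkey), n_true = length(tkey))
}

#' Empirical enrichment of a regulator's predicted targets in a bicluster
#'
#' Compares the number of a regulator's predicted target genes falling in a
#' bicluster to the distribution expected if the bicluster's genes were
#' drawn at random from the universe, with the add-one empirical p-value
#' correction. The pair is called a "predicted regulator" of the bicluster
#' when `p <= cutoff`.
#'
#' @param predicted_targets character vector of the regulator's predicted
#'   target genes.
#' @param cluster_genes genes of the bicluster.
#' @param universe gene universe both are drawn from.
#' @param n_resamples number of random gene-set draws.
#' @param seed seed for the draws.
#' @param cutoff call cutoff on the empirical p.
#' @return list with `p`, `observed`, `called`.
#' @export
assign_predictions_to_bicluster <- function(predicted_targets, cluster_genes,
                                            universe, n_resamples = 1000L,
                                            seed = 1L, cutoff = 0.05) {
  cluster_genes <- intersect(cluster_genes, universe)
  predicted_targets <- intersect(predicted_targets, universe)
  observed <- length(intersect(predicted_targets, cluster_genes))
  m <- length(predicted_targets)
  N <- length(universe)
  s <- length(cluster_genes)
  ## drawing a random size-s gene set and counting predicted members is a
  ## hypergeometric draw; sample the counts directly
  draws <- withr::with_seed(seed, rhyper(n_resamples, m, N - m, s))
  p <- empirical_p(sum(draws >= observed), n_resamples)
  list(p = p, observed = observed, called = p <= cutoff)
}

#' Shuffle-based significance of a prediction-observation correlation
#'
#' @param predicted,observed numeric series of equal length (>= 3).
#' @param n_shuffles number of experiment shuffles for the background.
#' @param seed seed for the shuffles.
#' @return list with `r` (Pearson correlation; `NA` when degenerate), `p`
#'   (add-one-corrected upper-tail empirical p) and `degenerate`.
#' @export
correlation_significance <- function(predicted, observed, n_shuffles = 1000L,
                                     seed = 1L) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    egr_stop("series must have equal length >= 3", "egrinet_contract_error")
  if (sd(predicted) == 0 || sd(observed) == 0)
    return(list(r = NA_real_, p = 1, degenerate = TRUE))
  r <- cor(predicted, observed)
  shuffled <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) cor(predicted, sample(observed)), numeric(1))
  })
  list(r = r, p = empirical_p(sum(shuffled >= r), n_shuffles),
       degenerate = FALSE)
}

#' Fit programs for cluster mean profiles
#'
#' The "old cluster" mode: instead of aggregating gene-level programs over
#' a cluster, regress each cluster's mean expression profile on the
#' regulator profiles directly. Kept as an option alongside gene-level
#' fits; cluster-level aggregation of gene fits is the preferred mode.
#'
#' @param exprs `egrin_expression` or genes x experiments matrix.
#' @param clusters named list of cluster gene sets.
#' @param regulators candidate regulator ids.
#' @param config an [fit_config()].
#' @return named `egrin_program_set`, one program per cluster id.
#' @export
fit_cluster_programs <- function(exprs, clusters, regulators,
                                 config = fit_config()) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  means <- t(vapply(clusters, function(g)
    colMeans(values[intersect(g, rownames(values)), , drop = FALSE]),
    numeric(ncol(values))))
  X <- t(values[regulators, , drop = FALSE])
  out <- lapply(setNames(names(clusters), names(clusters)), function(cl) {
    fit_program(means[cl, ], X, config, target = cl,
                provenance = "compendium")
  })
  class(out) <- c("egrin_program_set", class(out))
  out
}
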