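# Expression simulation: compendium, condition-specific and deletion arrays.

# Standard deviation of the per-experiment jitter on regulator activities.
# This is biological experiment-to-experiment variability of the latent
# signals, not measurement noise (which is config$noise_sd on the targets);
# targets respond to it, so it is what identifies individual regulators
# within a condition block.
REG_JITTER_SD <- 0.35

#' Build the experiment design table for a configuration
#' @noRd
experiment_design <- function(config) {
  comp_labels <- compendium_condition_labels(config)
  n_blocks <- length(comp_labels)
  block_of <- rep_len(comp_labels, config$n_compendium_experiments)
  block_of <- sort(block_of)
  comp_times <- unlist(lapply(split(seq_along(block_of), block_of),
                              function(i) seq_along(i)), use.names = FALSE)
  meta <- data.frame(
    condition = block_of,
    time = comp_times,
    set = "compendium",
    stringsAsFactors = FALSE
  )
  for (b in config$condition_blocks) {
    meta <- rbind(meta, data.frame(
      condition = rep(b$label, b$n),
      time = b$times,
      set = "condition",
      stringsAsFactors = FALSE
    ))
  }
  meta$experiment <- sprintf("e%04d", seq_len(nrow(meta)))
  meta$deleted_gene <- "-"
  meta[, c("experiment", "condition", "time", "set", "deleted_gene")]
}

#' Scale times to [0, 1] within each condition
#' @noRd
scaled_times <- function(meta) {
  out <- numeric(nrow(meta))
  for (cond in unique(meta$condition)) {
    i <- meta$condition == cond
    t <- meta$time[i]
    rng <- range(t)
    out[i] <- if (diff(rng) > 0) (t - rng[1]) / diff(rng) else 0
  }
  out
}

#' Latent regulator activity for a set of experiments
#' @noRd
regulator_activity <- function(truth, meta, jitter_sd = REG_JITTER_SD) {
  tt <- scaled_times(meta)
  X <- truth$reg_levels[, meta$condition, drop = FALSE] +
    truth$reg_ramps[, meta$condition, drop = FALSE] *
      matrix(tt, nrow(truth$reg_levels), nrow(meta), byrow = TRUE)
  if (jitter_sd > 0)
    X <- X + matrix(rnorm(length(X), 0, jitter_sd), nrow(X), ncol(X))
  colnames(X) <- meta$experiment
  X
}

#' Simulate the expression compendium and condition-specific experiments
#'
#' Realizes log2-ratio expression for every gene over the configured
#' compendium and condition blocks. Regulator rows carry their latent
#' condition-driven activity signals; every other gene equals its regulatory
#' program applied to those signals plus Gaussian noise of standard deviation
#' `config$noise_sd`. With `noise_sd = 0` target rows are exactly linear in
#' the regulator rows.
#'
#' @param truth an `egrin_truth` from [generate_ground_truth()].
#' @param config the [sim_config()] used to build `truth` (defaults to the
#'   one stored in `truth`).
#' @return an object of class `egrin_expression`: list with `values` (genes x
#'   experiments numeric matrix) and `meta` (experiment, condition, time,
#'   set, deleted_gene).
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "egrin_truth"))
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 2L), {
    meta <- experiment_design(config)
    X <- regulator_activity(truth, meta)
    Y <- truth$coefficients %*% X
    if (config$noise_sd > 0) {
      Y <- Y + matrix(rnorm(length(Y), 0, config$noise_sd), nrow(Y), ncol(Y))
    }
    Y[truth$regulators, ] <- X
    dimnames(Y) <- list(truth$genes, meta$experiment)
    structure(list(values = Y, meta = meta), class = "egrin_expression")
  })
}

#' @export
print.egrin_expression <- function(x, ...) {
  cat(sprintf("egrin expression: %d genes x %d experiments (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$meta$set)),
                            as.integer(table(x$meta$set))), collapse = ", ")))
  invisible(x)
}

#' Subset an expression object to an experiment set or condition
#'
#' @param exprs an `egrin_expression`.
#' @param set optional experiment set ("compendium" or "condition").
#' @param conditions optional condition labels to keep.
#' @return an `egrin_expression` restricted to the matching experiments.
#' @export
subset_experiments <- function(exprs, set = NULL, conditions = NULL) {
  keep <- rep(TRUE, nrow(exprs$meta))
  if (!is.null(set)) keep <- keep & exprs$meta$set %in% set
  if (!is.null(conditions)) keep <- keep & exprs$meta$condition %in% conditions
  structure(list(values = exprs$values[, keep, drop = FALSE],
                 meta = exprs$meta[keep, , drop = FALSE]),
            class = "egrin_expression")
}

#' Simulate a regulator-deletion microarray
#'
#' Emulates a knockout strain profiled against its matched wild type under
#' one condition. The deleted regulator's activity is forced to
#' `config$knockout_value`; every true target of the regulator shifts by its
#' coefficient times the activity change, and all other genes are pure
#' measurement noise. The log-ratio profile is taken against the expected
#' wild-type condition profile (the dye-flip-averaged reference), so
#' non-target rows have mean exactly zero.
#'
#' @param truth an `egrin_truth`.
#' @param regulator id of the regulator to delete.
#' @param condition condition label under which the strain is profiled.
#' @param config simulation config (defaults to the one in `truth`).
#' @param n_replicates number of replicate arrays (columns).
#' @param seed seed for the replicate noise; defaults to a stream derived
#'   from `config$seed`, the regulator and the condition.
#' @return an object of class `egrin_deletion`: list with `profile` (genes x
#'   replicates log-ratio matrix vs matched wild type), `values` (genes x
#'   replicates absolute deletion-condition expression on the compendium
#'   scale), `regulator`, `condition`.
#' @export
simulate_deletion <- function(truth, regulator, condition,
                              config = truth$config, n_replicates = 1L,
                              seed = NULL) {
  stopifnot(inherits(truth, "egrin_truth"))
  if (!regulator %in% truth$regulators)
    egr_stop(sprintf("unknown regulator '%s'", regulator),
             "egrinet_lookup_error")
  if (!condition %in% truth$conditions)
    egr_stop(sprintf("unknown condition '%s'", condition),
             "egrinet_lookup_error")
  if (is.null(seed)) {
    seed <- derive_seed(config$seed,
                        3L + match(regulator, truth$regulators) * 131L +
                          match(condition, truth$conditions))
  }
  withr::with_seed(seed, {
    x_wt <- truth$reg_levels[, condition]
    x_del <- x_wt
    x_del[regulator] <- config$knockout_value
    shift <- truth$coefficients %*% (x_del - x_wt)  # = B[, r] * (KO - x_r)
    wt_expected <- truth$coefficients %*% x_wt
    wt_expected[truth$regulators, ] <- x_wt

    n_genes <- length(truth$genes)
    rep_names <- sprintf("%s_%s_r%d", regulator, condition,
                         seq_len(n_replicates))
    ## gene-specific indirect knockout responses (strain-level pathway
    ## re-balancing): zero-mean, proportional to the direct shift, shared
    ## across replicate arrays of the strain
    indirect <- rnorm(n_genes, 0, config$deletion_indirect * abs(shift))
    profile <- matrix(rep(shift + indirect, n_replicates), n_genes,
                      n_replicates,
                      dimnames = list(truth$genes, rep_names)) +
      matrix(rnorm(n_genes * n_replicates, 0, config$noise_sd),
             n_genes, n_replicates)
    ## the deleted regulator reads out its knockout level exactly
    profile[regulator, ] <- config$knockout_value
    values <- profile + matrix(rep(wt_expected, n_replicates),
                               n_genes, n_replicates)
    values[truth$regulators, ] <- x_wt
    values[regulator, ] <- config$knockout_value
    dimnames(values) <- list(truth$genes, rep_names)
    structure(list(profile = profile, values = values,
                   regulator = regulator, condition = condition),
              class = "egrin_deletion")
  })
}
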