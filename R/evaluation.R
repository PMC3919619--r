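# Accuracy metrics against deletion experiments, gene- vs cluster-level
# classifier comparison (MCC / F1 / AUC), and the statistical tests used to
# compare prediction modes.

#' Tabulate deletion truth for evaluation
#'
#' @param deletion_de_tables named list: regulator -> data frame from
#'   [deletion_de()] (one condition, or several rbind-ed).
#' @param alpha FDR level for the per-gene significance flags
#'   (Benjamini-Hochberg within each regulator's table).
#' @return data frame: regulator, gene, log_ratio, p, significant,
#'   direction (`up` / `down` / `none` as seen in the deletion).
#' @export
deletion_truth_table <- function(deletion_de_tables, alpha = 0.05) {
  rows <- lapply(names(deletion_de_tables), function(r) {
    de <- deletion_de_tables[[r]]
    sig <- p.adjust(de$p, "BH") <= alpha
    data.frame(regulator = r, gene = de$gene, log_ratio = de$log_ratio,
               p = de$p, significant = sig,
               direction = ifelse(!sig, "none",
                                  ifelse(de$log_ratio > 0, "up", "down")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign agreement between predicted roles and deletion responses
#'
#' A predicted activator agrees with the deletion data when its target's
#' expression decreases on deletion of the regulator; a predicted repressor
#' agrees when the target increases. `agreement` is 1 minus the mismatch
#' fraction over the evaluated predictions; `correlation` is the Pearson
#' correlation between the target deletion log-ratios and minus the
#' predicted coefficients.
#'
#' @param edges predicted edges (regulator, target, beta).
#' @param truth deletion truth from [deletion_truth_table()].
#' @param significant_only evaluate only pairs whose target changed
#'   significantly in the regulator's deletion.
#' @return list with `agreement`, `correlation`, `n`, and the evaluated
#'   pair table (`pairs`).
#' @export
sign_agreement <- function(edges, truth, significant_only = TRUE) {
  m <- merge(edges, truth, by.x = c("regulator", "target"),
             by.y = c("regulator", "gene"))
  if (significant_only) m <- m[m$significant, , drop = FALSE]
  if (nrow(m) == 0L)
    return(list(agreement = NA_real_, correlation = NA_real_, n = 0L,
                pairs = m))
  mismatch <- sign(m$beta) == sign(m$log_ratio)  # activator & target up = miss
  agreement <- 1 - mean(mismatch)
  correlation <- if (nrow(m) >= 3L && sd(m$beta) > 0 && sd(m$log_ratio) > 0)
    cor(m$log_ratio, -m$beta) else NA_real_
  list(agreement = agreement, correlation = correlation, n = nrow(m),
       pairs = m)
}

#' Role-swapped ("fixed") agreement metrics
#'
#' Recomputes the sign metrics after flipping the coefficients of every
#' regulator whose predicted roles are significantly anti-correlated with
#' the roles revealed by its deletion (per-regulator Pearson test of the
#' deletion log-ratios against minus the coefficients, at `alpha`). This
#' separates "right target, wrong sign" errors from wrong-target errors.
#'
#' @param edges predicted edges (regulator, target, beta).
#' @param truth deletion truth table.
#' @param alpha significance level of the per-regulator anti-correlation
#'   test.
#' @param significant_only as in [sign_agreement()].
#' @return list with `agreement_fix`, `correlation_fix`, `swapped`
#'   (regulator ids flipped), plus the plain metrics.
#' @export
fixed_metrics <- function(edges, truth, alpha = 0.05,
                          significant_only = TRUE) {
  plain <- sign_agreement(edges, truth, significant_only)
  m <- plain$pairs
  swapped <- character()
  for (r in unique(m$regulator)) {
    i <- m$regulator == r
    if (sum(i) < 3L || sd(m$beta[i]) == 0 || sd(m$log_ratio[i]) == 0) next
    ct <- stats::cor.test(m$log_ratio[i], -m$beta[i])
    if (!is.na(ct$estimate) && ct$estimate < 0 && ct$p.value <= alpha)
      swapped <- c(swapped, r)
  }
  fixed_edges <- edges
  flip <- fixed_edges$regulator %in% swapped
  fixed_edges$beta[flip] <- -fixed_edges$beta[flip]
  fix <- sign_agreement(fixed_edges, truth, significant_only)
  list(agreement = plain$agreement, correlation = plain$correlation,
       agreement_fix = fix$agreement, correlation_fix = fix$correlation,
       swapped = swapped, n = plain$n)
}

#' Full-equation prediction metrics on a deletion experiment
#'
#' Predicts every evaluated target's deletion response through its complete
#' linear equation (all regulators at their deletion-experiment values,
#' the deleted regulator at its knockout readout), then scores the
#' fraction of correctly predicted up/down signs and the Pearson
#' correlation between predicted and actual values. A predicted or actual
#' zero matches nothing.
#'
#' @param programs named list of `egrin_program`s (targets to evaluate:
#'   those whose program is non-empty).
#' @param regulator_values named vector of regulator values in the deletion
#'   experiment.
#' @param actual named vector of actual per-gene deletion log-ratios.
#' @return list with `prediction_agreement`, `prediction_correlation`, `n`.
#' @export
prediction_metrics <- function(programs, regulator_values, actual) {
  programs <- Filter(function(p) length(p$terms) > 0, programs)
  targets <- intersect(names(programs), names(actual))
  if (length(targets) == 0L)
    return(list(prediction_agreement = NA_real_,
                prediction_correlation = NA_real_, n = 0L))
  pred <- vapply(targets, function(g)
    predict_expression(programs[[g]], regulator_values), numeric(1))
  act <- actual[targets]
  agree <- sign(pred) != 0 & sign(act) != 0 & sign(pred) == sign(act)
  correlation <- if (length(targets) >= 3L && sd(pred) > 0 && sd(act) > 0)
    cor(pred, act) else NA_real_
  list(prediction_agreement = mean(agree),
       prediction_correlation = correlation, n = length(targets))
}

#' Matthews correlation coefficient from confusion counts
#' @param tp,fp,fn,tn confusion counts.
#' @return MCC in [-1, 1]; 0 (with a warning) when a margin is empty.
#' @export
mcc_score <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) {
    warning("degenerate confusion matrix: MCC reported as 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' F1 score from confusion counts
#' @param tp,fp,fn confusion counts.
#' @return F1 in [0, 1] (0 when there are no predicted or true positives).
#' @export
f1_score <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Rank-based area under the ROC curve
#' @param scores numeric ranking scores (larger = more confidently positive).
#' @param labels logical truth.
#' @return AUC; `NA` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Gene-level classifier metrics against deletion truth
#'
#' A (regulator, gene) pair is a predicted positive when the regulator has
#' a nonzero coefficient for the gene; a true positive additionally has the
#' gene changing significantly when the regulator is deleted. The pair
#' universe is all (evaluated regulator) x (universe gene) combinations;
#' AUC ranks pairs by `|beta|` with unpredicted pairs scoring 0.
#'
#' @param edges predicted edges (regulator, target, beta).
#' @param truth deletion truth table (defines the evaluated regulators).
#' @param universe genes forming the pair universe (default: genes in
#'   `truth`).
#' @return list with `mcc`, `f1`, `auc`, and the confusion counts.
#' @export
gene_level_confusion <- function(edges, truth,
                                 universe = unique(truth$gene)) {
  regs <- unique(truth$regulator)
  grid_key <- as.vector(outer(regs, universe, paste))
  pred_score <- setNames(rep(0, length(grid_key)), grid_key)
  e <- edges[edges$regulator %in% regs & edges$target %in% universe, ]
  pred_score[paste(e$regulator, e$target)] <- abs(e$beta)
  tr <- truth[truth$significant & truth$gene %in% universe, ]
  true_flag <- grid_key %in% paste(tr$regulator, tr$gene)
  pred_flag <- pred_score > 0
  tp <- sum(pred_flag & true_flag); fp <- sum(pred_flag & !true_flag)
  fn <- sum(!pred_flag & true_flag); tn <- sum(!pred_flag & !true_flag)
  list(mcc = mcc_score(tp, fp, fn, tn), f1 = f1_score(tp, fp, fn),
       auc = auc_score(pred_score, true_flag),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Cluster-level classifier metrics
#'
#' Positives are (regulator, cluster) pairs significantly enriched for the
#' regulator's predicted targets; truth pairs have the cluster enriched for
#' genes that changed significantly on the regulator's deletion. AUC ranks
#' pairs by the enrichment `-log10 p`.
#'
#' @param enrichment data frame (regulator, cluster, p, called) from
#'   repeated [assign_predictions_to_bicluster()] calls.
#' @param truth_calls data frame (regulator, cluster, significant) from
#'   FDR-adjusted [deletion_cluster_call()] p-values.
#' @return list with `mcc`, `f1`, `auc` and the confusion counts.
#' @export
cluster_level_confusion <- function(enrichment, truth_calls) {
  key <- function(d) paste(d$regulator, d$cluster)
  m <- merge(enrichment, truth_calls, by = c("regulator", "cluster"))
  if (nrow(m) == 0L)
    egr_stop("no (regulator, cluster) pairs shared between predictions and truth",
             "egrinet_contract_error")
  pred_flag <- m$called
  true_flag <- m$significant
  tp <- sum(pred_flag & true_flag); fp <- sum(pred_flag & !true_flag)
  fn <- sum(!pred_flag & true_flag); tn <- sum(!pred_flag & !true_flag)
  list(mcc = mcc_score(tp, fp, fn, tn), f1 = f1_score(tp, fp, fn),
       auc = auc_score(-log10(pmax(m$p, 1e-300)), true_flag),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Compare two metric samples
#'
#' Two-sided Wilcoxon signed-rank (paired; zero differences dropped,
#' Wilcoxon's original treatment) or Mann-Whitney (unpaired) test; exact
#' enumeration for small samples without ties, normal approximation
#' otherwise.
#'
#' @param sample_a,sample_b numeric vectors (equal length for the paired
#'   test).
#' @param test `"wilcoxon-signed-rank"` or `"mann-whitney"`.
#' @return two-sided p-value.
#' @export
compare_metric_sets <- function(sample_a, sample_b,
                                test = c("wilcoxon-signed-rank",
                                         "mann-whitney")) {
  test <- match.arg(test)
  if (test == "wilcoxon-signed-rank") {
    if (length(sample_a) != length(sample_b))
      egr_stop("paired samples must have equal length",
               "egrinet_contract_error")
    d <- sample_a - sample_b
    if (all(d == 0)) return(1)
    exact <- sum(d != 0) <= 12L && !any(duplicated(abs(d[d != 0])))
    return(suppressWarnings(
      wilcox.test(sample_a, sample_b, paired = TRUE, exact = exact,
                  correct = !exact)$p.value))
  }
  exact <- length(sample_a) <= 12L && length(sample_b) <= 12L &&
    !any(duplicated(c(sample_a, sample_b)))
  suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact,
                correct = !exact)$p.value)
}

#' Exact two-tailed binomial test for a fraction
#'
#' Sums the probabilities of all outcomes no more likely than the observed
#' count under the null success probability.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return two-tailed p-value.
#' @export
binomial_fraction_test <- function(k, n, p0) {
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 1 || k > n)
    egr_stop("need 0 <= k <= n", "egrinet_contract_error")
  if (p0 <= 0 || p0 >= 1)
    egr_stop("p0 must be in (0, 1)", "egrinet_contract_error")
  stats::binom.test(k, n, p0)$p.value
}
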