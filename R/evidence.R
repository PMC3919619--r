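# Indirect evidence streams (deletion differential expression, deletion
# cluster calls, bicluster shattering) and the direct binding stream.

#' Two-tailed deletion differential expression
#'
#' Fits a normal distribution (moment fit over the whole profile) to a
#' deletion array's log ratios and assigns every gene a two-tailed
#' p-value; genes up on deletion are candidate repression targets of the
#' deleted regulator, genes down are candidate activation targets.
#'
#' @param deletion an `egrin_deletion`, or a named numeric vector / genes x
#'   replicates matrix of log ratios (replicates are averaged).
#' @param exclude genes dropped before fitting (the deleted regulator's own
#'   forced knockout value would otherwise distort the fit; when an
#'   `egrin_deletion` is given, its regulator is excluded automatically).
#' @return data frame: gene, log_ratio, p, direction
#'   (`"repression"` when the gene rises on deletion, `"activation"` when it
#'   falls, as seen from the deleted regulator).
#' @export
deletion_de <- function(deletion, exclude = character()) {
  if (inherits(deletion, "egrin_deletion")) {
    exclude <- union(exclude, deletion$regulator)
    deletion <- deletion$profile
  }
  x <- if (is.matrix(deletion)) rowMeans(deletion) else deletion
  fit_on <- x[setdiff(names(x), exclude)]
  if (length(fit_on) < 30L)
    egr_stop("deletion profile needs >= 30 genes", "egrinet_contract_error")
  ## plain moment fit of a normal to the whole profile: responding genes
  ## inflate the fitted scale, so only clear responders reach
  ## significance — deliberately conservative per-gene truth that the
  ## cluster-level calls then aggregate over
  loc <- mean(fit_on)
  s <- sqrt(mean((fit_on - loc)^2))
  if (s <= 0)
    egr_stop("degenerate (constant) deletion profile", "egrinet_contract_error")
  z <- (x - loc) / s
  data.frame(gene = names(x), log_ratio = as.numeric(x),
             p = 2 * pnorm(-abs(z)),
             direction = ifelse(x > loc, "repression", "activation"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric deletion call for a cluster
#'
#' Is the cluster enriched for genes that changed significantly when the
#' regulator was deleted? Identical machinery to [annotation_enrichment()],
#' applied to the differentially expressed gene set; callers adjust across
#' (regulator, cluster) pairs with [p.adjust()].
#'
#' @param significant_genes genes called significantly changed on deletion.
#' @param cluster_genes genes of the cluster.
#' @param universe gene universe.
#' @return hypergeometric upper-tail p-value.
#' @export
deletion_cluster_call <- function(significant_genes, cluster_genes, universe) {
  annotation_enrichment(cluster_genes, significant_genes, universe)
}

#' Bicluster shattering test
#'
#' A deletion "shatters" a bicluster when the within-cluster expression
#' variance in the deletion experiment exceeds more than 95% of the
#' cluster's variances across the wild-type condition experiments — tightly
#' co-regulated clusters are easy to shatter, loose ones hard. The p-value
#' is the add-one-corrected fraction of wild-type variances at or above the
#' deletion variance.
#'
#' @param deletion_values expression values of the cluster's genes in the
#'   deletion experiment (named numeric vector over genes, or a genes x 1
#'   matrix).
#' @param wildtype_variances the cluster's within-experiment variances over
#'   the wild-type condition experiments (>= 5 values).
#' @param quantile_cutoff shattering threshold (fraction of wild-type
#'   variances that must be exceeded).
#' @return list with `variance`, `p`, `shattered`.
#' @export
shattering_test <- function(deletion_values, wildtype_variances,
                            quantile_cutoff = 0.95) {
  if (length(wildtype_variances) < 5L)
    egr_stop("need >= 5 wild-type variance observations",
             "egrinet_background_error")
  v <- var(as.numeric(deletion_values))
  p <- empirical_p(sum(wildtype_variances >= v), length(wildtype_variances))
  shattered <- mean(wildtype_variances < v) > quantile_cutoff
  list(variance = v, p = p, shattered = shattered)
}

#' Cluster variances over wild-type condition experiments
#'
#' @param cluster_genes genes of the cluster.
#' @param exprs `egrin_expression` restricted to the wild-type condition
#'   experiments.
#' @return named numeric vector of per-experiment variances.
#' @export
cluster_wildtype_variances <- function(cluster_genes, exprs) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  setNames(col_vars(values[cluster_genes, , drop = FALSE]), colnames(values))
}

#' Assign binding events to genes
#'
#' A binding event supports regulation of a gene when it falls in the
#' window from `upstream` bases upstream of the gene's transcription start
#' site to `downstream` bases after it, measured along the gene's own
#' strand (the TSS of a minus-strand gene is its rightmost coordinate).
#' Events on either strand count; an event inside the windows of two
#' divergently transcribed genes is assigned to both. When several events
#' support one (regulator, gene) pair, the lowest p-value is kept. Events
#' with `p <= strong_cutoff` are strong evidence, all others weak.
#'
#' @param events data frame: tf, chrom, position, p_value.
#' @param gene_models data frame: gene, chrom, strand, tss (1-based).
#' @param upstream,downstream window extent in bases.
#' @param strong_cutoff strong-evidence threshold.
#' @return data frame: regulator, gene, p, strength.
#' @export
assign_binding <- function(events, gene_models, upstream = 1000L,
                           downstream = 100L, strong_cutoff = 0.01) {
  need <- c("tf", "chrom", "position", "p_value")
  if (!all(need %in% names(events)))
    egr_stop("binding events need columns tf, chrom, position, p_value",
             "egrinet_parse_error")
  if (any(!is.finite(events$position)))
    egr_stop(sprintf("malformed binding coordinate at line %d",
                     which(!is.finite(events$position))[1]),
             "egrinet_parse_error")
  lo <- ifelse(gene_models$strand == "+", gene_models$tss - upstream,
               gene_models$tss - downstream)
  hi <- ifelse(gene_models$strand == "+", gene_models$tss + downstream,
               gene_models$tss + upstream)
  rows <- vector("list", nrow(gene_models))
  for (i in seq_len(nrow(gene_models))) {
    hit <- events$chrom == gene_models$chrom[i] &
      events$position >= lo[i] & events$position <= hi[i]
    if (!any(hit)) next
    sub <- events[hit, ]
    best <- tapply(sub$p_value, sub$tf, min)
    rows[[i]] <- data.frame(regulator = names(best),
                            gene = gene_models$gene[i],
                            p = as.numeric(best), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(regulator = character(), gene = character(),
                      p = numeric(), strength = character()))
  out$strength <- ifelse(out$p <= strong_cutoff, "strong", "weak")
  rownames(out) <- NULL
  out
}

#' Binding-score call for a cluster
#'
#' Scores the cluster as the sum over its genes of `-log10` of the gene's
#' best binding p-value (genes without binding contribute p = 1, score 0),
#' compares the score to the same score for random gene sets of the same
#' size, and calls regulation when the observed score lands in the top 5%
#' of the background (ties break against assignment).
#'
#' @param cluster_genes genes of the cluster.
#' @param gene_binding_p named numeric vector: per gene, the regulator's
#'   best binding p (genes absent from the vector count as p = 1).
#' @param universe gene universe to resample from.
#' @param n_resamples number of random gene sets.
#' @param seed seed for the draws.
#' @param top_fraction background tail that counts as regulation.
#' @return list with `score`, `p`, `regulated`.
#' @export
binding_cluster_call <- function(cluster_genes, gene_binding_p, universe,
                                 n_resamples = 1000L, seed = 1L,
                                 top_fraction = 0.05) {
  scores <- setNames(rep(0, length(universe)), universe)
  known <- intersect(names(gene_binding_p), universe)
  scores[known] <- -log10(pmax(gene_binding_p[known], 1e-300))
  observed <- sum(scores[intersect(cluster_genes, universe)])
  s <- length(intersect(cluster_genes, universe))
  bg <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) sum(scores[sample.int(length(universe), s)]),
           numeric(1))
  })
  p <- empirical_p(sum(bg >= observed), n_resamples)
  regulated <- mean(bg < observed) > 1 - top_fraction
  list(score = observed, p = p, regulated = regulated)
}
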