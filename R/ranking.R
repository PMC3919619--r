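# Ranking candidate regulators of an annotation of interest.

#' Score and rank candidate regulators
#'
#' Combines, over the annotation-enriched biclusters a regulator is
#' predicted to regulate, the strength of the regulation call with how
#' broadly the bicluster stays coherent across conditions:
#'
#' `score(r) = sum over enriched clusters c with p[r, c] <= cutoff of
#'   (-log10(p[r, c]) * (1 + #conditions where c is coherent))`
#'
#' The `+ 1` keeps clusters that are never condition-coherent contributing,
#' so a ranking is available before condition-specific data exist. Ties are
#' broken lexicographically by regulator id; every candidate appears in the
#' returned ranking (regulators with no contributing cluster score 0).
#'
#' @param regulation_p data frame with columns regulator, cluster, p (the
#'   empirical bicluster-regulation p-values from
#'   [assign_predictions_to_bicluster()]).
#' @param enriched_clusters ids of the annotation-enriched biclusters.
#' @param coherence_counts named integer vector: per cluster, the number of
#'   conditions under which it is coherent.
#' @param regulators full candidate list (ensures zero-score rows).
#' @param cutoff regulation-call cutoff on p.
#' @return data frame: rank, regulator, score, n_clusters, ordered by
#'   decreasing score.
#' @export
score_regulators <- function(regulation_p, enriched_clusters,
                             coherence_counts,
                             regulators = unique(regulation_p$regulator),
                             cutoff = 0.05) {
  stopifnot(all(c("regulator", "cluster", "p") %in% names(regulation_p)))
  missing <- setdiff(enriched_clusters, names(coherence_counts))
  if (length(missing) > 0)
    egr_stop(sprintf("no coherence flags for cluster '%s'", missing[1]),
             "egrinet_contract_error")
  hits <- regulation_p[regulation_p$cluster %in% enriched_clusters &
                         regulation_p$p <= cutoff, , drop = FALSE]
  weight <- -log10(hits$p) * (1 + coherence_counts[hits$cluster])
  score <- tapply(weight, hits$regulator, sum)
  n_clusters <- tapply(hits$cluster, hits$regulator, length)
  out <- data.frame(regulator = regulators,
                    score = as.numeric(score[regulators]),
                    n_clusters = as.integer(n_clusters[regulators]),
                    stringsAsFactors = FALSE)
  out$score[is.na(out$score)] <- 0
  out$n_clusters[is.na(out$n_clusters)] <- 0L
  out <- out[order(-out$score, out$regulator), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "regulator", "score", "n_clusters")]
}
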