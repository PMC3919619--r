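# Six-stream evidence integration into a high-confidence gene-level network.

EVIDENCE_STREAMS <- c("influence", "deletion-DE", "shattering",
                      "binding", "known-motif", "denovo-motif")

#' Construct an evidence-edge table
#'
#' @param regulator,target,stream,p vectors of equal length.
#' @param direction `"activation"`, `"repression"` or `"unknown"` (direct
#'   streams carry no sign).
#' @param strength `"strong"` or `"weak"`.
#' @param condition condition label or `"global"`.
#' @return data frame with the evidence-edge columns.
#' @export
evidence_edges <- function(regulator, target, stream, p,
                           direction = "unknown", strength = "weak",
                           condition = "global") {
  stopifnot(all(stream %in% EVIDENCE_STREAMS))
  if (any(p < 0 | p > 1)) egr_stop("p-values must be in [0, 1]",
                                   "egrinet_contract_error")
  data.frame(regulator = regulator, target = target, stream = stream,
             direction = direction, p = p, strength = strength,
             condition = condition, stringsAsFactors = FALSE)
}

#' Import de-novo motif assignments
#'
#' Reads externally computed de-novo motif matches — rows of (regulator,
#' cluster, p) — keeps rows with `p <= cutoff`, and expands each kept row to
#' one edge per cluster gene (a de-novo motif found for a cluster is taken
#' as evidence for every gene in that cluster). Duplicate expanded edges
#' are collapsed to their minimum p.
#'
#' @param assignments path to a TSV with columns regulator, cluster, p, or
#'   an equivalent data frame.
#' @param clusters named list of cluster gene sets.
#' @param cutoff assignment cutoff on p.
#' @return evidence-edge data frame (stream `"denovo-motif"`).
#' @export
import_denovo_assignments <- function(assignments, clusters, cutoff = 0.05) {
  if (is.character(assignments)) {
    assignments <- read.delim(assignments, stringsAsFactors = FALSE)
  }
  if (!all(c("regulator", "cluster", "p") %in% names(assignments)))
    egr_stop("de-novo assignments need columns regulator, cluster, p",
             "egrinet_parse_error")
  unknown <- setdiff(assignments$cluster, names(clusters))
  if (length(unknown) > 0)
    egr_stop(sprintf("unknown cluster id '%s' in de-novo assignments",
                     unknown[1]), "egrinet_parse_error")
  kept <- assignments[assignments$p <= cutoff, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(evidence_edges(character(), character(), character(), numeric()))
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    genes <- clusters[[kept$cluster[i]]]
    evidence_edges(kept$regulator[i], genes, "denovo-motif", kept$p[i])
  })
  out <- do.call(rbind, rows)
  ## deduplicate to the minimum p per (regulator, target)
  key <- paste(out$regulator, out$target)
  out <- out[order(key, out$p), ]
  out <- out[!duplicated(paste(out$regulator, out$target)), ]
  rownames(out) <- NULL
  out
}

#' Quantile-normalize p-values across evidence streams
#'
#' Maps each stream's p-values onto the pooled empirical distribution of
#' all streams by rank (average ranks for ties), so that no stream
#' dominates the integrated edge weights merely because its p-values run
#' smaller.
#'
#' @param edges evidence-edge data frame.
#' @return the same data frame with a `p_norm` column.
#' @export
quantile_normalize_streams <- function(edges) {
  pooled <- sort(edges$p)
  edges$p_norm <- NA_real_
  for (s in unique(edges$stream)) {
    i <- edges$stream == s
    r <- rank(edges$p[i], ties.method = "average")
    probs <- (r - 0.5) / sum(i)
    edges$p_norm[i] <- quantile(pooled, probs = probs, type = 4,
                                names = FALSE)
  }
  edges
}

#' Integrate evidence streams into high-confidence edges
#'
#' Groups evidence by (regulator, target, condition) — edges tagged
#' `"global"` (the motif streams, and binding) apply to every condition
#' present — and keeps the groups supported by at least `min_streams`
#' distinct streams. Stream p-values are quantile-normalized across streams
#' first; the integrated edge weight is the mean `-log10` normalized p over
#' the supporting streams (one value per stream: its smallest normalized p).
#'
#' @param edges evidence-edge data frame.
#' @param min_streams minimum number of distinct supporting streams.
#' @return data frame: regulator, target, condition, n_streams, streams
#'   (comma-joined), weight, direction (`"unknown"` unless the signed
#'   streams agree), sorted by regulator, target, condition.
#' @export
integrate_evidence <- function(edges, min_streams = 2L) {
  if (nrow(edges) == 0L)
    return(data.frame(regulator = character(), target = character(),
                      condition = character(), n_streams = integer(),
                      streams = character(), weight = numeric(),
                      direction = character()))
  if (any(is.na(edges$p)))
    egr_stop("all evidence edges must carry a p-value",
             "egrinet_contract_error")
  edges <- quantile_normalize_streams(edges)
  conds <- setdiff(unique(edges$condition), "global")
  if (length(conds) == 0L) conds <- "global"
  glob <- edges[edges$condition == "global", , drop = FALSE]
  expanded <- edges[edges$condition != "global", , drop = FALSE]
  if (nrow(glob) > 0L) {
    expanded <- rbind(expanded,
                      do.call(rbind, lapply(conds, function(cc) {
                        g <- glob
                        g$condition <- cc
                        g
                      })))
  }
  key <- paste(expanded$regulator, expanded$target, expanded$condition,
               sep = "\r")
  groups <- split(expanded, key)
  rows <- lapply(groups, function(g) {
    streams <- sort(unique(g$stream))
    if (length(streams) < min_streams) return(NULL)
    ## one value per stream: its strongest (smallest) normalized p
    p_by_stream <- vapply(streams, function(s)
      min(g$p_norm[g$stream == s]), numeric(1))
    dirs <- setdiff(unique(g$direction), "unknown")
    data.frame(regulator = g$regulator[1], target = g$target[1],
               condition = g$condition[1], n_streams = length(streams),
               streams = paste(streams, collapse = ","),
               weight = mean(-log10(pmax(p_by_stream, 1e-300))),
               direction = if (length(dirs) == 1L) dirs else "unknown",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(regulator = character(), target = character(),
                      condition = character(), n_streams = integer(),
                      streams = character(), weight = numeric(),
                      direction = character()))
  out <- out[order(out$regulator, out$target, out$condition), ]
  rownames(out) <- NULL
  out
}
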