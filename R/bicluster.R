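# Gene clustering, coherence testing against variance backgrounds,
# condition assignment, and annotation enrichment.
#
# The clustering front-end is deliberately interchangeable: any gene
# partition can be supplied (e.g. imported from an external biclustering
# run); the shipped default is k-means on row-standardized profiles, which
# is equivalent to clustering under Pearson-correlation distance.

#' Cluster genes by expression profile
#'
#' @param exprs `egrin_expression` or genes x experiments matrix.
#' @param k number of clusters (>= 1).
#' @param method `"kmeans-correlation"` (row-standardized k-means with
#'   seeded restarts) is the only built-in method; externally computed
#'   memberships can be supplied through [read_cluster_tsv()].
#' @param seed seed for the restarts.
#' @param nstart number of seeded k-means restarts.
#' @return named list of gene-id vectors (clusters `c001`, `c002`, ...).
#' @export
cluster_genes <- function(exprs, k, method = "kmeans-correlation",
                          seed = 1L, nstart = 5L) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  method <- match.arg(method, "kmeans-correlation")
  if (k < 1L) egr_stop("k must be >= 1", "egrinet_config_error")
  if (k > nrow(values))
    egr_stop("k exceeds the number of genes", "egrinet_config_error")
  if (k == 1L) return(list(c001 = sort(rownames(values))))
  rs <- values - rowMeans(values)
  rsd <- sqrt(rowSums(rs^2))
  rsd[rsd == 0] <- 1
  rs <- rs / rsd
  km <- withr::with_seed(seed,
                         kmeans(rs, centers = k, nstart = nstart,
                                iter.max = 50L))
  split(rownames(values), sprintf("c%03d", km$cluster))
}

#' Empirical variance backgrounds for random gene sets
#'
#' For every experiment and every requested gene-set size, draws
#' `n_resamples` random gene sets and records the within-experiment variance
#' of their values. These backgrounds calibrate the coherence test: a
#' bicluster is coherent in an experiment when its variance is unusually low
#' for a random gene set of its size.
#'
#' @param exprs `egrin_expression` or genes x experiments matrix (use the
#'   same scale the coherence test will run on; the pipeline uses z-scored
#'   ratios).
#' @param sizes integer vector of gene-set sizes to build backgrounds for.
#' @param n_resamples number of random gene sets per (experiment, size).
#' @param seed seed for the draws.
#' @return object of class `egrin_var_background`.
#' @export
variance_background <- function(exprs, sizes, n_resamples = 1000L, seed = 1L) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  sizes <- sort(unique(as.integer(sizes)))
  if (n_resamples < 100L)
    egr_stop("n_resamples must be >= 100", "egrinet_config_error")
  if (any(sizes < 2L) || any(sizes > nrow(values)))
    egr_stop("background sizes must be in [2, n_genes]",
             "egrinet_config_error")
  by_size <- withr::with_seed(seed, {
    lapply(setNames(sizes, sizes), function(s) {
      idx <- sample.int(nrow(values), n_resamples * s, replace = TRUE)
      grp <- rep(seq_len(n_resamples), each = s)
      x <- values[idx, , drop = FALSE]
      sums <- rowsum(x, grp, reorder = FALSE)
      sums2 <- rowsum(x^2, grp, reorder = FALSE)
      (sums2 - sums^2 / s) / (s - 1)  # n_resamples x n_experiments
    })
  })
  structure(list(by_size = by_size, n_resamples = n_resamples,
                 experiments = colnames(values), seed = seed),
            class = "egrin_var_background")
}

#' Per-experiment coherence of a gene cluster
#'
#' Compares the within-cluster variance in each experiment to the empirical
#' background for random gene sets of the same size:
#' `p = (1 + #{background <= observed}) / (n_resamples + 1)`. Low variance
#' gives low p; the cluster is coherent in an experiment when `p <= alpha`.
#'
#' @param cluster_genes gene ids of the cluster (>= 2).
#' @param exprs `egrin_expression` or matrix the background was built from.
#' @param background an `egrin_var_background` containing the cluster size.
#' @param alpha coherence call cutoff.
#' @return data frame with columns experiment, variance, p, coherent.
#' @export
experiment_coherence <- function(cluster_genes, exprs, background,
                                 alpha = 0.05) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  s <- length(cluster_genes)
  bg <- background$by_size[[as.character(s)]]
  if (is.null(bg))
    egr_stop(sprintf("no variance background for gene-set size %d", s),
             "egrinet_state_error")
  obs <- col_vars(values[cluster_genes, , drop = FALSE])
  n_le <- colSums(bg <= rep(obs, each = nrow(bg)))
  p <- empirical_p(n_le, background$n_resamples)
  data.frame(experiment = colnames(values), variance = obs, p = p,
             coherent = p <= alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Condition coherence by the strict-majority rule
#'
#' A cluster is coherent under a condition if and only if strictly more than
#' half of that condition's experiments are coherent in the cluster.
#'
#' @param coherent named logical vector (per experiment).
#' @param condition_experiments experiment ids belonging to the condition.
#' @return single logical.
#' @export
condition_coherence <- function(coherent, condition_experiments) {
  if (length(condition_experiments) == 0L)
    egr_stop("condition has no experiments", "egrinet_contract_error")
  n_coherent <- sum(coherent[condition_experiments], na.rm = TRUE)
  n_coherent > length(condition_experiments) / 2
}

#' Condition coherence flags for all conditions
#'
#' @param coherence data frame from [experiment_coherence()].
#' @param meta experiment metadata with columns experiment, condition.
#' @return named logical vector over conditions.
#' @export
condition_coherence_map <- function(coherence, meta) {
  coherent <- setNames(coherence$coherent, coherence$experiment)
  conds <- unique(meta$condition)
  vapply(setNames(conds, conds), function(cc)
    condition_coherence(coherent, meta$experiment[meta$condition == cc]),
    logical(1))
}

#' Hypergeometric annotation enrichment of a cluster
#'
#' One-sided over-representation p-value: the probability of observing at
#' least the actual overlap between the cluster and the annotation set when
#' drawing the cluster at random from the universe.
#'
#' @param cluster_genes,annotation_genes,universe gene-id vectors;
#'   cluster and annotation must be subsets of the universe.
#' @return hypergeometric upper-tail p-value.
#' @export
annotation_enrichment <- function(cluster_genes, annotation_genes, universe) {
  if (length(universe) == 0L)
    egr_stop("empty gene universe", "egrinet_config_error")
  cluster_genes <- intersect(cluster_genes, universe)
  annotation_genes <- intersect(annotation_genes, universe)
  k <- length(intersect(cluster_genes, annotation_genes))
  phyper(k - 1L, length(annotation_genes),
         length(universe) - length(annotation_genes),
         length(cluster_genes), lower.tail = FALSE)
}

#' Enrichment table over all (cluster, annotation) pairs with FDR control
#'
#' @param clusters named list of gene sets.
#' @param annotation_sets named list of annotation gene sets.
#' @param universe gene universe.
#' @return data frame: cluster, annotation, overlap, p, p_adjusted.
#' @export
annotation_enrichment_table <- function(clusters, annotation_sets, universe) {
  grid <- expand.grid(cluster = names(clusters),
                      annotation = names(annotation_sets),
                      stringsAsFactors = FALSE)
  grid$overlap <- mapply(function(cl, an)
    length(intersect(intersect(clusters[[cl]], universe),
                     intersect(annotation_sets[[an]], universe))),
    grid$cluster, grid$annotation)
  grid$p <- mapply(function(cl, an)
    annotation_enrichment(clusters[[cl]], annotation_sets[[an]], universe),
    grid$cluster, grid$annotation)
  grid$p_adjusted <- p.adjust(grid$p, "BH")
  grid
}

#' Assemble full bicluster records
#'
#' Runs the coherence test, the condition-coherence rule and annotation
#' enrichment for every cluster, producing the bicluster objects the
#' ranking and evidence stages consume.
#'
#' @param clusters named list of gene sets (>= 2 genes each).
#' @param exprs `egrin_expression` on the coherence scale (z-scored ratios).
#' @param annotation_sets named list of annotation gene sets.
#' @param n_resamples background resamples for the coherence test.
#' @param alpha coherence cutoff.
#' @param seed background seed.
#' @return named list of bicluster records (class `egrin_biclusters`), each
#'   with `id`, `genes`, `coherence` (per-experiment table),
#'   `condition_coherence` (named logical), `enrichment` (per-annotation
#'   table rows).
#' @export
make_biclusters <- function(clusters, exprs, annotation_sets = list(),
                            n_resamples = 1000L, alpha = 0.05, seed = 1L) {
  clusters <- clusters[vapply(clusters, length, 1L) >= 2L]
  sizes <- unique(vapply(clusters, length, 1L))
  bg <- variance_background(exprs, sizes, n_resamples, seed)
  enr <- if (length(annotation_sets) > 0)
    annotation_enrichment_table(clusters, annotation_sets,
                                rownames(exprs$values))
  else NULL
  out <- lapply(names(clusters), function(id) {
    coh <- experiment_coherence(clusters[[id]], exprs, bg, alpha)
    list(id = id,
         genes = clusters[[id]],
         coherence = coh,
         condition_coherence = condition_coherence_map(coh, exprs$meta),
         enrichment = if (is.null(enr)) NULL else enr[enr$cluster == id, ])
  })
  names(out) <- names(clusters)
  class(out) <- "egrin_biclusters"
  out
}

#' Trim weakly co-expressed genes from clusters
#'
#' A partition front-end assigns every gene somewhere, but a co-regulated
#' module need not cover the whole genome. This refinement drops members
#' whose profile correlates poorly with their cluster's mean profile, so
#' downstream cluster-level calls (coherence, shattering, motif expansion)
#' operate on tight cores rather than on catch-all partitions. Genes
#' removed here simply stay unclustered.
#'
#' @param clusters named list of gene sets.
#' @param exprs `egrin_expression` or genes x experiments matrix.
#' @param min_cor minimum Pearson correlation with the cluster mean.
#' @param min_size clusters smaller than this after trimming are dropped.
#' @return named list of refined gene sets.
#' @export
refine_clusters <- function(clusters, exprs, min_cor = 0.4, min_size = 3L) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  out <- lapply(clusters, function(genes) {
    genes <- intersect(genes, rownames(values))
    if (length(genes) < min_size) return(NULL)
    centre <- colMeans(values[genes, , drop = FALSE])
    if (sd(centre) == 0) return(genes)
    keep <- vapply(genes, function(g) {
      v <- values[g, ]
      if (sd(v) == 0) return(FALSE)
      cor(v, centre) >= min_cor
    }, TRUE)
    if (sum(keep) < min_size) NULL else genes[keep]
  })
  out[!vapply(out, is.null, TRUE)]
}
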