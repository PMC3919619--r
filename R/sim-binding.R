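# Promoter sequences, planted motif sites and binding-event simulation.

#' Simulate promoters, motif matrices and binding events
#'
#' Draws one promoter per gene — `promoter_upstream` bases upstream of the
#' transcription start site (TSS) through `promoter_downstream` bases
#' downstream, written 5' to 3' along the gene's own strand — from an i.i.d.
#' background with the configured GC fraction. Every planted site from the
#' ground truth is spelled into its promoter as the regulator's consensus,
#' with each base independently corrupted (replaced by a different base) with
#' probability `config$corruption`. Binding events for true regulator-target
#' pairs receive low p-values (Beta(1, 150); median well below 0.01) at the
#' planted-site coordinate; decoy events receive Uniform(0, 1) p-values at
#' random chromosome coordinates.
#'
#' @param truth an `egrin_truth`.
#' @param config simulation config (defaults to the one in `truth`).
#' @param regulators regulators to emit binding events and matrices for
#'   (default: all); promoters are always generated for every gene.
#' @param decoys_per_regulator number of random decoy events per regulator.
#' @return an object of class `egrin_binding_sim`: list with `promoters`
#'   (named character vector, one sequence per gene), `pwms` (regulator ->
#'   4 x L probability matrix), `events` (data frame: tf, chrom, position,
#'   p_value) and `gene_models` (gene, chrom, strand, tss).
#' @export
simulate_binding_and_promoters <- function(truth, config = truth$config,
                                           regulators = truth$regulators,
                                           decoys_per_regulator = 25L) {
  stopifnot(inherits(truth, "egrin_truth"))
  validate_sim_config(config)
  if (is.null(truth$motif_library))
    egr_stop("ground truth carries no motif library", "egrinet_state_error")
  bad <- setdiff(regulators, truth$regulators)
  if (length(bad) > 0)
    egr_stop(sprintf("unknown regulator '%s'", bad[1]), "egrinet_lookup_error")

  up <- config$promoter_upstream
  down <- config$promoter_downstream
  prom_len <- up + down
  bases <- c("A", "C", "G", "T")
  base_prob <- c((1 - config$gc) / 2, config$gc / 2,
                 config$gc / 2, (1 - config$gc) / 2)

  withr::with_seed(derive_seed(config$seed, 4L), {
    n_genes <- length(truth$genes)
    seqmat <- matrix(sample(bases, prom_len * n_genes, TRUE, base_prob),
                     prom_len, n_genes)
    colnames(seqmat) <- truth$genes

    ## plant corrupted consensus sites (promoter index 1 is position -up)
    sites <- truth$planted_sites
    for (i in seq_len(nrow(sites))) {
      cons <- strsplit(pwm_consensus(truth$motif_library[[sites$regulator[i]]]),
                       "")[[1]]
      if (config$corruption > 0) {
        flip <- runif(length(cons)) < config$corruption
        if (any(flip)) {
          cons[flip] <- vapply(cons[flip], function(b)
            sample(setdiff(bases, b), 1L), "")
        }
      }
      idx <- sites$offset[i] + up + seq_along(cons)
      seqmat[idx, sites$gene[i]] <- cons
    }
    promoters <- apply(seqmat, 2L, paste, collapse = "")

    ## binding events
    gm <- truth$gene_models
    rownames(gm) <- gm$gene
    chrom_len <- max(gm$tss) + up + down
    events <- list()
    for (r in regulators) {
      targets <- truth$true_binding[[r]]
      if (!is.null(targets) && length(targets) > 0) {
        site <- sites[sites$regulator == r & sites$gene %in% targets, ]
        centre <- site$offset + config$motif_length %/% 2L
        strand <- gm[site$gene, "strand"]
        pos <- ifelse(strand == "+",
                      gm[site$gene, "tss"] + centre,
                      gm[site$gene, "tss"] - centre)
        events[[length(events) + 1L]] <- data.frame(
          tf = r, chrom = "chrS", position = as.integer(pos),
          p_value = rbeta(nrow(site), 1, 150), stringsAsFactors = FALSE)
      }
      if (decoys_per_regulator > 0) {
        events[[length(events) + 1L]] <- data.frame(
          tf = r, chrom = "chrS",
          position = sample.int(chrom_len, decoys_per_regulator),
          p_value = runif(decoys_per_regulator), stringsAsFactors = FALSE)
      }
    }
    events <- do.call(rbind, events)
    rownames(events) <- NULL

    structure(list(promoters = promoters,
                   pwms = truth$motif_library[regulators],
                   events = events,
                   gene_models = truth$gene_models),
              class = "egrin_binding_sim")
  })
}

#' @importFrom stats rbeta
#' @export
print.egrin_binding_sim <- function(x, ...) {
  cat(sprintf("egrin binding simulation: %d promoters, %d PWMs, %d events\n",
              length(x$promoters), length(x$pwms), nrow(x$events)))
  invisible(x)
}
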