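# Ground-truth regulatory system generation.
#
# The generative model: each candidate regulator carries a latent activity
# signal that is "on" (condition-specific base level plus a temporal ramp)
# in a small set of conditions and quiescent elsewhere. A module is a set of
# genes sharing a sparse linear program over one to three regulators whose
# activity defines the module's active conditions; per-gene coefficient
# scaling keeps the module tightly coherent while its drivers are on. Each
# module gene additionally carries private coefficients on regulators active
# only outside the module's conditions, so coherence is lost exactly where
# the module is inactive. Genes outside modules follow small private
# programs. All of this yields targets that are exactly linear in regulator
# activities, the assumption the downstream elastic-net inference makes.

#' Derive a reproducible sub-stream seed
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + stream * 1000003) %% 2147483562)
}

#' Generate a ground-truth regulatory system
#'
#' Draws the complete synthetic truth: gene and regulator identities, module
#' memberships with active-condition sets, per-target regulatory programs,
#' annotation sets (one, `peroxisome_like`, is a superset of the two
#' "annotated" modules plus distractor genes), a motif library with one
#' position weight matrix per regulator, planted promoter sites and the true
#' binding map. Deterministic for a fixed `config$seed`.
#'
#' The first two modules are designated annotated modules and are forced to
#' be active under every named condition block (LS/EO/LO under the default
#' design), mirroring tightly co-regulated modules that stay coherent across
#' an induction time course.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `egrin_truth`: a list with elements `genes`,
#'   `regulators`, `conditions`, `modules`, `programs`, `coefficients`
#'   (genes x regulators matrix), `edges`, `annotation_sets`,
#'   `motif_library`, `planted_sites`, `true_binding`, `gene_models`,
#'   `reg_active`, `reg_levels`, `reg_ramps` and the `config` itself.
#' @export
#' @examples
#' truth <- generate_ground_truth(sim_config(n_genes = 200, n_regulators = 12,
#'                                           n_modules = 5, seed = 7))
#' length(truth$modules)
generate_ground_truth <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    regulators <- genes[seq_len(config$n_regulators)]
    targets <- setdiff(genes, regulators)

    conditions <- c(compendium_condition_labels(config),
                    vapply(config$condition_blocks, `[[`, "", "label"))
    named_conditions <- setdiff(conditions, compendium_condition_labels(config))

    ## Regulator activity architecture
    reg_active <- lapply(regulators, function(r) {
      sample(conditions, sample(2:4, 1L))
    })
    names(reg_active) <- regulators

    n_cond <- length(conditions)
    reg_levels <- matrix(0, config$n_regulators, n_cond,
                         dimnames = list(regulators, conditions))
    reg_ramps <- matrix(0, config$n_regulators, n_cond,
                        dimnames = list(regulators, conditions))

    ## Modules: sizes, memberships, shared programs
    sizes <- sample(seq(config$module_size_range[1],
                        config$module_size_range[2]),
                    config$n_modules, replace = TRUE)
    if (sum(sizes) > length(targets))
      egr_stop("invalid simulation config: 'n_modules' with these sizes exceeds available genes",
               "egrinet_config_error")
    pool <- sample(targets)
    module_genes <- vector("list", config$n_modules)
    offset <- 0L
    for (m in seq_len(config$n_modules)) {
      module_genes[[m]] <- sort(pool[(offset + 1L):(offset + sizes[m])])
      offset <- offset + sizes[m]
    }

    primaries <- sample(regulators,
                        config$n_modules,
                        replace = config$n_modules > config$n_regulators)
    n_annotated <- min(2L, config$n_modules)
    for (m in seq_len(n_annotated)) {
      ## annotated modules stay active across all named condition blocks
      r <- primaries[m]
      reg_active[[r]] <- unique(c(named_conditions,
                                  sample(compendium_condition_labels(config), 1L)))
    }

    ## fill activity levels and ramps for active conditions; the named
    ## condition blocks are a strong dedicated perturbation (4- to 16-fold
    ## responses), compendium blocks are milder routine conditions
    for (r in regulators) {
      act <- reg_active[[r]]
      named <- act %in% named_conditions
      mag <- ifelse(named, runif(length(act), 2, 4),
                    runif(length(act), 0.8, 2.5))
      reg_levels[r, act] <- sample(c(-1, 1), length(act), TRUE,
                                   prob = c(0.35, 0.65)) * mag
      reg_ramps[r, act] <- rnorm(length(act), 0, 0.75)
    }

    modules <- vector("list", config$n_modules)
    B <- matrix(0, config$n_genes, config$n_regulators,
                dimnames = list(genes, regulators))
    for (m in seq_len(config$n_modules)) {
      primary <- primaries[m]
      active <- reg_active[[primary]]
      n_extra <- sample(0:2, 1L)
      extras <- if (n_extra > 0)
        sample(setdiff(regulators, primary), n_extra) else character()
      shared_regs <- c(primary, extras)
      shared_beta <- sample(c(-1, 1), length(shared_regs), TRUE,
                            prob = c(0.3, 0.7)) * runif(length(shared_regs), 1.0, 2.5)
      names(shared_beta) <- shared_regs

      ## private regulators: quiescent throughout the module's active
      ## conditions, so coherence is lost exactly outside them; regulators
      ## with the least activity overlap are preferred when fully disjoint
      ## ones are scarce
      overlap <- vapply(reg_active, function(a)
        length(intersect(a, active)), 1L)
      pool <- setdiff(names(sort(overlap)), shared_regs)
      gset <- module_genes[[m]]
      for (g in gset) {
        scale_g <- runif(1, 0.75, 1.25)
        B[g, shared_regs] <- shared_beta * scale_g
        n_priv <- min(2L, length(pool))
        if (n_priv > 0L) {
          ## weight the draw toward the least-overlapping regulators
          priv <- sample(head(pool, max(n_priv, min(8L, length(pool)))),
                         n_priv)
          B[g, priv] <- sample(c(-1, 1), length(priv), TRUE) *
            runif(length(priv), 1.0, 2.0)
        }
      }
      modules[[m]] <- list(
        id = sprintf("m%03d", m),
        genes = gset,
        conditions = sort(active),
        regulators = shared_regs,
        program = shared_beta,
        annotated = m <= n_annotated
      )
    }

    ## background genes: small private programs
    in_module <- unique(unlist(module_genes))
    background <- setdiff(targets, in_module)
    for (g in background) {
      k <- sample(1:2, 1L)
      regs <- sample(regulators, k)
      B[g, regs] <- sample(c(-1, 1), k, TRUE) * runif(k, 0.8, 2.0)
    }

    ## annotation sets: one engineered superset plus random distractor sets
    annotated_genes <- unique(unlist(module_genes[seq_len(n_annotated)]))
    n_distract <- min(length(background), 35L)
    perox <- sort(unique(c(annotated_genes, sample(background, n_distract))))
    annotation_sets <- list(peroxisome_like = perox)
    for (i in seq_len(8)) {
      annotation_sets[[sprintf("random_set_%02d", i)]] <-
        sort(sample(genes, sample(20:60, 1L)))
    }

    motif_library <- random_motif_library(regulators, config$motif_length)

    edges <- which(B != 0, arr.ind = TRUE)
    edge_df <- data.frame(
      regulator = regulators[edges[, 2L]],
      target = genes[edges[, 1L]],
      beta = B[edges],
      stringsAsFactors = FALSE
    )
    edge_df <- edge_df[order(edge_df$regulator, edge_df$target), ]
    rownames(edge_df) <- NULL

    true_binding <- split(edge_df$target, edge_df$regulator)

    ## two tandem sites per regulated promoter (multiple binding sites are
    ## the norm for strongly regulated genes and are what the multi-hit
    ## motif route keys on); the pair is kept non-overlapping
    max_offset <- config$promoter_downstream - config$motif_length
    window <- seq(-config$promoter_upstream, max_offset)
    offsets1 <- sample(window, nrow(edge_df), replace = TRUE)
    offsets2 <- sample(window, nrow(edge_df), replace = TRUE)
    for (it in seq_len(50L)) {
      clash <- abs(offsets2 - offsets1) < config$motif_length + 2L
      if (!any(clash)) break
      offsets2[clash] <- sample(window, sum(clash), replace = TRUE)
    }
    planted_sites <- data.frame(
      regulator = rep(edge_df$regulator, 2L),
      gene = rep(edge_df$target, 2L),
      offset = c(offsets1, offsets2),
      stringsAsFactors = FALSE
    )

    gene_models <- data.frame(
      gene = genes,
      chrom = "chrS",
      strand = rep_len(c("+", "-"), config$n_genes),
      tss = 2500L * seq_len(config$n_genes),
      stringsAsFactors = FALSE
    )

    programs <- apply(B, 1L, function(row) row[row != 0], simplify = FALSE)

    truth <- list(
      genes = genes, regulators = regulators, conditions = conditions,
      named_conditions = named_conditions,
      modules = modules, programs = programs, coefficients = B,
      edges = edge_df, annotation_sets = annotation_sets,
      motif_library = motif_library, planted_sites = planted_sites,
      true_binding = true_binding, gene_models = gene_models,
      reg_active = reg_active, reg_levels = reg_levels,
      reg_ramps = reg_ramps, config = config
    )
    class(truth) <- "egrin_truth"
    truth
  })
}

#' Labels of the compendium pseudo-condition blocks
#'
#' The compendium emulates many small studies: blocks of about five
#' experiments each, every block its own environmental condition.
#' @noRd
compendium_condition_labels <- function(config) {
  n_blocks <- max(1L, ceiling(config$n_compendium_experiments / 5))
  sprintf("C%02d", seq_len(n_blocks))
}

#' Random position weight matrix with a dominant consensus base per column
#' @noRd
random_pwm <- function(len, dominant = 0.85, consensus_codes = NULL) {
  bases <- c("A", "C", "G", "T")
  pwm <- matrix((1 - dominant) / 3, 4L, len, dimnames = list(bases, NULL))
  hit <- if (is.null(consensus_codes)) sample(4L, len, replace = TRUE)
         else consensus_codes
  pwm[cbind(hit, seq_len(len))] <- dominant
  pwm
}

#' One PWM per regulator with mutually distinct consensus sequences
#'
#' Rejection-samples consensi so that every pair differs in at least
#' `min_dist` positions on both strands; otherwise near-identical motifs
#' make planted sites of one regulator read out as evidence for another.
#' @noRd
random_motif_library <- function(regulators, len,
                                 min_dist = min(3L, len - 1L)) {
  chosen <- matrix(0L, 0, len)
  out <- vector("list", length(regulators))
  names(out) <- regulators
  for (i in seq_along(regulators)) {
    for (try in seq_len(500L)) {
      cand <- sample(4L, len, replace = TRUE)
      cand_rc <- rev(5L - cand)
      ok <- nrow(chosen) == 0L ||
        (min(rowSums(chosen != rep(cand, each = nrow(chosen)))) >= min_dist &&
         min(rowSums(chosen != rep(cand_rc, each = nrow(chosen)))) >= min_dist)
      if (ok) break
    }
    chosen <- rbind(chosen, cand)
    out[[i]] <- random_pwm(len, consensus_codes = cand)
  }
  out
}

#' Consensus sequence of a position weight matrix
#' @param pwm a 4 x L probability matrix with rows A, C, G, T.
#' @return a character scalar of length L.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
}

#' @export
print.egrin_truth <- function(x, ...) {
  cat(sprintf(
    "egrin ground truth: %d genes, %d regulators, %d modules, %d true edges\n",
    length(x$genes), length(x$regulators), length(x$modules), nrow(x$edges)))
  invisible(x)
}
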