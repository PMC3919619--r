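#' Simulation configuration
#'
#' Bundles every tunable of the synthetic regulatory system. The defaults are
#' the study conditions the package benchmarks itself under: a 2000-gene
#' genome with 60 candidate regulators, 50 co-regulated modules of 10-40
#' genes, a 150-experiment compendium spread over ten pseudo-condition blocks,
#' and a 70-experiment condition-specific set split into the three named
#' fatty-acid induction conditions (30 low-sugar "LS", 19 early-oleate "EO",
#' 21 late-oleate "LO" experiments).
#'
#' @param n_genes number of genes in the synthetic genome.
#' @param n_regulators number of genes flagged as candidate regulators.
#' @param n_modules number of planted co-regulated modules.
#' @param module_size_range integer vector of length 2, inclusive bounds on
#'   module sizes.
#' @param n_compendium_experiments number of compendium (training) arrays.
#' @param condition_blocks list of condition-specific experiment blocks, each
#'   a list with elements `label`, `n` and `times` (hours, length `n`).
#' @param noise_sd standard deviation of the Gaussian expression noise added
#'   to every target profile (log2 units).
#' @param knockout_value log2 ratio assigned to a deleted regulator.
#' @param deletion_indirect relative magnitude of gene-specific indirect
#'   knockout responses: each true target's deletion response gains an
#'   independent Gaussian component with standard deviation
#'   `deletion_indirect` times its direct shift. Knockout strains
#'   re-balance entire pathways, so co-regulated genes respond with
#'   heterogeneous magnitudes — this is what lets a deletion "shatter" the
#'   expression coherence of a module. Set to 0 for the idealized
#'   direct-effects-only system.
#' @param motif_length length in bases of every regulator binding motif.
#' @param corruption per-base probability that a planted motif site deviates
#'   from the consensus.
#' @param gc GC fraction of the background promoter composition.
#' @param promoter_upstream,promoter_downstream extent of the promoter window
#'   around the transcription start site, in bases.
#' @param seed integer seed; every generator draws from a stream derived from
#'   it, so a configuration pins the whole synthetic system.
#'
#' @return an object of class `egrin_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_regulators = 12, n_modules = 6)
#' cfg$n_modules
sim_config <- function(n_genes = 2000,
                       n_regulators = 60,
                       n_modules = 50,
                       module_size_range = c(10L, 40L),
                       n_compendium_experiments = 150,
                       condition_blocks = default_condition_blocks(),
                       noise_sd = 0.3,
                       knockout_value = -4,
                       deletion_indirect = 0.5,
                       motif_length = 8L,
                       corruption = 0.1,
                       gc = 0.5,
                       promoter_upstream = 1000L,
                       promoter_downstream = 100L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_regulators = as.integer(n_regulators),
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    n_compendium_experiments = as.integer(n_compendium_experiments),
    condition_blocks = condition_blocks,
    noise_sd = noise_sd,
    knockout_value = knockout_value,
    deletion_indirect = deletion_indirect,
    motif_length = as.integer(motif_length),
    corruption = corruption,
    gc = gc,
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    seed = as.integer(seed)
  )
  class(cfg) <- "egrin_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default condition-specific blocks (the fatty-acid induction design)
#' @return list of blocks with labels LS, EO and LO.
#' @export
default_condition_blocks <- function() {
  list(
    list(label = "LS", n = 30L, times = rep(0, 30)),
    list(label = "EO", n = 19L, times = rep(0.5, 19)),
    list(label = "LO", n = 21L, times = rep(5, 21))
  )
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    egr_stop(sprintf("invalid simulation config: '%s' %s", field, why),
             "egrinet_config_error")
  }
  for (f in c("n_genes", "n_regulators", "n_modules",
              "n_compendium_experiments", "motif_length")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      bad(f, "must be a positive count")
  }
  if (cfg$n_regulators >= cfg$n_genes)
    bad("n_regulators", "must be smaller than n_genes")
  msr <- cfg$module_size_range
  if (length(msr) != 2L || any(is.na(msr)) || msr[1] > msr[2])
    bad("module_size_range", "must be an ordered pair")
  if (msr[1] < 3L || msr[2] > cfg$n_genes)
    bad("module_size_range", "must lie within [3, n_genes]")
  if (msr[1] * cfg$n_modules > cfg$n_genes - cfg$n_regulators)
    bad("n_modules", "cannot be housed by the non-regulator genes")
  if (is.na(cfg$noise_sd) || cfg$noise_sd < 0)
    bad("noise_sd", "must be >= 0")
  if (is.null(cfg$deletion_indirect) || cfg$deletion_indirect < 0)
    bad("deletion_indirect", "must be >= 0")
  if (cfg$corruption < 0 || cfg$corruption > 1)
    bad("corruption", "must be a probability")
  if (cfg$gc <= 0 || cfg$gc >= 1)
    bad("gc", "must be in (0, 1)")
  if (cfg$motif_length > cfg$promoter_upstream + cfg$promoter_downstream)
    bad("motif_length", "exceeds the promoter window")
  if (!is.list(cfg$condition_blocks) || length(cfg$condition_blocks) == 0L)
    bad("condition_blocks", "must be a non-empty list")
  for (b in cfg$condition_blocks) {
    if (!all(c("label", "n", "times") %in% names(b)) || b$n <= 0L ||
        length(b$times) != b$n)
      bad("condition_blocks", "entries need label, n and n time points")
  }
  invisible(cfg)
}

#' @export
print.egrin_sim_config <- function(x, ...) {
  cat(sprintf(
    "egrin simulation config: %d genes (%d regulators), %d modules [%d-%d]\n",
    x$n_genes, x$n_regulators, x$n_modules,
    x$module_size_range[1], x$module_size_range[2]))
  cat(sprintf("  %d compendium experiments + blocks: %s\n",
              x$n_compendium_experiments,
              paste(vapply(x$condition_blocks,
                           function(b) sprintf("%s(%d)", b$label, b$n), ""),
                    collapse = ", ")))
  cat(sprintf("  noise_sd=%.3g knockout=%.3g motif_length=%d seed=%d\n",
              x$noise_sd, x$knockout_value, x$motif_length, x$seed))
  invisible(x)
}
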