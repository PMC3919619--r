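#!/usr/bin/env Rscript
# Generate the synthetic study system and materialize every pipeline input.
#
# The system emulates the statistical structure of a fatty-acid induction
# compendium study: 2000 genes with 60 candidate regulators, 50 planted
# co-regulated modules (two of them "peroxisome-like" annotated modules
# active under all three named induction conditions), a 150-array
# compendium over ~30 pseudo-conditions, and 30 LS / 19 EO / 21 LO
# condition-specific arrays. Outputs land in results/data/.

suppressMessages(library(egrinet))

seed <- 1L
cfg <- sim_config(seed = seed)
print(cfg)

truth <- generate_ground_truth(cfg)
print(truth)
exprs <- simulate_expression(truth, cfg)
print(exprs)

annotated <- Filter(function(m) isTRUE(m$annotated), truth$modules)
cat(sprintf("annotated modules: %s (sizes %s; primaries %s)\n",
            paste(vapply(annotated, `[[`, "", "id"), collapse = ", "),
            paste(vapply(annotated, function(m) length(m$genes), 1L),
                  collapse = ", "),
            paste(vapply(annotated, function(m) m$regulators[1], ""),
                  collapse = ", ")))

binding <- simulate_binding_and_promoters(
  truth, cfg, regulators = unique(vapply(annotated, function(m)
    m$regulators[1], "")))
paths <- simulate_to_dir(truth, exprs, binding, "results/data")
cat("wrote:\n")
print(paths)
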