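# egrinet

Reconstruction of environment and gene regulatory influence networks
(EGRINs) from log-ratio expression compendia, with a fully seeded
synthetic benchmark system.

## The problem

A compendium of public expression arrays contains enough signal to
predict how a genome responds to conditions that were never part of the
compendium — but mining it into *mechanism* requires more than one
global regression. egrinet implements a three-level strategy:

1. **Level 1 — global network.** Genes are clustered into modules whose
   per-experiment expression *coherence* is tested against empirical
   variance backgrounds (random gene sets of the same size), and every
   target is given a sparse regulatory program

   *y* = β₀ + Σⱼ βⱼ xⱼ

   by elastic-net regression on candidate regulator profiles (positive
   coefficients are activators, negative repressors; the temporal decay
   term is fixed at zero). Candidate regulators of an annotation of
   interest are ranked by combining bicluster-regulation p-values with
   the clusters' conditional coherence.
2. **Level 2 — condition-specific refinement.** A small dedicated
   experiment set drives three filters (significance of change,
   prediction accuracy under experiment shuffling, condition coherence
   by the strict-majority rule), programs are re-fitted on the condition
   data, and coefficients are merged with the compendium programs with
   condition-specific priority.
3. **Level 3 — gene-level evidence integration.** Six streams of
   evidence — regression influence, deletion differential expression,
   bicluster shattering, promoter binding events in the [−1000, +100] bp
   TSS window, exact-null PWM motif scanning, imported de-novo motif
   assignments — are combined, and only edges supported by **two or more
   distinct streams** enter the high-confidence network, weighted by the
   mean −log₁₀ of quantile-normalized p-values.

Because the original compendium-scale inputs are not reproducible at
desk scale, the package ships a first-class synthetic-data generator
that emulates their statistical structure (condition-coherent modules,
linear regulator programs, two-tailed deletion responses with indirect
knockout heterogeneity, promoter-proximal binding, planted tandem motif
sites) and provides the ground truth against which all recovery
benchmarks are scored.

## Worked example

```r
library(egrinet)

cfg   <- sim_config(n_genes = 500, n_regulators = 30, n_modules = 6,
                    module_size_range = c(8, 12),
                    n_compendium_experiments = 80, seed = 42)
res   <- egrin_analysis(cfg, fit = fit_config(seed = 42))

res$evaluation$level1_precision      # edge precision of compendium programs
res$evaluation$integrated_precision  # precision of the >=2-stream network
head(res$rank2)                      # ranked candidate regulators
```

A full-scale run of the same machinery is scripted in `analysis/`:

```sh
Rscript analysis/01_simulate.R      # system + every pipeline input -> results/data/
Rscript analysis/02_run_pipeline.R  # three levels -> results/run/ (+ manifest)
Rscript analysis/03_benchmark.R     # ten-seed recovery table -> results/benchmark.tsv
Rscript analysis/04_noise_free.R    # exact-identity check -> results/noise_free.json
```

`analysis/02_run_pipeline.R` prints the run's headline numbers; on the
default system (seed 1) it reports:

```
Level 1 edge precision/recall: 0.977 / 1.000
Level 2 filtered precision:    0.974 (recall 0.692)
Integrated >=2-stream network: 1541 edges, precision 0.885, recall 0.996
Cluster vs gene MCC: 0.875 vs 0.778 (AUC 0.995 vs 0.986)
Deletion sign agreement 1.000 (correlation 0.907)
True annotated-module regulator rank: 1 of 60
```

Read: the genome-wide elastic-net programs recover planted regulator →
target edges nearly perfectly at noise sd 0.3; cluster-level
aggregation improves the deletion-validated classifier over per-gene
calls (0.875 vs 0.778 MCC — the per-gene deletion readout misses weak
responders that cluster enrichment recovers); and the regulator planted
as the driver of the annotated ("peroxisome-like") modules surfaces at
the top of the candidate ranking. Every artifact the run writes (programs, coherence
report, evidence table, SIF network with a Cytoscape-loadable JSON
attribute table, manifest with seeds and checksums) lands under
`results/run/`.

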