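---
title: "Methods: three-level regulatory influence network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level regulatory influence network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

egrinet reconstructs an environment and gene regulatory influence network
(EGRIN) from a log-ratio expression compendium in three levels of
resolution.

**Regulatory programs.** Every target gene (or cluster mean) $y$ is
modelled as a sparse static linear combination of candidate regulator
expression profiles $x_j$:

$$ y = \beta_0 + \sum_j \beta_j x_j + \varepsilon $$

fitted by elastic-net regression. Regulators with $\hat\beta_j > 0$ are
read as activators, $\hat\beta_j < 0$ as repressors. Two modelling
restrictions are deliberate: the temporal decay term of classical
influence models is fixed at zero (the compendium mixes chemostat- and
batch-style experiments whose time axes are not commensurable, and the
temporal resolution is too coarse to estimate decay), and no logical
interaction ("and") terms are formed, which keeps the number of candidate
predictors linear in the regulator count.

**Biclusters and coherence.** Genes are grouped into putatively
co-regulated modules, and each module is assigned the *experiments* and
*conditions* in which it behaves as a unit. The statistic is the
within-cluster expression variance in one experiment, referred to an
empirical background: the variance of `n_resamples` random gene sets of
the same size in the same experiment. The coherence p-value is the
add-one-corrected fraction of background variances at or below the
observed one, so a cluster is "coherent" where its genes sit unusually
close together. A cluster is coherent under a *condition* when strictly
more than half of that condition's experiments are coherent — the strict
majority rule.

**Three levels.**

* *Level 1 (global):* z-score normalization, clustering, coherence
  testing, genome-wide program fits on the compendium, and a ranked list
  of candidate regulators of an annotation of interest.
* *Level 2 (condition-specific):* three filters driven by a small
  dedicated experiment set — (1) keep only targets whose expression
  changes significantly in the condition experiments, (2) keep only
  targets whose Level-1 predictions are accurate on the condition
  experiments (shuffle-based correlation significance), (3) keep only
  targets inside condition-coherent clusters — then programs are
  re-fitted on the condition data (candidate regulators restricted to
  the significantly changing ones: that is where the regulator side of
  filter 1 acts) and merged with the compendium programs,
  condition-specific coefficients taking priority so that a handful of
  targeted experiments is not outvoted by the compendium. Pruning
  regulator terms out of the *compendium* programs instead would remove
  compendium-validated edges that the condition experiments simply
  cannot see, which is why the filter is target-side there.
* *Level 3 (gene-level):* six evidence streams — regression influence,
  deletion differential expression, bicluster shattering, promoter
  binding, known-motif scanning, imported de-novo motif assignments — are
  integrated, and only edges supported by at least two distinct streams
  enter the high-confidence network. Edge weights are the mean
  $-\log_{10}$ of quantile-normalized p-values across the supporting
  streams, so no stream dominates merely because its p-values run small.

# The synthetic study system

The generator (`sim_config()`, `generate_ground_truth()`,
`simulate_expression()`, `simulate_deletion()`,
`simulate_binding_and_promoters()`) produces every input the pipeline
consumes, together with the ground truth needed to score recovery. Its
defaults are the package's study conditions:

| parameter | default | why |
|---|---|---|
| genes / regulators | 2000 / 60 | a genome-scale problem at desk scale; the regulator list emulates a curated candidate set |
| modules | 50, sizes 10–40 | cluster-scale co-regulation; two modules are "annotated" and active under every named condition |
| compendium | 150 arrays in ~30 pseudo-condition blocks of ~5 | a compendium is many small studies; block structure plus per-experiment activity jitter (sd 0.35) is what makes individual regulators identifiable |
| condition set | 30 LS + 19 EO + 21 LO arrays | the named induction design |
| expression noise | sd 0.3 (log2) | array-scale measurement noise |
| knockout readout | −4 (log2) | strong, detectable, finite |
| deletion indirect heterogeneity | 0.5 × direct shift | knockout strains re-balance pathways; per-gene heterogeneous responses are what lets a deletion *shatter* a module's coherence. Without it a knockout translates a module rigidly and no shattering signal exists at all |
| motifs | 8 bp, consensi ≥ 3 mismatches apart, 2 sites per regulated promoter, 10% per-base corruption | distinct motifs keep the motif stream a test of scanning rather than of paralog disambiguation; tandem sites are the norm for strongly regulated promoters and are what the multi-hit route keys on |

Mechanically, each regulator carries a latent activity signal: a
condition-specific base level (drawn at magnitude 0.8–2.5 for compendium
blocks and 2–4 for the named induction conditions, which model a strong
dedicated perturbation) plus a temporal ramp within a block and
per-experiment jitter. A module's genes share a program over one to three
regulators (with per-gene coefficient scaling), and each module gene also
carries *private* coefficients on regulators active only outside the
module's conditions — that is precisely what makes a module coherent
exactly where its drivers are active and incoherent elsewhere. Targets
are exactly linear in regulator activities, so with all noise sources at
zero the inference problem has an exact solution and the pipeline is
required to find it.

**What the generator does not emulate:** realistic promoter composition
and chromatin context; regulator cascades (regulators are latent sources,
not targets of one another); growth-rate confounding between deletion
strains and wild type; array platform artifacts (dye bias, spatial
effects); post-transcriptional regulation. Passing the recovery
benchmarks therefore demonstrates that the machinery is a correct
inverse of this generative model at realistic noise levels — not that it
would achieve the same operating point on real arrays.

# Tunable parameters of the analysis

* `alpha = 0.05` everywhere a call is made (coherence, enrichment,
  changing-genes filter, accurate-prediction filter, deletion DE,
  de-novo import), with Benjamini–Hochberg control wherever a family of
  tests is adjusted. 0.05 is the cutoff used throughout the source
  protocol wherever one is printed.
* `mixing = 0.5`: the elastic-net compromise; it does not arbitrarily
  drop members of correlated regulator groups the way the lasso does.
* Penalty selection: 5-fold cross-validation at minimum error, on a
  15-point penalty path down to 5% of the largest penalty. With ~150
  experiments, 10-fold folds of 15 produce noisy curves at double the
  cost; the coarse path loses nothing because of pruning (next item).
  Ties resolve toward the larger penalty (the sparser model);
  `"cv-1se"` and fixed penalties are available.
* `prune_fraction = 0.2`: after shrinkage, coefficients below 20% of the
  program's largest are treated as zero. Cross-validated penalties
  optimize prediction, not support recovery, and leave a fringe of
  near-zero nuisance coefficients on correlated decoys; in the synthetic
  system true and nuisance coefficients are separated by roughly a factor
  of three, and the relative threshold removes the fringe without touching
  genuine secondary regulators.
* Background resamples: 1000 for coherence variance backgrounds and for
  bicluster-assignment backgrounds (matching the shuffle count used for
  correlation significance), with the add-one correction so no empirical
  p is exactly zero.
* `k`: the clustering front-end asks for the planted module count plus
  20% slack clusters, and `refine_clusters()` then drops members
  correlating below 0.4 with their cluster mean — a partition front-end
  must put every gene somewhere, but a co-regulated module need not cover
  the genome, and cluster-expanded evidence (shattering, de-novo motifs)
  should operate on tight cores.
* Promoter window: 1000 bp upstream to 100 bp downstream of the TSS,
  measured along the gene's own strand; binding events on either strand
  count, and an event inside two divergent genes' windows assigns to
  both. Strong binding evidence is `p <= 0.01`, anything else reported is
  weak evidence.
* Motif calls: per-window p-values are **exact** tail probabilities of
  the integerized log-odds score under the background model, computed by
  dynamic programming over motif positions (no Gaussian or extreme-value
  approximation). Window hits pass a Bonferroni correction over all
  windows on both strands. The multi-hit route combines hits by Fisher's
  method, Bonferroni-corrected across scanned genes, and requires at
  least two hits — at genome scale a single borderline window carries no
  multi-site information; the best-hit route recalibrates the best
  window p against the best-of-n background and calls at 0.01. Either
  route is motif evidence.
* Shattering: a deletion shatters a cluster when the within-cluster
  variance in the deletion experiment exceeds more than 95% of the
  cluster's wild-type variances over the condition experiments. The test
  is run only for (cluster, condition) pairs that are condition-coherent
  in the wild type — a cluster that was never coherent under a condition
  cannot lose coherence there. A gene in several shattered clusters keeps
  its minimum p.
* Integration: at least two distinct streams per (regulator, target,
  condition); motif and binding streams are condition-less and apply to
  every condition present; stream p-values are rank-mapped onto the
  pooled empirical distribution (average ranks for ties) before weights
  are averaged.

# Evaluation machinery

The deletion-based metrics mirror the standard definitions: *agreement*
is the fraction of evaluated (regulator, target) predictions whose
activator/repressor role matches the direction of the target's response
to the regulator's deletion; *correlation* is the Pearson correlation of
deletion log-ratios with minus the coefficients. The "fixed" variants
first flip every regulator whose role profile is significantly
anti-correlated (per-regulator Pearson test at 0.05) with the deletion
responses — separating right-target-wrong-sign errors, which are expected
when activator and target rise together, from wrong-target errors. The
full-equation metrics predict each target's deletion response through its
complete program with the deleted regulator at its knockout readout; a
predicted or actual zero matches nothing (the conservative tie rule).

Gene-level classifier metrics (MCC, F1, AUC) treat a (regulator, gene)
pair as a predicted positive when the coefficient is nonzero and as a
true positive when the gene additionally changes significantly on the
regulator's deletion; the pair universe is all evaluated regulators
crossed with the significantly changing genes, and AUC ranks pairs by
coefficient magnitude with unpredicted pairs at zero. Cluster-level
metrics replace pairs with (regulator, cluster): positives are clusters
enriched for the regulator's predicted targets (empirical resampling
background), truth pairs have the cluster enriched for
deletion-responsive genes, and AUC ranks by enrichment $-\log_{10} p$;
both sides are Benjamini–Hochberg adjusted over the same evaluated
family. The gene- versus cluster-level comparison is run on the plain
Level-1 output — the condition filters are a separate axis, scored by
the before/after precision comparison.

A candid note on this comparison: cluster aggregation pays off exactly
when gene-level information is noisy. With the program fits close to
the planted truth, the dominant noise source is the per-gene deletion
readout — a moment normal fit whose scale the strong responders
inflate, so weak targets fall below per-gene significance. Cluster
enrichment recovers them, which is why the cluster-level classifier
beats the gene-level one in the shipped benchmarks.
Mode comparisons use the Wilcoxon signed-rank test (paired; zeros
dropped) or the Mann–Whitney test, exact by enumeration for small
samples without ties, and the two-tailed exact binomial test for
fractions.

# Numerical choices and degenerate inputs

* Empirical p-values always carry the add-one correction; $-\log_{10}$
  transforms floor their argument at `1e-300`.
* Z-scoring a zero-variance experiment yields a zero column with a
  warning rather than an error (simulated deletions can produce
  degenerate replicates); a zero-variance target yields an empty program
  with a warning; a constant series in the correlation test returns a
  degenerate result with p = 1.
* The significance-of-change model fits each experiment's log-ratio
  distribution with robust location and scale (median and MAD): the null
  is the non-changing majority, and moment fits let strong responders
  inflate the null scale and mask themselves. The chi-squared mode
  (degrees of freedom configurable, default 1) matches the squared
  standardized ratio's median to the chi-squared median; the
  provided-lambda mode refers precomputed statistics directly to the
  chi-squared tail.
* PWM scores are integerized at 1000 steps per log2 unit; the exact null
  is convolved on that grid, and observed window scores are computed on
  the same grid, so test and null are never misaligned. Ambiguous bases
  score as the column minimum.
* k-means ties and restarts are fixed by seed; every stochastic step
  (backgrounds, shuffles, folds, resampling) draws from a seed derived
  from the simulation seed, so a run is reproducible from its manifest.

# Scale of the shipped benchmarks

The recovery benchmarks (`egrin_benchmark()`) run the complete analysis
on ten seeds at the full study conditions; the test suite reuses one
shared set of those runs. Oracle-equivalence and calibration checks use
small instances where brute-force enumeration is exact (universes up to
~30 genes, motif length up to 6, sample sizes up to 10). The noise-free
identity check runs a 300-gene system, since the identity is exact at
any size.

# Known limitations

* The interchangeable clustering front-end is k-means with refinement,
  not a full biclustering optimizer; module recovery therefore depends on
  modules being separated in correlation distance, which the generator
  guarantees but real data need not.
* Condition-specific program fits see only three distinct conditions (70
  experiments), so regulators co-active in the named conditions are
  statistically interchangeable there; the condition-priority merge
  inherits that ambiguity. This is visible in the ranking, where
  co-active regulators can tie with the true driver.
* The ranking score's empirical regulation p-values are floored at
  1/(resamples+1), so very strong regulators tie and order within ties is
  lexicographic.
* Evidence streams expanded from cluster calls (shattering, de-novo
  motifs) inherit cluster impurity: a cluster member that is not a true
  target of the regulator still receives the expanded edge. The two-stream
  rule is what keeps such edges out of the final network unless a second
  line of evidence concurs.
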