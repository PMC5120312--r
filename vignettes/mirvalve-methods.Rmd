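---
title: "Methods: integrated miRNA/mRNA analysis with mirvalve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA/mRNA analysis with mirvalve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvalve)
```

`mirvalve` implements the statistical core of an integrated
miRNA/mRNA expression study of diseased versus control tissue, the setting
being calcific aortic valve stenosis: cases are surgically explanted
stenotic valves, controls post-mortem valves, and the biological question
is which microRNAs are dysregulated and which of their predicted target
genes show the anti-correlated expression that repression predicts. This
vignette is the package's own account of each model and of the design
choices that were genuinely open.

## Differential expression

Each feature of a log2 expression matrix is tested with Welch's
unequal-variance *t*-test. The unequal-variance form is a deliberate
default: the two tissue sources differ in size and in provenance (surgical
vs post-mortem), so assuming a common variance is the riskier choice.
P-values are adjusted with the Benjamini–Hochberg step-up procedure and
features with adjusted p < α (default 0.05) are flagged. Fold change is
reported both as the signed log2 difference (case − control) and as the
linear ratio `2^Δ`, so "up-regulated more than 2-fold" means log2fc > 1.

Degenerate inputs follow fixed conventions rather than erroring mid-scan:
two exactly constant groups give t = 0, p = 1 when the means agree and
|t| = ∞, p = 0 when they differ; groups of fewer than two samples are a
validation error.

Group structure is summarised by PCA (components sign-fixed by making the
largest-magnitude loading positive, so results are deterministic) and by
average-linkage hierarchical clustering — correlation distance
`1 − r` for features, Euclidean for samples. Features are sorted by ID
before clustering, which makes the ordering invariant to input row order.
No linkage was dictated by the original design; average linkage on
correlation distance is the common choice for expression heatmaps. When
multiple probes map to one gene, the probe with the highest mean
expression is kept; the collapse rule was likewise unspecified upstream,
and highest-mean is the convention that preserves the best-measured probe.
No variance pre-filter is applied before testing.

## Co-expression network and Markov clustering

Edges connect DE miRNAs with Pearson correlation above 0.5. The default
mode is the literal rule `r > 0.5`; an `"absolute"` mode (`|r| > 0.5`) is
available because whether the original network tool thresholded signed or
absolute correlation is ambiguous. Weights are stored signed for
reporting; the random-walk transition matrix uses `|r|`, since transition
probabilities must be non-negative.

The Markov Clustering implementation is written from first principles.
Self-loops of weight 1 are added (standard MCL practice; they prevent
oscillation on bipartite-like structures), the adjacency matrix is column
normalized, and the algorithm alternates expansion (matrix power, fixed at
2) with inflation (entrywise power, default 2.0 — the conventional
granularity default) followed by column renormalization. Entries below
`prune_below` (default 1e−5) are zeroed each iteration, with the guard
that a column's maximum entry is never pruned; iteration stops when the
maximum entrywise change drops below `tol` (1e−6) or after `max_iter`
(100) iterations, in which case the result is returned with
`converged = FALSE` and a warning. Clusters are read off attractor rows
(nonzero diagonal); attractors still exchanging mass form one attractor
system, and each node joins the system from which it receives the most
mass, ties resolved toward the smallest cluster ID — MCL can natively
produce overlapping interpretations, and this resolution yields the
disjoint partition the downstream stages need. Nodes are processed in
sorted order, so the partition is invariant to input relabeling.

## Integration with a permutation null

Candidate interactions are pairs (miRNA, gene) in the target-score table
with both members differentially expressed and a mean prediction score
≥ 0.8 (duplicate rows, e.g. multiple transcripts, are aggregated by their
mean before filtering — the "mean target score" semantics). Each candidate
is scored by Spearman correlation across paired per-sample profiles; at
the paired design size (n = 20) exact rank-permutation p-values are
impractical, so the t-approximation on n − 2 degrees of freedom is used,
with midranks for ties. The default test is one-sided for negative
correlation, because repression — the modelled mechanism — predicts the
sign; a two-sided mode is provided since upstream conventions are
unstated. BH adjustment runs across all candidates.

The significance of the interaction *count* is assessed by permuting the
identity labels of the DE miRNAs among their expression rows, which breaks
the identity→target link while leaving the expression correlation
structure intact, and re-running the caller. With `b` of `N` permutations
reaching the observed count, the add-one estimator `p = (b + 1)/(N + 1)`
is used, so the p-value can never be 0 and "higher than any of 100
permutations" reports 1/101 < 0.01. The 95% interval on the exceedance
proportion `b/N` is the exact Clopper–Pearson interval from Beta
quantiles; for b = 0, N = 100 its upper bound is `1 − 0.025^(1/100)` =
0.0362. Because the candidate list is fixed under relabeling, the
implementation precomputes the rank-correlation matrix once and evaluates
each permutation by indexing; a test verifies this kernel is identical to
naively re-running the caller on a relabelled matrix.

The permutation p-value is conservative when the count distribution is
concentrated: ties with the observed count inflate `b` by construction.
Its calibration test therefore uses a dense decoy prediction table
(4000 decoy rows), giving the count enough spread for the discrete null
to approximate uniformity; with sparse candidates the p-value remains
valid but visibly conservative.

## Over-representation and drug-target triage

Gene sets (GMT) are trimmed to the assay universe and tested with the
two-sided hypergeometric test. The two-sided p is the doubled smaller
tail, capped at 1 — the conventional symmetric construction, documented
here because other two-sided constructions (e.g. summing all masses below
the observed one) exist. The universe defaults to all genes on the
collapsed mRNA matrix.

Drug-target triage keeps genes that are in the integrated network,
up-regulated more than 2-fold, and annotated with at least one drug whose
interaction type (case-insensitive exact token) is inhibitor, antagonist
or antibody. The report separates connected genes (network degree ≥ 2)
from peripheral ones. The source design stated the degree rule both as
"more than two" and as "two or more" while tabulating degree-2 genes;
the default follows the tabulated behaviour (≥ 2) and is configurable.

## qPCR statistics

Wells with Ct above 35 cycles are treated as not detected and excluded
(not imputed — downstream handling was unspecified upstream, and
exclusion is the assumption-free choice). ΔCt subtracts the arithmetic
mean Ct of the two reference probes, equivalent to a geometric mean in
linear space; relative expression is `2^−ΔCt` and a planted fold change
`f` appears as ΔΔCt = −log2(f). Group comparisons use the Mann–Whitney
test: exact enumeration of the U distribution when the combined sample
size is ≤ 20 and the pooled values are tie-free, otherwise the normal
approximation with tie and continuity corrections; the method used is
reported. Statistics always use all retained wells — outlier trimming is
a display concern only.

Reference-gene choice uses a NormFinder-style variance decomposition on
log-scale data. Each sample is centred across the candidate genes,
removing sample loading; per group, the per-gene residual variance is
recovered from the centred values by inverting the mixing the centring
introduces (each row absorbs 1/k of every other row's noise — this is why
at least three candidates are required), clamped at zero. The per-gene
intergroup deviation is estimated from group means of the centred values,
corrected for its sampling error and shrunk toward zero accordingly. The
stability value is the mean absolute shrunken intergroup deviation plus
the root mean intragroup sampling variance — lower is more stable. This
combination keeps ranking sensible in both regimes: genes with no group
effect are ordered by residual noise, and any systematic group difference
dominates the score.

## The synthetic-data generator

The generator's defaults encode the emulated study's conditions and were
fixed once: 15 cases vs 16 controls on the arrays (the first 10 of each
forming the paired integration subset), 16 vs 36 in the qPCR table; 150
miRNAs of which 30 are DE with 75% down-regulated (mirroring a reported
majority of ~80/106 down); five co-expression clusters with within-cluster
correlation 0.7; 300 genes with 60 independently DE; 25 planted repressive
pairs at Spearman strength 0.8; log2 shift 1.5 at residual SD 0.5 (an
effect of three residual SDs, the regime in which the sensitivity
guarantee is stated); prediction scores in [0.85, 1] for planted pairs and
[0.6, 0.95] for 250 random decoy rows, straddling the 0.8 threshold so the
score filter does real work.

Clusters use a shared latent factor,
`x = sqrt(ρ)·z_cluster + sqrt(1−ρ)·ε`, giving exactly the target pairwise
correlation in expectation. Repressive targets are coupled to the
standardized miRNA profile with latent Pearson correlation
`2·sin(πρ_s/6)`, the value for which a bivariate-normal pair has Spearman
correlation ρ_s; because the coupling includes the miRNA's group shift,
repressed targets are themselves DE in the opposite direction, as
repression implies. At strength 1 the coupling is exactly monotone and the
sample Spearman correlation is −1. All randomness flows from one seed
through an isolated RNG scope; no global random state is disturbed.

What the generator does **not** emulate: probe-level array artifacts,
batch and RNA-quality effects, heavy-tailed or intensity-dependent noise,
correlated mRNA co-expression modules, and target predictions whose
scores correlate with true repression strength. Passing recovery tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not performance on real arrays.

One behaviour of the generative model is worth flagging because it is a
genuine property of anti-correlation integration, not an artifact: any
up-regulated gene anti-correlates with any down-regulated miRNA across
pooled case/control samples, whether or not the pair is causally coupled.
Decoy pairs that happen to link opposite-direction DE features are
therefore frequently called significant — exactly as a correlation-based
integration of real data would call them. The false-call rate is
accordingly measured against all decoy prediction rows (the denominator a
user of a prediction database faces), and the triple filter (DE status,
score ≥ 0.8, FDR on the correlation) keeps it below a few percent under
the default conditions.

## Problem sizes and reproducibility

The test suite exercises recovery at the study's own group sizes (15/16
arrays, 10+10 paired, 16/36 qPCR) with 20 replicate simulations per
stochastic guarantee, and `scripts/acceptance.R` recomputes the headline
quantities with 10 replicates per quantity — sizes chosen as a sensible
desk-scale compromise between Monte-Carlo error and turnaround. Pipeline
runs (`run_all()`) write a manifest keyed by package version, seed and a
hash of the analysis parameters; two runs with the same configuration and
seed are byte-identical, which the tests assert file by file.

## Known limitations

* Moderated-variance (empirical-Bayes) testing, batch correction and
  variance filtering are out of scope; with few samples per group a
  moderated test would typically be more powerful.
* The permutation p-value's resolution is bounded by 1/(N+1) and is
  conservative under count ties (see above).
* The one-sided repression test will not detect targets whose expression
  rises with their miRNA (e.g. indirect effects).
* NormFinder-style stability assumes additive sample loading on the log
  scale and at least three candidates; with exactly two groups the
  intergroup component is estimated from two group means and is
  correspondingly coarse.
* The manual "visual differentiation" fallback sometimes used when few
  markers pass the FDR threshold is inherently interactive and is not
  automated here.
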