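---
title: "Methods: feed-forward-loop discovery in paired tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-forward-loop discovery in paired tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflnet)
```

`fflnet` discovers three-node regulatory motifs — a transcription factor
(TF) and a microRNA that regulate each other (in at least one direction)
and co-regulate a common target gene — from paired tumor versus
matched-adjacent expression data, and asks whether the discovered loop
stratifies patient survival. This vignette documents the statistical model
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-cohort generator does and does not emulate,
and the numerical and design decisions a maintainer should know about.

## Differential expression: an empirical joint-tail probability

The caller is non-parametric and works directly on continuous
RSEM-normalized abundances; no count distribution is assumed.

For every feature that survives the minimum-expression filter (strictly
above 20 normalized counts for genes and TFs, strictly above 10 for
miRNAs, taking the maximum over all samples of both conditions), two
signal statistics are computed from the unweighted condition means:

* `M = log2((mean_tumor + k) / (mean_adjacent + k))`, the shrunken log2
  fold change, with pseudocount `k = 0.5` guarding zeros;
* `D = |mean_tumor − mean_adjacent|`, the absolute expression difference.

The null ("noise") distribution is empirical: for every unordered pair of
samples *within* a condition, the same two statistics (`|m*|`, `d*`) are
computed per feature and pooled across features and both conditions. The
DE probability is the fraction of noise points strictly dominated by the
signal:

```
prob(f) = #{ (|m*|, d*) : |m*| < |M_f| and d* < D_f } / #noise
```

A feature is called differentially expressed iff `prob > 0.99` (strict)
and its linear fold change `2^|M|` is at least 2 (genes) or 1.6 (TFs and
miRNAs — regulators act with amplified downstream effect, so a milder
cutoff is used). The sign of `M` sets the up/down direction.

Decisions worth recording:

* **Fold-change scale.** Published cutoff conventions are ambiguous
  between linear and log2 scale. The default is linear
  (`2^|M| ≥ cutoff`, i.e. cutoff 2 means `|M| ≥ 1`); `fc_scale = "log2"`
  switches to `|M| ≥ cutoff`.
* **Pairing is not used by the statistic.** Condition means are plain
  arithmetic means; the tumor/adjacent pairing shapes the simulation, not
  the test. This matches the "real" (replicate-based) flavor of empirical
  signal/noise DE callers.
* **Noise subsampling.** With `n` samples per condition there are
  `n(n−1)/2` pairs; at the default cap `max_pairs = 30` per condition a
  50-pair cohort contributes 60 pairs × features ≈ 22,000 noise points,
  plenty for a 0.99 tail. The subsample is drawn on columns sorted by
  sample id, so results are invariant to input column order, and the same
  pair indices are used in both conditions, so swapping the condition
  labels flips every `M` and leaves `prob` unchanged exactly.
* **No multiplicity correction.** `prob` is an empirical exceedance
  fraction, not a p-value; the cutoff is used as-is.

A structural property of the pooled-noise design: `d*` from
highly-expressed features dominates the pooled noise, so `prob` for a
weakly-expressed feature is bounded by the rank of its `D` among noise
from *all* features. The caller is therefore intrinsically more sensitive
for well-expressed features — on real data, DE calls are biased toward
high expression. The generator defaults were chosen with this in mind
(below).

## The regulatory network

An interaction-catalog edge is retained iff both regulator and target are
DE; nodes are DE features with at least one retained edge. Multiple
evidence rows for one (regulator, target) collapse into one edge carrying
the evidence set. Edge types follow the regulator class (`tf-target`,
`mirna-target`); a symbol usable as both gene and TF is treated as a TF.
Keeping only both-DE edges is a deliberate reading of how a DE-restricted
co-regulatory network is normally built; the alternative (one DE
endpoint) would produce a much larger, mostly non-differential graph.

## Eight centralities and hub selection

All eight measures are computed on the symmetrized simple undirected
graph — the classical definitions are undirected and no directionality
protocol is imposed:

* `DC` degree; `BC` betweenness (unordered pairs); `CC` closeness,
  per connected component: `(n_c − 1) / Σ d(v, u)`;
* `EC` eigenvector centrality, by power iteration on `A + I` (the shift
  makes the dominant eigenvalue unique on bipartite-like graphs without
  changing eigenvectors), tolerance `1e-12`, at most `1e5` iterations,
  computed on the largest component and 0 elsewhere, L2-normalized,
  nonnegative;
* `SC` subgraph centrality `Σ_j u_j(v)² e^{λ_j}` from the dense adjacency
  eigendecomposition;
* `IC` information centrality via the Stephenson–Zelen matrix
  `C = (L + J)^{-1}`, `IC(v) = [C_vv + (T − 2R_v)/n]^{-1}`, per component;
* `LAC` local average connectivity: mean within-neighborhood degree of a
  node's neighbors; `NC` the sum over incident edges of the edge
  clustering coefficient `z / min(deg−1, deg−1)` (0 where the denominator
  vanishes).

Isolated nodes score 0 on every measure by convention (this includes
`SC`, whose mathematical value at an isolated node would be 1; a uniform
zero keeps "no connections ⇒ no centrality" consistent across measures).
Dense eigendecomposition and matrix inversion are used deliberately:
DE-restricted networks here are at most a few hundred nodes.

Hubs are the intersection of the eight per-measure retained sets, where a
measure retains every node at or above its `(1 − fraction)` quantile
(default fraction 0.5, i.e. the median; ties at the threshold are all
retained, which makes selection deterministic and order-invariant). On
highly skewed measures the tie rule can retain more than half the nodes;
that is accepted as the cost of determinism.

## FFL enumeration and the candidate cascade

A loop is any (TF `t`, miRNA `m`, gene `g`) with edges `t→g` and `m→g`
and at least one of `t→m` / `m→t`; the orientation of the TF–miRNA edge
names the subtype (TF-FFL, miRNA-FFL, composite-FFL). Candidates must
then pass, in order: (a) all three members are hubs; (b) every
participating edge carries ChIP-Seq or TargetScan evidence; (c) every
member has mean expression ≥ 20 in its higher condition and
`|M| ≥ 1` ("high expression, large difference" — no canonical thresholds
exist, so both are configurable and logged); (d) neither the TF nor the
gene is methylation- or CNV-associated. Survivors are ranked by the sum
of members' `|M|`, ties broken lexicographically.

The association test in (d) is a documented stand-in for an unspecified
procedure: per feature, Spearman correlation between expression and the
covariate across shared samples, a permutation p-value (999 permutations
by default, one shared sample permutation per draw), and BH-FDR per
covariate; "affected" requires `|rho| ≥ 0.3` *and* FDR < 0.05. Two
numerical points matter. First, the permutation p-value floor is
`1/(n_perm+1)`, so BH across many features cannot reach FDR 0.05 with 999
permutations if thousands of features are tested; the pipeline therefore
runs the test over the network's genes and TFs — the candidates the
filter actually applies to — keeping the floor well below the FDR cutoff.
Second, constant vectors have no defined rank correlation; such features
are flagged unaffected with a warning rather than dropped.

## Survival stratification

Kaplan–Meier estimation and the two-group Mantel–Cox log-rank test are
delegated to the `survival` package (the product-limit estimator with
events before censorings at ties, and the standard hypergeometric
expectation/variance accumulation); the package's tests verify both
against hand-computed oracles. Grouping rules:

* **Single-gene quartile**: samples are ranked by the gene's expression
  and the `floor(n/4)` smallest / largest form the low / high groups.
  Rank-based grouping makes group sizes exact even with ties (332
  samples give exactly 83 per arm); ties in value are ordered by sample
  id for determinism.
* **Multi-gene median**: each gene is split at its cohort median (ties
  assigned to "low" — deterministic and documented; configurable only by
  preprocessing), the best-prognosis arm is the samples at the low-risk
  level of every gene, the worst-prognosis arm the samples at the
  opposite level of every gene.

Lost-to-follow-up subjects are dropped by default (`"censor"` keeps them
as censored records — standard practice; both supported, the choice is
recorded in the rule). Follow-up is truncated at a horizon (default 60
months); events beyond the horizon become censorings at the horizon.
With no events in either arm the log-rank statistic is degenerate and is
reported as χ² = 0, p = 1 with a warning.

The caliper-based xenograft tumor-volume utility `V = L·W²/2` (mm³) is
included for completeness of the downstream toolbox.

## What the synthetic generator emulates

`simulate_cohort()` produces the full input bundle with known ground
truth. Its defaults are the study conditions the package is tested under:

* **Paired log-normal expression.** Each feature draws a baseline
  log-mean from `Normal(6, 0.5)` (natural log; median ≈ 400 normalized
  counts) and each sample multiplies the baseline by
  `exp(Normal(0, 0.06))` replicate noise; tumor samples of DE features
  additionally multiply by `2^log2fc`. Log-normal is chosen over negative
  binomial because RSEM-normalized values are continuous. The noise and
  baseline spread were fixed by a detectability analysis, not fitted to
  data: for the empirical joint-tail `prob` to recover planted fold
  changes down to `|log2FC| = 1.5` at 50 pairs, the pooled `d*` noise of
  the most expressed features must sit below the `D` of the weakest
  planted effect, which bounds both the replicate noise (log-sd ≈ 0.06)
  and the baseline spread (log-sd ≈ 0.5). Real cohorts are noisier and
  wider; passing the recovery tests shows the caller is correct, not that
  it would reach the same sensitivity on real data.
* **Planted DE.** A fraction `de_fraction` (default 0.1) of features gets
  fold changes with magnitudes uniform on `[1.5, 4]` log2 units. The
  first planted loop emulates the discovered module of the motivating
  study design: its miRNA is up-regulated at the top of the range (+4,
  emulating a top-ranked differential miRNA) with TF and gene down-regulated at
  the top of the range, and background DE magnitudes draw from the lower
  92% of the range, so the planted loop is the strongest differential
  module by construction. Sign pattern: miRNA up, TF down, gene down.
* **Catalog with planted loops and hub-like wiring.** Random edges at
  `catalog_density = 50` expected targets per regulator (interaction
  catalogs compiled from ChIP-Seq/TargetScan collections carry tens to
  hundreds of targets per regulator; much sparser catalogs produce
  degenerate DE-restricted networks). Planted-loop edges (`m→t`, `m→g`
  ChIP-Seq/TargetScan as appropriate, `t→g`) are always present, and the
  members are wired into the differential set — extra targets for the
  miRNA and TF, extra regulators for the gene, with interconnections that
  create triangles — because the emulated discovered loop consisted of
  hub nodes; without this, a three-node loop hanging off a sparse network
  would rightly fail the hub filter.
* **Survival.** Event times are exponential with rate
  `h0 · exp(β · score)`, `score = z(miRNA) − z(TF) − z(gene)` over tumor
  samples of the first planted loop, `h0 = log(2)/36` per month (median
  survival 36 months at score 0) and `β = 1` by default. Censoring times
  are uniform on `(0, c_max)` with `c_max` root-solved so the realized
  censored fraction matches `censor_fraction` (default 0.3); a 5%
  lost-to-follow-up flag is sampled independently.
* **Covariates.** Methylation betas `Beta(2, 5)` and copy-number values
  `Normal(0, 0.4)` are independent of expression by default; the
  `meth_affected` / `cnv_affected` options plant features whose covariate
  tracks expression (logistic-transformed z-scores with noise, Spearman
  rho well above the 0.3 flag cutoff), to exercise the association filter
  in both directions.

Not emulated: read-level sequencing, batch effects, library-size
artifacts, inter-patient biological heterogeneity beyond replicate noise,
subclonal copy-number structure, and any correlation structure among
background features. All draws flow from one seed; identical seeds give
bit-identical cohorts and TSV outputs.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at deliberately modest
scales chosen to exercise every code path with comfortable statistical
margins: cohorts of 370 features × 50 pairs for DE recovery; 300-subject
cohorts, 200 null replicates and 50 alternative replicates for log-rank
calibration and power; 20 seeded end-to-end runs for planted-loop
recovery; 50 random graphs of ≤ 8 nodes against brute-force centrality
oracles (path enumeration, matrix-exponential series, Laplacian
pseudo-inverse resistances) at `1e-8` tolerance; and 50 random 30-node
networks against exhaustive triple-loop FFL enumeration. Every stochastic
step funnels through a single seed argument.

## Known limitations

* The DE caller's `prob` is an exceedance fraction, not a p-value, and is
  expression-biased by construction (see above); no FDR is attached.
* Centralities treat the network as undirected, following the classical
  definitions; regulatory direction is kept for enumeration but ignored
  for hubness.
* The hub tie rule can retain well over half the nodes on skewed or
  tiny networks, making the hub filter permissive there.
* The methylation/CNV "affected" test is a correlation screen, not a
  causal analysis; it cannot distinguish methylation-driven expression
  from expression-driven methylation.
* The log-rank χ² approximation is slightly anti-conservative at the
  default group sizes (≈ 35–40 per arm); the package's calibration test
  bounds the empirical type-I error rather than assuming exactness.
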