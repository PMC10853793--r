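---
title: "Coexpression-based gene set association: model and design choices"
author: "gsce maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression-based gene set association: model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsce)
```

## The question the method answers

Classical overrepresentation analysis asks whether a list of
differentially expressed genes (DEGs) *overlaps* a gene set more than
chance predicts.  That ignores everything the expression data say about how
genes behave together in the disease state.  `gsce` instead asks whether
the DEG list -- or any single DEG in it -- is *coexpressed* with a gene
set's differentially expressed members: condition-specific correlation
structure, not bare membership, carries the signal.  The unit of evidence
is the **coexpressed gene pair**: two DEGs whose expression across case
samples has Pearson correlation $|r| \ge c$.

The pipeline is:

1. **DEG calling** between control and case samples.
2. **Coexpression network** over the dataset's DEGs, built from *case
   samples only* (the network is meant to describe the disease state,
   which is why the case class needs reasonable depth).
3. **Pair-count tests** of each query against each gene set, with
   Benjamini--Hochberg (BH) correction.
4. Optionally, a **Stouffer meta-z layer** combining association
   significance across datasets (e.g. cancer types) or across gene sets.

## The association statistic

Let $S'$ be the DEG members of gene set $S$ (the intersection of the set
with *all* DEGs called in the dataset, not merely the query list).  For a
single query DEG $a$, the possible pairs are $\{(a, x) : x \in S'
\setminus \{a\}\}$; $n$ is their number and $m$ the number of those pairs
that are network edges.  Pooling the same two quantities over every set in
the collection gives the background $N$ and $M$.  The association P value
is the upper tail of the hypergeometric distribution,

$$
P \;=\; 1 - \sum_{i=0}^{m-1}
\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}} ,
$$

i.e. the probability of drawing at least $m$ coexpressed pairs when $n$
pairs are drawn from an urn of $N$ pairs of which $M$ are coexpressed.
For a query *list* $L$ the same construction applies to unordered pairs
$\{a, x\}$ with $a \in L$, $x \in S'$, $a \ne x$, each counted once; with
$k = |L \cap S'|$ this gives $n_g = |L||S'| - k - \binom{k}{2}$ possible
pairs.  In the fully disjoint case $n_g = |L||S'|$ exactly (a 7-gene list
against a 5-DEG set yields $n_g = 35$).

P values are BH-corrected and an association is significant at
$q \le 0.05$ (the `fdrLevel` parameter).

### Design choices in the counting

Several corners of the counting are genuinely open; the package fixes them
as follows and exposes the alternatives where they are defensible.

* **Overlapping gene sets.** Background counts sum per-set contributions
  (`background = "per_set_sum"`), so a gene in two sets contributes two
  possible pairs.  This is the only reading under which each set's draw is
  a sub-collection of the urn, guaranteeing $n \le N$.  A distinct-pair
  background (`"dedup_union"`) is available for sensitivity analysis.
* **Self and duplicate pairs.** A query gene inside the tested set forms
  no pair with itself; a pair with both ends in $L \cap S'$ is counted
  once.  Both rules follow from treating pairs as unordered sets.
* **BH family at gene level.** Each query DEG is corrected across gene
  sets separately (`geneFamily = "per_gene"`): each gene's question --
  "which sets is this gene tied to?" -- is its own family.  A pooled
  family over all (gene, set) tests is available (`"global"`).
* **Untestable sets.** A set with no possible pair ($n = 0$) has no test;
  it is reported with `NA` p and q and excluded from the BH family rather
  than entered as $p = 1$, which would dilute the correction.
* **Zero-variance genes.** A DEG with identical values across all case
  samples has no defined correlation.  It is excluded from the network
  (degree zero) but *kept in pair universes*: it still contributes
  possible pairs, never coexpressed ones.  This keeps $n$ equal to the
  set's DEG count in worked examples and avoids silently shrinking the
  urn.  Only exact constancy triggers the rule; near-constant vectors are
  legitimate data and are kept.

### Numerical policy

The tail probability is computed by `stats::phyper()` (log-gamma
implementation, stable for backgrounds up to $10^7$ pairs), is exactly 1
at $m = 0$, and is clipped to $[10^{-300}, 1]$.  An independent
exact-enumeration oracle (`hypergeomOracle()`, direct evaluation of the
binomial sum with `choose()`) is kept in the package and the test suite
verifies agreement to $10^{-12}$ exhaustively for all valid count tuples
with $N \le 12$.

## DEG calling

Two criteria sets are provided, matching common practice for the two data
generations, plus a pass-through:

* `microarray_topN`: among genes with two-sample t-test $P < 0.05$
  (strict), the 400 genes with largest $|\log_2 \mathrm{FC}|$ (both
  defaults tunable).  Ties at the cap are broken by smaller P, then gene
  id, so the call is deterministic.
* `threshold`: $|\log_2 \mathrm{FC}| \ge 1$ **and** BH $q \le 0.05$, both
  bounds inclusive as written.
* `precomputed`: DEG status supplied by the user; statistics are still
  computed for the record, and an id absent from the matrix is an error.

The t test defaults to the pooled-variance (Student) form -- the default
of the common two-sample t implementations this workflow historically
relied on -- with Welch available via `equalVariance = FALSE`.  The
fold change is `mean(case) - mean(control)` on log2-scale values; raw
values can be transformed at load time with `log2(x + 1)`, the pseudocount
avoiding $-\infty$ on zeros.  For RNA-seq data a moderated
(empirical-Bayes) statistic is deliberately out of scope; the ordinary t
plus BH keeps the package self-contained, and a precomputed DEG list from
any external caller drops straight in.

Class sizes: correlations over case samples need depth more than the t
test does, so `runGsce()` requires at least 3 control and 5 case samples
and refuses smaller designs unless `strict = FALSE` (which downgrades the
stop to a warning -- deliberately, for exploratory use only).

## The meta-analysis layer

Association q values (or nominal P values, by flag) are mapped to z scores
by $z = \Phi^{-1}(1 - q)$, clipping q to $[10^{-15}, 1 - 10^{-15}]$ to
keep z finite, and combined over strata with Stouffer's unweighted method
$\sum z_i / \sqrt{k}$.  All associations are transformed, significant or
not: nonsignificant strata carry real (negative) evidence, and dropping
them would bias the meta-z upward.  A stratum where the entity was
untestable reduces $k$ instead of contributing $z = 0$.  Significance
flags use the one-sided 1.64 and two-sided 1.96 normal quantiles,
inclusive.  With `axis = "strata"` entities are (query, set) associations
matched across tables; with `axis = "sets"` a query gene's z scores are
pooled over sets, measuring pathway-wide enrichment of that gene.

## What the synthetic benchmark emulates

`generateDataset()` plants known structure so that recovery can be scored
exactly:

* background genes i.i.d. Normal($\mu_0 = 7$, `noiseSd`) on the log2
  scale in both classes -- a generic log-intensity scale;
* `nDegs` genes shifted by `degShift` in case samples;
* the first `moduleSize` DEGs share, in case samples, one latent factor:
  $x = \sqrt{\rho} f + \sqrt{1-\rho}\,\varepsilon$, the equicorrelated
  construction with pairwise correlation exactly $\rho$ = `moduleR`.  One
  factor was chosen over an arbitrary covariance because the method
  thresholds pairwise $|r|$, and the single-factor design makes the
  expected edge pattern analytically checkable;
* one gene set receives `plantedSetOverlap` module genes plus random
  fill; all other sets are uniform random draws, so null sets contain
  DEGs at the dataset's DEG proportion and their tests are not vacuous.

The reference settings -- 1000 genes, 10 control / 50 case samples, 100
DEGs shifted by 1.5, a 20-gene module at $\rho = 0.8$, 50 sets of 15--40
genes with a 15-gene planted overlap, unit noise -- are what a small but
adequately powered two-class expression study looks like, and all
benchmark claims in the test suite are made at these settings (or
explicitly scaled-down variants used in unit tests for speed: a few
hundred genes, 10--20 case samples).  What the generator does **not**
emulate: count-distributed RNA-seq noise and mean--variance coupling,
batch effects, correlated background (housekeeping) modules, or annotation
error in the gene sets.  A pass on this benchmark therefore demonstrates
correctness of the machinery and sensible calibration under idealized
noise, not performance on any particular real platform.

In ranking experiments (`recoveryExperiment()`) ties in list-level q are
broken uniformly at random with a per-replicate seed: under a pure null
nearly every set ties at $q = 1$, and a deterministic tie-break would make
the planted set's rank an artifact of set ordering instead of the uniform
draw the null implies.

## Known limitations

* Hierarchical, cascade-like regulation can couple genes that are not
  strongly pairwise-correlated; such relationships are invisible at any
  $c$.
* Node degree is ignored: a hub's many edges all count equally.  Degree
  weighting is attractive but sensitive to false edges, and is left out.
* The choice of $c$ is the user's.  0.7 is the default; lowering it to
  0.5 or 0.3 trades specificity for sensitivity, and the provenance
  record always logs the value used.
* With very few case samples the correlation estimates are noisy enough
  that the network is unreliable -- hence the 5-case floor.
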