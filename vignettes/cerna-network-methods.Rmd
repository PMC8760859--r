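---
title: "Methods: ceRNA network inference from RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernakit)
library(dplyr)
```

# The analysis

cernakit implements the computational core of a common bulk RNA-seq study
design in ligament biology: two tissues with very different endogenous
healing capacity — the anterior cruciate ligament (ACL) and the medial
collateral ligament (MCL) — are profiled in normal and partially injured
states, differentially expressed mRNAs and lncRNAs are called, lncRNAs are
classified by genomic position, and a competing endogenous RNA (ceRNA)
network is inferred in which lncRNAs act as miRNA sponges that indirectly
de-repress mRNAs sharing those miRNAs. Hub nodes of the resulting networks
are ranked, differentially expressed gene sets are tested for term
over-representation, and selected transcripts are validated by qPCR with
the 2^-ddCt method.

Every stage is a plain function over data frames, and a seeded synthetic
data generator reproduces the statistical structure each stage assumes, so
the whole pipeline is testable without sequencing data.

# Normalization

Sequencing depth is removed with median-of-ratios size factors: for sample
$j$, $s_j = \mathrm{median}_i \; c_{ij} / (\prod_k c_{ik})^{1/n}$ over
features $i$ with strictly positive counts in every sample, rescaled so the
factors have geometric mean 1. When no feature is positive everywhere the
estimator is undefined and `size_factors()` stops with an explicit error
rather than silently switching to a pseudo-reference. Normalized counts
(`raw / s_j`) feed differential expression and co-expression; FPKM
($c_{ij} \cdot 10^9 / (\ell_i \, T_j)$ with feature length $\ell_i$ in bp
and per-sample total $T_j$) is provided for reporting because ligament
RNA-seq studies conventionally quote transcript abundance on that scale.

# Differential expression

The test is a moment-matched negative-binomial Wald test on normalized
counts, with the NB parameterized as $\mathrm{Var} = \mu + \alpha \mu^2$:

1. per-feature dispersion $\hat\alpha_i$ by the method of moments from the
   pooled within-group variance, floored at zero;
2. a lowess trend of $\hat\alpha$ against the log mean, and moderation of
   each feature's estimate toward the trend with 8 prior degrees of freedom
   (a conventional amount of pooling for small designs);
3. Wald statistic on $\log \bar y_1 - \log \bar y_2$ with delta-method
   standard error $\sqrt{(1/\bar y_1 + \alpha)/n_1 + (1/\bar y_2 + \alpha)/n_2}$,
   referred to the standard normal.

A feature with a zero group mean receives a +0.5 continuity correction in
both groups before the ratio, so fold changes and p-values are always
finite; exactly equal groups give $p = 1$ by construction.

This is deliberately **not** a re-implementation of a shrunken-GLM engine
such as DESeq2's: the scientific content of the downstream analysis lies in
the calling thresholds and the network construction, and the simplified
test is calibrated (null type-I error near nominal, simulation-verified in
the test suite) while remaining transparent. Expect its p-values to differ
from DESeq2's on real data, mainly for low-count features.

Calls use the study rule: **FDR < 0.01 (strict) and fold change at least
2-fold in either direction**, i.e. `up` when $\mathrm{FC} \ge 2$, `down`
when $\mathrm{FC} \le 1/2$, always requiring `fdr < 0.01`. The
Benjamini-Hochberg step-up adjustment is exposed as `bh_adjust()`. Four
contrasts are hard-wired as the default comparison design (injured vs
normal within each tissue; ACL vs MCL within each condition) and can be
replaced through `de_contrast()`.

The sequencing design this emulates used 2 biological replicates per group;
the package's tests and simulations use $n \ge 5$ per group because power
at $n = 2$ is not a meaningful surface for validating a test — the contract
checked is calibration and recovery at usable sample sizes.

# lncRNA positional classification

The four standard positional classes are assigned with an explicit
precedence, first match wins:

1. **lincRNA** — no base overlap with any gene span;
2. **intronic** — entirely inside one intron, any strand;
3. **antisense** — overlaps an exon on the opposite strand;
4. **sense** — overlaps an exon on the same strand.

Containment is the most specific relation, so intronic is tested before
the exon-overlap classes and strand-agnostically. A transcript that
overlaps a gene but matches no rule (e.g. lies fully within the gene yet
straddles nothing classifiable, which cannot happen with single-intron
models but can with real annotations) falls through to sense and is flagged
in a `fallback` column. Interval arithmetic is done on 0-based half-open
coordinates internally; GTF input/output stays 1-based inclusive.

# ceRNA pair calling

For each lncRNA--mRNA pair sharing at least one miRNA, with target-miRNA
sets of sizes $n_A$, $n_B$ drawn from a universe of $M$ miRNAs and overlap
$k$:

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(M, n_A, n_B).$$

The universe $M$ is the number of distinct miRNAs in the interaction table
— not a genome-wide constant — because the null of the test must match the
sampled universe. A pair is called when **all** of the following hold
(defaults in `cerna_thresholds()`):

* shared miRNAs $k > 5$ (strictly more than five);
* hypergeometric $p < 0.01$ and BH FDR $< 0.01$ across the scored pairs;
* co-expression: Pearson $r \ge 0.7$ with $p < 0.05$, computed on
  $\log_2(x + 1)$ of the expression values by default. Positive
  correlation is required because ceRNA partners are co-regulated by the
  loss or gain of their shared miRNAs; the log scale is the usual
  variance-stabilised choice for expression correlation and makes the
  coefficient robust to the heavy right tail of count data.

The differential network retains a triplet (lncRNA, miRNA, mRNA) when the
pair passed, the miRNA targets both partners, and all three members are
differentially expressed in the contrast at hand; the union of retained
triplets forms the typed network. How miRNA differential status is obtained
is left to the caller (`de_status` input): the emulated study design
includes no small-RNA sequencing, so the package treats both the
miRNA-target table and miRNA regulation status as exogenous inputs (the
simulator generates miRNA counts only so that an end-to-end run can derive
a status table).

# Hub ranking

Both network types are reduced to simple undirected graphs (multi-edges
collapsed, self-loops dropped). Two scores are provided:

* **Degree** — incident edge count, used with top-50 reporting for ceRNA
  networks;
* **MCC** (Maximal Clique Centrality) —
  $\mathrm{MCC}(v) = \sum_{C \ni v} (|C| - 1)!$ over maximal cliques $C$,
  used with top-30 reporting for PPI networks. An isolated node scores
  $0! = 1$, and on triangle-free graphs MCC equals degree for non-isolated
  nodes.

Maximal cliques come from Bron-Kerbosch with pivoting (igraph); the test
suite verifies both the clique sets and the MCC scores against an
exhaustive subset-enumeration oracle on random graphs up to 12 nodes.
Because enumeration is worst-case exponential, graphs above a configurable
node ceiling (default 5000) are refused with a clear error. Ranking ties
are broken by node id ascending so every ranked list is reproducible; when
a network has fewer nodes than requested, all of them are returned (a
45-node network asked for its top 50 yields 45).

# Term enrichment

`enrichment_test()` is a classic one-sided hypergeometric
over-representation test per term with BH FDR across terms, reported as the
top 20 by p-value (configurable; ties broken by term id). The universe
defaults to all features tested for differential expression in the
contrast. Graph-aware decorrelation schemes (as in topGO's elim/weight
algorithms) are intentionally not replicated: they require ontology
topology files and change the test's null in ways that are hard to audit;
the plain test is the transparent baseline for descriptive enrichment.

# qPCR quantification

`ddct()` averages technical replicates first, then computes per sample
$\Delta Ct = Ct_{target} - Ct_{reference}$,
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}$ (arithmetic
mean over control samples), and $\mathrm{fold} = 2^{-\Delta\Delta Ct}$.
Consequences used as tests: the control group's folds have geometric mean
exactly 1, and any constant added to all Ct values of a sample cancels.
Group comparison is a Welch two-sample t-test on fold values with mean and
SEM per group; Welch is the safer default when only "t-test" is specified.
Amplification-efficiency correction (Pfaffl) is out of scope.

# The synthetic-data generator

`simulate_dataset()` produces every input with known ground truth:

* **Annotation** — one synthetic chromosome; genes occupy dedicated 20 kb
  units (two 500 bp exons around a 2 kb intron), lincRNAs their own
  gene-free units, guaranteeing the >= 5 kb clearance that makes the
  lincRNA label unambiguous; antisense/sense/intronic transcripts are
  placed on host genes so that each realizes exactly one classification
  rule. Class counts follow the configured fractions by largest-remainder
  rounding (default fractions 40% / 8.8% / 48.8% / 2.4%, the proportions
  reported for rabbit ligament lncRNA); classification of the generator's
  own output must return 100% of the labels (a round-trip invariant).
* **Counts** — NB draws with $\mathrm{Var} = \mu + \alpha\mu^2$
  ($\alpha = 0.1$ by default, a typical bulk RNA-seq value), log-normal
  baseline means (median 200), per-sample size factors log-uniform in
  [0.5, 2] to exercise normalization, and a 2 tissue x 2 condition x
  $n$ replicate design. Three disjoint planted effect sets (ACL injury,
  MCL injury, tissue) of $\pm$`planted_log2fc` drive the four contrasts,
  so each feature is non-null in at most one effect and the per-contrast
  truth table is exact.
* **Interactions** — each planted triplet's lncRNA and mRNA are targeted by
  the same `k_shared` miRNAs (default 8) and receive no background edges,
  so planted pairs share *exactly* `k_shared`; background miRNAs target 2
  features each, drawn uniformly, giving a sparse background in which no
  pair exceeds the shared-miRNA cutoff by chance. Triplet members also
  share a per-sample latent factor on the log2 scale (sd 2) so the
  co-expression filter passes — the generator's contract is that planted
  triplets are recoverable at the default thresholds.
* **qPCR** — Ct = baseline − log2(relative expression) + per-sample offset
  + Gaussian noise (sd 0.25 cycles), three technical replicates, reference
  gene with no effect.

All generators are pure functions of `(config, seed)`; each draws from a
named sub-stream of the root seed, so regenerating any one input never
perturbs the others.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: gene-level count correlation structure
beyond the planted triplets, varying gene lengths and isoforms, GC and
mappability biases, outlier samples, dispersion trends that differ between
tissues, miRNA target-prediction error, and the very small replicate
numbers of the motivating design. Recovery rates on synthetic data are a
correctness check of the machinery, not a power claim for any real
experiment.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on simulated data at
moderate sizes chosen to make every check exact or tightly bounded: DE
calibration uses 2,500 features (500 planted, 2,000 null) at $n = 5$ per
group; ceRNA recovery uses the default configuration (400 genes, 250
lncRNAs, 150 miRNAs, 10 planted triplets) over 20 seeds; clique/MCC
equivalence uses exhaustive oracles up to 12 nodes, where subset
enumeration is still exact. Hypergeometric tails are evaluated through the
distribution function's upper tail (stable in log space internally) rather
than naive summation; BH is the standard step-up with capping at 1;
degenerate inputs (zero-variance expression, all-zero features, constant
qPCR folds) are defined to fail filters or return boundary p-values rather
than produce NaN.

# A worked run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
out <- file.path(tempdir(), "demo_run")
manifest <- run_pipeline(out, cfg, quiet = TRUE)
manifest$counts$de$ACL_injured_vs_normal
manifest$counts$cerna_pairs_passed
```

The manifest records seed, thresholds, per-stage counts, and an MD5 hash of
every output file; rerunning with the same configuration reproduces the
manifest byte for byte.

# Known limitations

* The DE engine is a calibrated simplification, not a DESeq2 clone;
  borderline features can be called differently.
* The four lncRNA classes use the standard positional definitions; studies
  rarely state theirs operationally, so label-for-label agreement with any
  particular published pipeline is not guaranteed.
* Whether co-expression in the motivating analyses used FPKM or normalized
  counts (and which correlation cutoff) is typically unstated; the default
  here (normalized counts, log2, $r \ge 0.7$) is explicit and configurable.
* Clique enumeration is exponential in the worst case; the node ceiling
  exists for a reason.
* Published headline counts from the motivating study derive from deposited
  reads processed with an external alignment/assembly stack, and are not
  reproducible from summary inputs; this package validates its machinery
  by planted-truth recovery instead.
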