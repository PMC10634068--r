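---
title: "Scoring read-level DNA methylation heterogeneity"
author: "methylhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring read-level DNA methylation heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylhet)
```

## The problem

Bulk bisulfite or EM-seq data average DNA methylation over thousands of
cells, and the usual per-site summary — the methylation level
$\#C/(\#C+\#T)$ — discards everything those cells disagree about. Each
aligned read, however, is a molecule from a single cell, and the ordered
methylation states it carries across several neighbouring cytosines form
a *methylation pattern* (an epiallele). The spread of patterns at a
locus is a direct, read-level measure of epigenetic heterogeneity in the
cell population, and it moves in situations — tumour progression,
cell-type mixtures, transposon control in plants — where the mean level
barely changes.

`methylhet` quantifies this spread genome-wide. Windows of $w$
consecutive cytosines of one context (CG, CHG or CHH; H = A, C or T)
slide one cytosine at a time along each strand; every read that covers
all $w$ sites with unambiguous calls contributes one complete pattern;
windows with at least `min_depth` such reads are scored.

## The diversity framework

All three model-based scores are Hill numbers of order $q$ over an
*attribute system*: entities $u$ with attribute values $v_u$ and
abundances $a_u$, normalizer $\bar V = \sum_u v_u a_u$, and diversity

$$ {}^{q}AD = \Big[ \sum_u v_u \big( a_u / \bar V \big)^q
   \Big]^{1/(1-q)} . $$

We fix $q = 2$ (the reciprocal-Simpson form, robust to rare-pattern
noise); `attribute_diversity()` exposes general $q$, with $q = 1$
handled as the Shannon limit. The three scores differ only in what the
entities are:

* **AB** (abundance-based): entities are the distinct patterns,
  $v_u = 1$. $AB = (\sum_i p_i^2)^{-1}$ is the effective number of
  patterns, between 1 (homogeneous window) and $2^w$.
* **PWS** (pairwise-similarity-based): entities are pattern pairs with
  the pairwise distance $d_{ij}$ as attribute. With
  $Q = \sum_{ij} d_{ij} p_i p_j$ and $p_{ij} = p_i p_j / Q$,
  $PWS = (\sum_{ij} d_{ij} p_{ij}^2)^{-1/2}$. The square root is
  deliberate: pooling two equally diverse, fully separated groups
  quadruples the distance-based diversity, so the rooted form doubles,
  which keeps differences between samples on a linear scale.
* **PHY** (phylogenetic-tree-based): entities are the branches of a
  rooted tree over the patterns, with branch length $L_i$ as attribute
  and the summed relative abundance of descendant leaves as $a_i$.
  With $a_i = p_i / \sum_j L_j p_j$, $PHY = (\sum_i L_i a_i^2)^{-1}$.

```{r scores}
pc <- pattern_counts(c("0000", "1111"), c(2, 2))
c(AB = ab_score(pc), PWS = pws_score(pc), PHY = phy_score(pc))
```

An equal split between two maximally distant patterns gives
$PWS = \sqrt 2 \approx 1.41$ — the expected score increase when a new
pattern appears, and therefore the default minimum group-mean
difference for differential-heterogeneity calls.

### Distances

Pattern distances default to the normalized Hamming index,
$d = (\text{mismatches})/w \in [0,1]$. A weighted-degree-kernel
distance is available (`metric = "wdk"`): similarity is the
$\beta_k$-weighted fraction of matching contiguous $k$-mers,
$\beta_k = 2(w-k+1)/(w(w+1))$, and the distance is one minus that. The
weights sum to 1 so both metrics share the $[0,1]$ range, and at
$w = 1$ they coincide. Both are exposed because the combination used
alongside the Hamming index in the published description of the method
is not fully specified; Hamming is the default since the
$\sqrt 2$ threshold arithmetic above is stated in terms of it.

### The pattern tree

No tree construction method is canonical for patterns, so we use
average-linkage (UPGMA) agglomerative clustering of the pairwise
distances: it is deterministic (patterns are sorted lexicographically
before clustering so ties break reproducibly), rooted, ultrametric, and
yields exactly $B = 2R - 2$ branch segments for $R$ leaves — five
distinct patterns give eight branches. Node heights are half the merge
heights; leaf branches run from height 0 to their parent. Branch
lengths are used raw, not normalized by tree depth.

### Degenerate windows and numerical conventions

Equations for PWS and PHY are 0/0 at $R = 1$; a homogeneous window is
reported as $PWS = PHY = 0$, the continuity limit, which also makes the
"expected increase" interpretation of $\sqrt 2$ exact (from 0 to 1.41
when a second, maximally distant pattern appears at equal abundance).
Relative abundances always sum to 1 within $10^{-12}$; all-zero
abundance vectors and all-zero branch-length trees are rejected rather
than silently scored.

### Properties, and what the tests exercise

The framework's properties are kept as executable tests: scale
invariance (multiplying all counts by a constant changes nothing), the
doubling property (pooling two pattern-disjoint windows of equal AB
doubles AB exactly; a constructed equal-$Q$ two-group pooling doubles
PWS), and weak monotonicity (diversity grows when a maximally distinct
new pattern arrives). Two notes on the latter. For PWS the doubling
construction requires the pooled $Q$ to equal the group $Q$; with
Hamming distances bounded by 1 this cannot coincide with "all
between-group distances maximal", so the test constructs the distance
matrix directly. For PHY, the score is diversity per unit branch
length: appending a very distant pattern to a tightly clustered set
deepens the tree and can legitimately *lower* PHY. Monotonicity is
therefore exercised on systems of mutually maximally distant patterns,
where it holds strictly; AB and PWS are monotone under the plain
Hamming construction and are tested that way.

## Comparison scores

Seven published read-level statistics are implemented over the same
complete-pattern windows, so all ten scores see identical input:
methylation entropy (ME), epipolymorphism (EP), proportion of
discordant reads (PDR), fraction of discordant read pairs (FDRP), its
Hamming-weighted form (qFDRP), methylation haplotype load (MHL) and
methylation concurrence (MC). Because every read carries a complete
pattern, the shared-site set of any read pair is all $w$ sites, and
MHL's maximum substring length is $w$. MC weighs each read by the
number of window sites it covers ($\omega = w$ here) and trichotomizes
reads as fully methylated, fully unmethylated or mixed; an all-mixed
window reaches 1 even though the score's published range is stated as
$[0,1)$ — the boundary case is admitted rather than clipped. On toy
locus series where patterns accumulate one at a time, AB, PWS, PHY,
FDRP, qFDRP, MHL, ME and EP all rise monotonically; holding the
abundance vector fixed and making the two patterns more mutually
distant moves only PWS, qFDRP and MHL — the separation that motivates
the similarity-aware scores.

## Genome screening and differential calling

`screen_genome()` locates context cytosines on the reference (reads
supply only methylation status), screens both strands separately —
bisulfite reads are strand-specific, and symmetric CpG positions are
*not* merged across strands — and scores every window with depth ≥ 4
(default). Methylation calls come from a Bismark-style `XM` tag when
present, otherwise from the read sequence against the expected
conversion (C/T on plus, G/A on minus strand); insertions and deletions
are handled by projecting the read to reference space before looking up
the window sites. Duplicate reads are not removed internally — that is
deliberately left to upstream `samtools markdup`.

Window scores are merged into 400-bp tiles by the window's *start*
cytosine (unambiguous and order-independent; the alternative
midpoint/overlap rules change little at 4-cytosine windows), with the
tile value the arithmetic mean of its member windows. Coordinates are
1-based inclusive everywhere inside the package and in CSV output;
bedGraph output is 0-based half-open with values rounded to 6 decimals,
CSV keeps full precision. Per-site methylation levels
($\#C/(\#C+\#T)$, reported at coverage ≥ 4) feed the DMR caller.

Differential calls compare two groups of ≥ 2 replicates per tile with a
two-sided, pooled-variance Student's t-test (no Welch correction, no
multiple-testing adjustment by default; a BH flag exists but is off,
matching the raw $p < 0.05$ rule):

* **DHR**: $|\Delta\,\text{heterogeneity}| > 1.41$ and $p < 0.05$;
* **DMR**: $|\Delta\,\text{level}| > 0.15$, $p < 0.05$, and at least 5
  covered cytosines in the tile — in *every* replicate, the
  conservative reading of the site-count rule.

When both groups have zero variance the t statistic is undefined; the
continuity limit is used ($p = 1$ for equal means, else $p = 0$), which
is what makes exact parameter-recovery experiments on noiseless
synthetic data well defined. Genes whose annotated body (start–end,
introns and UTRs included, promoters not extended) overlaps a
qualifying region become DHGs/DMGs; gene-set overlaps are tested with
the upper-tail hypergeometric probability.

## The synthetic generator

The generator exists so that every pipeline stage can be exercised
without downloads, and it defines the conditions under which the test
suite's claims hold. A mini-reference places each locus in its own
400-bp tile: $w$ context cytosines spaced 10 bp on an A-only backbone,
so no accidental context sites arise and each read covers exactly one
locus. `make_toy_alignment()` realizes an exact pattern multiset per
locus; `simulate_pooled_methylome()` draws reads per cell from
per-cell-type pattern distributions (emulating pooled single-cell
methylomes of one or several cell types); `merge_methylomes()` produces
nested pools for merging series; `inject_call_errors()` flips each call
independently with probability $e$ — the minimal error model, chosen
because the published simulation's parameters are not available.
Everything is seed-deterministic and restores the caller's RNG state.

What the generator does *not* emulate: read-length and quality
variation, incomplete bisulfite conversion, PCR duplicates, partially
overlapping reads, coverage heterogeneity, or correlated errors.
Passing tests therefore demonstrate correctness of the scoring and
calling machinery under clean, complete-pattern input — not robustness
to every artefact of real libraries.

Test and acceptance problem sizes are deliberately modest — loci in the
tens, depths ≤ 50, 1,000 random windows for the oracle-equivalence
sweep, 40 tiles with 3 replicates per group for parameter recovery —
sizes at which exhaustive brute-force oracles are feasible and the
whole suite runs in about a minute.

## Known limitations

* Windows are defined per strand; tools that merge symmetric CpGs
  across strands will score different windows.
* PHY's published formula is followed with exponent $-1$ (its
  typeset range carries a stray ".5" that would suggest $-0.5$; the
  worked methods equation prints $-1$).
* Real-data regional counts from published cancer/plant analyses are
  not reproduced here; they depend on external accessions outside the
  package's scope.
* The genome-wide summary is a plain mean of window scores per sample;
  the published "heterogeneity ratio" normalization is not specified in
  the main text and is not reimplemented.
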