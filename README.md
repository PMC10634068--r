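# methylhet

Genome-wide **read-level DNA methylation heterogeneity** from
bisulfite/EM-seq alignments.

Bulk methylome data average over thousands of cells, and the usual
per-site methylation level `#C/(#C+#T)` hides how much those cells
disagree. Each aligned read is a single molecule: the ordered
methylation calls it carries across `w` neighbouring cytosines form a
*methylation pattern* (epiallele), and the spread of patterns at a
locus measures cell-to-cell epigenetic heterogeneity directly.
`methylhet` is for anyone analysing bisulfite or EM-seq data — human,
mouse or plant (CG, CHG and CHH contexts are all supported) — who
wants that second layer of information next to methylation levels.

## The scores

All three model-based scores are Hill numbers of order *q* = 2
(reciprocal Simpson) over an attribute system with entities *u*,
attribute values *v<sub>u</sub>*, abundances *a<sub>u</sub>* and
normalizer V̄ = Σ v<sub>u</sub> a<sub>u</sub>:

> ²AD = [ Σ<sub>u</sub> v<sub>u</sub> (a<sub>u</sub>/V̄)² ]<sup>−1</sup>

| score | entities | attribute | formula |
|---|---|---|---|
| **AB** | distinct patterns | 1 | AB = (Σ p<sub>i</sub>²)<sup>−1</sup> |
| **PWS** | pattern pairs | pairwise distance d<sub>ij</sub> | PWS = (Σ d<sub>ij</sub> p<sub>ij</sub>²)<sup>−1/2</sup>, p<sub>ij</sub> = p<sub>i</sub>p<sub>j</sub>/Q, Q = Σ d<sub>ij</sub>p<sub>i</sub>p<sub>j</sub> |
| **PHY** | tree branches | branch length L<sub>i</sub> | PHY = (Σ L<sub>i</sub> a<sub>i</sub>²)<sup>−1</sup>, a<sub>i</sub> = p<sub>i</sub>/Σ L<sub>j</sub>p<sub>j</sub> |

AB is the effective number of patterns (1 for a homogeneous window, up
to 2<sup>w</sup>); PWS additionally rewards patterns for being
*different* from one another (square-rooted so pooling two disjoint,
equally diverse groups doubles rather than quadruples the score); PHY
summarizes total pattern similarity through a UPGMA tree built from
the pairwise distances. An equal split between two maximally distant
patterns gives PWS = √2 ≈ 1.41, which doubles as the default
differential-heterogeneity threshold. Seven published comparison
scores (ME, EP, PDR, FDRP, qFDRP, MHL, MC) are implemented over the
same windows for benchmarking.

The pipeline: slide windows of 4 context cytosines (one cytosine at a
time, strands separate), keep windows with ≥ 4 complete read patterns,
score them, average into 400-bp tiles, and compare groups of
replicates per tile with a pooled-variance t-test — DHRs need
|Δ| > 1.41 and p < 0.05; DMRs need |Δ level| > 0.15, p < 0.05 and ≥ 5
covered cytosines. Genes whose body overlaps a qualifying region
become DHGs/DMGs.

## Worked example

Three synthetic loci — homogeneous, two maximally distant patterns at
equal abundance, and five distinct patterns — written to a real BAM and
screened back:

```r
library(methylhet)
sim <- make_toy_alignment(list(
  list(patterns = "0000", counts = 4L),
  list(patterns = c("0000", "1111"), counts = c(2L, 2L)),
  list(patterns = c("0000", "0001", "0011", "0111", "1111"),
       counts = rep(2L, 5))))
paths <- sim_to_bam(sim, "example")
win <- screen_genome(paths[["bam"]], paths[["fasta"]],
                     scores = c("AB", "PWS", "PHY", "ME", "EP"))
print(win, digits = 4)
#>   chrom start end strand context depth AB   PWS    PHY     ME  EP
#> 1  chrS   100 130      +      CG     4  1 0.000 0.0000 0.0000 0.0
#> 2  chrS   500 530      +      CG     4  2 1.414 1.0000 0.2500 0.5
#> 3  chrS   900 930      +      CG    10  5 3.162 0.8681 0.5805 0.8
```

The homogeneous window scores AB = 1 and PWS = PHY = 0; the two-pattern
window scores AB = 2 (two effective patterns) and PWS = 1.414 = √2; the
five-pattern window has five effective patterns and the largest PWS.
Tiling and summarizing:

```r
tile_scores(win, "PWS")
#>   chrom start  end context score value n_windows
#> 1  chrS     1  400      CG   PWS 0.000         1
#> 2  chrS   401  800      CG   PWS 1.414         1
#> 3  chrS   801 1200      CG   PWS 3.162         1
summarize_genome(win, "PWS")$genome_mean
#> [1] 1.525456
```

The same screen is available from a shell via the bundled CLI
(`inst/cli/methylhet`):

```sh
methylhet screen --bam example.bam --ref example.fa \
  --context CG --score PWS,AB --out tracks
methylhet dhr --group-a a1.csv,a2.csv,a3.csv \
  --group-b b1.csv,b2.csv,b3.csv --out dhr.csv
```

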