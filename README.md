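# clustersig

Significance statistics for approximate gene clusters.

Comparative genomics models genomes as strings of gene-family identifiers
and looks for *gene clusters*: gene sets that stay co-localized across
genomes far more than random gene order would allow. Sensitive detection
models tolerate imperfectly conserved occurrences — rearranged, invaded by
foreign genes, missing cluster genes, or absent from many genomes — and
therefore need a statistical brake: the probability of a prediction of the
observed quality arising by chance. `clustersig` computes exactly that for
the approximate common intervals / reference gene cluster model, for
people analysing gene order in bacterial (or other microbial) genome sets.

## The statistic

Conservation quality is measured by the symmetric set distance
`D(C, CS(S[a,b])) = |C \ CS| + |CS \ C|` between the cluster `C` and the
character set of an interval; an interval with `D <= δ` (sharing at least
one gene with `C`) is a *δ-location*. Under a null model in which each
genome position independently carries gene `c` with probability
proportional to its frequency, the per-genome p-value is

    P(S has a δ-location of C) ≈ 1 − Π_{L=1..n} (1 − q(L, δ))^(n−L+1),

where `q(L, δ)` comes from an exact dynamic program that splits an
interval's distance into missing characters (a distinct-outcomes
recurrence over the cluster alphabet) and additional characters (the same
recurrence over frequency-pooled complement genes). Per-genome values are
combined across genomes under a quorum — by total distance, by a shared
distance bound, or by per-genome *individual distance bounds*
(Poisson-binomial recurrence, the default) — and corrected for multiple
testing by the conservative FDR factor `T / rank`, with
`T = Σ n_j(n_j+1)/2` candidate reference intervals. Everything is carried
in log space: real cluster p-values reach 1e-1000 and far beyond, so
results are reported as p-scores (−log10 p).

The package also contains the surrounding machinery: an exact brute-force
reference-cluster finder for desk-scale genome sets, a Monte-Carlo
validation module (empirical p-values, Agresti–Coull intervals, log-log
agreement statistics), a Pareto gene-family-size genome simulator, TSV
I/O and a small CLI (`inst/cli/clustersig`).

## Worked example

```r
library(clustersig)

# three genomes sharing a shuffled 4-gene cluster on disjoint backgrounds
core <- 1:4
mk <- function(id, perm, bg0) genome(c(bg0 + 0:4, perm, bg0 + 5:9), id = id)
gs <- list(mk("ga", core, 100), mk("gb", c(3, 1, 4, 2), 200),
           mk("gc", c(2, 4, 3, 1), 300))

fit <- gene_cluster_significance(gs, s = 3, delta = 1, quorum = 3,
                                 reference = "ga")
fit
#> Gene cluster significance: 1 cluster(s) from 3 genome(s)
#>   combination: individual bounds; quorum k' = 3; FDR universe T = 105 intervals
#>  ID G GN min max avg p-score corr. p-score       genes
#>   1 5  3   1   1 1.0    3.71          2.16 1 2 3 4 105
```

The planted cluster is found in all three genomes (`GN = 3`; the reported
maximal interval also carries one flanking background gene, hence `G = 5`
and per-genome distances 1). Its p-score 3.71 means p ≈ 1.9e-4 under
random gene order; after correcting for the 105 candidate reference
intervals of the 14-gene reference genome the corrected p-score is
3.71 − log10(105) = 2.16, i.e. p ≈ 6.9e-3 — still significant. Lower-level
pieces are exported too:

```r
single_genome_pvalue(c(1, 2), 1, frequency_model(c(1, 2, 3)))
#> <lprob> p = 1 (log p = 0, p-score = 0.0000)   # boundary: delta' = |C|-1
agresti_coull(0, 1e10)[["high"]]
#> [1] 4.637051e-10
```

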