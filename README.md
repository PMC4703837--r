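# madzyd

Chromatin states in early embryos are built by two regimes: maternal
factors loaded into the egg, and the products of the embryo's own
(zygotic) transcription. Blocking embryonic transcription with
alpha-amanitin and running ChIP-seq on treated versus control embryos at
mid-gastrulation separates the two — a chromatin feature still acquired
under blockade is **maternally defined (MaD)**, one lost under blockade
(or first appearing later) is **zygotically defined (ZyD)**. `madzyd` is
an R package for that classification and the analyses around it, aimed
at epigenomics researchers studying the maternal-to-zygotic transition.

At its core is an MA-based two-sample model on a merged peak set. For
control count *x* and treated count *y* (pseudocount *c* = 0.5):

    M = log2((x + c) / (y + c)),   A = 0.5 * log2((x + c)(y + c))

A robust linear fit of M on A over common peaks removes between-sample
bias (`M_norm = M − a − bA`), and significance comes from the
Audic–Claverie count statistic

    P(k | x) = (x + k)! / (x! · k! · 2^(x + k + 1))

summed in log space on the normalized counts. A peak is *lost* when
`M_norm > 1`, `−log10 P` exceeds the mark's cutoff (1.3 for H3K4me3 and
p300, 5 for H3K27me3) and relative RPKM (peak RPKM over the 95th
percentile of random background regions) exceeds 1 in the required
samples; *maintained* peaks are not lost and enriched in control,
treated and reference stages. Peaks maintained in both replicates and
present by stage 11 are MaD; lost in both replicates (or emerging after
stage 11) are ZyD; everything else is ND.

Around this sit: gene-level classification through promoter windows
(±250 bp H3K4me3, ±2.5 kb H3K27me3) and GREAT-style regulatory domains
(p300); enhancer-cluster calling (12.5-kb stitching, ranked-signal
elbow cutoff, hypergeometric enrichment, seeding analysis); ISMARA-style
motif-activity inference by ridge regression with z-score selection;
promoter DNA-methylation logic (coverage-weighted levels, CpG density,
Bio-CAP ratio calls); and 200-bp chromatin-state transition accounting
with exact flow conservation. A synthetic-data module plants ground
truth for all of it, so the full pipeline runs and is verified with no
downloads.

## Worked example

Simulate the benchmark transcription-blockade experiment (2,000 peaks,
60% MaD / 25% ZyD / 15% ambiguous, mean 30 reads, 8× depletion, two
replicates) and classify it:

```r
library(madzyd)
sim <- simulate_amanitin_experiment(simulation_config(seed = 1L))
cls <- classify_experiment(sim, pipeline_config(seed = 1L))
table(called = cls$table$label, truth = sim$truth$label)
#>       truth
#> called ambiguous  MaD  ZyD
#>    MaD         1 1179    0
#>    ND        296   21    3
#>    ZyD         3    0  497
```

1179/1200 true-MaD peaks (98.3%) and 497/500 true-ZyD peaks (99.4%)
recover their planted label; 296/300 replicate-inconsistent peaks land
in ND, as they should. The per-replicate normalization is essentially
the identity on this null-dominated common set:

```r
cls$fits$rep1
#> rep1 normalization: intercept -0.050, slope 0.013 (irls-bisquare, n=1481)
```

Per-peak output carries the full evidence trail:

```r
head(cls$table[, c("peak_id", "M_norm_rep1", "neg_log10_p_rep1", "label")], 3)
#>     peak_id M_norm_rep1 neg_log10_p_rep1 label
#>  peak_00001  -0.3025520        0.5036914   MaD
#>  peak_00002   2.6013771        6.8092757    ND
#>  peak_00003  -0.1971907        0.4168059    ND
```

`run_pipeline(pipeline_config(seed = 1L))` runs every stage —
classification, gene labels, enhancer clusters, motif activities,
methylation tables, state flows — and writes a machine-readable
`summary.json` that is byte-identical across runs with the same seed.

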