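# tipDNB

Dynamic network biomarker (DNB) analysis for ordered-condition expression
time courses: find the condition at which a system is about to tip from a
mild, reversible state into a severe, irreversible one.

## The problem and who this is for

In graded-insult designs — the motivating case is renal
ischemia/reperfusion injury in mice, with a sham group and increasing
ischemia durations (16–30 min) — the interesting question is not which
genes differ at the end, but *at which condition the transcriptome starts
to destabilize*. DNB theory predicts that just before a critical
transition a gene module appears with three simultaneous properties:
strongly increased expression variance across replicates, strong mutual
correlation, and weakened correlation with everything else. `tipDNB` is
for transcriptomics analysts who want that analysis — and the supporting
stages such a study uses — as tested, scriptable R functions.

## The statistic at the core

Per non-reference group, genes with high expression deviation are
selected (`SD(group) >= sdFold * SD(sham)`), their Pearson correlation
matrix is clustered at a fixed threshold (average linkage on `1 − |PCC|`,
cut at `1 − 0.9`), and each cluster is scored with the composite index

    CI = mean_SD · PCC₁ / PCC₀

(mean within-group SD of cluster genes × mean absolute intra-cluster
correlation ÷ mean absolute cluster-to-other-selected-genes
correlation). The group whose best cluster maximizes CI is the candidate
tipping point; on null data no sharp peak appears.

Supporting stages: threshold-based DEG screening against the reference
(BH FDR < 0.01 and |log2FC| > 1.2, both strict), fuzzy c-means clustering
of standardized temporal profiles, weighted running-sum gene-set
enrichment with permutation nulls, leading-edge extraction and key-gene
screening, 2^−ΔΔCt qPCR fold changes, and a negative-binomial simulator
with planted ground truth (DE genes, temporal shapes, enriched sets, and
a DNB module at a chosen tipping group).

## Worked example

Simulate a study-shaped time course (six ordered groups, a 20-gene DNB
module planted at IR22 with variance inflation 4 and intra-module
correlation 0.9; 10 replicates for correlation stability), then run the
DNB stage:

```r
library(tipDNB)
cfg <- simulationConfig(nGenes = 500, replicates = 10)
sim <- simulateTimecourse(cfg, seed = 7)
x   <- normalizeLogCpm(sim$experiment)
dnb <- runDnb(x)
dnbTable(dnb)
#>   group selected_gene_number cluster_size   mean_SD      pcc1      pcc0      CI
#> 1  IR16                   14           NA        NA        NA        NA      NA
#> 2  IR18                   18           NA        NA        NA        NA      NA
#> 3  IR22                   35            5 0.8871055 0.9315414 0.6390111 1.29321
#> 4  IR26                   18           NA        NA        NA        NA      NA
#> 5  IR30                   26           NA        NA        NA        NA      NA
tippingPoint(dnb)$group
#> [1] "IR22"
```

Reading the table: only the planted tipping group produces a gene cluster
coherent enough to survive the 0.9 correlation cut (every one of its 5
cluster genes is a planted module gene in this run); the other groups
select only sporadic high-SD genes, form no cluster, and have no defined
CI — which is exactly the DNB signature. With published summary values
the same machinery reproduces the worked example of the motivating study:

```r
compositeIndex(10.69, 0.96, 0.44)
#> [1] 23.32364
tippingPoint(c(IR16 = 18.15, IR18 = 19.43, IR22 = 23.32,
               IR26 = 19.10, IR30 = 19.35))$group
#> [1] "IR22"
```

The full pipeline (DEG → clustering → GSEA → DNB, with TSV/JSON outputs
and a run manifest) runs from one configuration:

```r
runPipeline(list(matrix = "expression.tsv", design = "design.tsv",
                 sets = "sets.gmt", out_dir = "out", seed = 1))
```

See `vignettes/tipDNB-methods.Rmd` for the model, parameter meanings,
calibration of the simulator, and known limitations.

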