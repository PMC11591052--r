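# ecdymet

Differential expression with transcript-length bias correction, plus
extracellular-flux ATP-rate decomposition and bench-assay statistics, for
cell-culture studies of 20-hydroxyecdysone (20E, ecdysterone) and similar
metabolic stimuli.

## What it is for

Studies of metabolic effectors in cultured cells (myoblasts, fibroblasts)
typically combine three data layers: bulk RNA-seq of treated vs control
replicates, Seahorse-style real-time ATP-rate profiling (OCR/ECAR traces
through oligomycin and rotenone/antimycin-A injections), and bench assays
(qPCR, immunoblot densitometry, plate assays). `ecdymet` implements the
analysis of all three layers as a tested, reusable R package, together
with seeded synthetic-data generators so that every stage can be exercised
and validated without external data.

The package's core is the transcript-length bias correction. Two-group
RNA-seq comparisons can show a spurious dependence of the per-gene log2
fold change (LogFC) on log2 transcript length (LogTL). `ecdymet`
diagnoses it and removes it conservatively:

1. fit LogFC ~ LogTL by OLS and report the Spearman/Pearson diagnostics;
2. subtract the fitted line: `corrected = initial − (a + b·LogTL)`;
3. reconcile: `final = 0` if `initial · corrected ≤ 0`, otherwise the
   one with the smaller |value| — so corrected calls are always a
   shrunken subset, never inflated;
4. call genes up/down at FDR ≤ 0.05 and |final LogFC| ≥ 0.1 (p-values
   are not recomputed; the correction touches effect size only).

Around it sit a minimal classic NB differential-expression engine
(median-of-ratios size factors; method-of-moments dispersion
`max(0, (s² − μ)/μ²)` with shrinkage toward a trimmed-mean common value;
the conditional exact test on the split of the equalized group totals;
Benjamini–Hochberg FDR), the ATP decomposition
(`mito_atp = (OCR_basal − OCR_oligo) × 2 × P/O` with P/O = 2.75;
`glyco_atp = PER_basal − CCF·(OCR_basal − OCR_rotaa)` with CCF = 0.61),
and the assay statistics (Livak 2^−ΔΔCt, densitometry and
percent-of-control normalization, pooled-variance Student's t for N = 3,
exact Mann–Whitney for N = 5).

## Worked example

```r
library(ecdymet)

# counts: 3,000 genes, 6 vs 6 replicates, length artifact calibrated to
# Spearman(LogFC, LogTL) = -0.42
se <- simulateCounts(simCountsConfig(n_genes = 3000,
                                     target_spearman = -0.42, seed = 7))
se
#> DECountSet: 3000 genes x 12 samples (6 control, 6 treated)
#>   rowData: transcript_length_bp present
#>   simulated; realized Spearman(LogFC, LogTL) = -0.403

de  <- runDE(se)                  # logfc, pvalue, fdr per gene
res <- correctTable(de, se)       # length-bias correction + calls
res$model
#> CorrectionModel (LogFC ~ LogTL)
#>   slope     -0.08493 log2FC per log2 bp
#>   intercept +0.97863 log2FC
#>   Spearman rho -0.4029 ; Pearson r -0.2942 ; n = 3000 genes

table(res$table$call)
#>  up: 179   down: 135   (rest not_significant)

# flux: 5 wells/group, treated OCR 1.5x, ECAR 1.6x
ts  <- simulateSeahorse(simSeahorseConfig(seed = 7))
atp <- atpRates(phaseRates(ts))
summarizeAtpByGroup(atp)
#>     group   measure n   mean    sem fold_vs_control   pvalue
#> 1 control  mito_atp 5 324.14 12.754           1.000       NA
#> 2 treated  mito_atp 5 492.91 18.677           1.521 0.007937
#> 3 control glyco_atp 5  71.58  4.072           1.000       NA
#> 4 treated glyco_atp 5 109.57  5.489           1.531 0.007937
#> 5 control total_atp 5 395.71 11.080           1.000       NA
#> 6 treated total_atp 5 602.47 14.797           1.523 0.007937
```

The fitted slope (−0.085 log2FC per log2 bp) is the injected artifact the
simulator calibrated to reach Spearman −0.42; after subtraction the
corrected LogFC is orthogonal to length to machine precision. The ATP
summary recovers the simulated 1.5×/1.6× treatment effects, each at the
minimum exact two-sided Mann–Whitney p for 5 vs 5 wells (2/252 ≈ 0.0079).
Dose conversion for context: `massToMolar(c(350, 650), 480.64)` gives
0.73–1.35 µM for plasma levels of 350–650 ng/mL of 20E.

`runPipeline()` chains all stages (objects or TSV/CSV paths in, tidy TSVs
and a printable run report out).

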