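# KaKsEval

Pairwise Ka/Ks estimation with eight methods, cross-method consistency
analysis, and Ka-percentile classification of protein-coding genes.

## The problem

For a pair of orthologous coding sequences, **Ka** is the number of
nonsynonymous substitutions per nonsynonymous site, **Ks** the number of
synonymous substitutions per synonymous site, and **ω = Ka/Ks** the
standard measure of selection strength (ω < 1 purifying, ω > 1
positive). Many estimators of (Ka, Ks) coexist and disagree — far more
for Ks than for Ka. This package is for comparative genomicists who want
to (1) compute Ka/Ks for ortholog pairs with the widely used estimators
behind one interface, (2) quantify how much the estimators agree on
their data, and (3) rank and classify genes by evolutionary rate with
the statistic that is most stable across methods.

The eight estimators:

| Tag | Family | Distinguishing feature |
|-----|--------|------------------------|
| NG | counting | equal weight to every mutation pathway, Jukes–Cantor correction |
| LWL | counting | 0/2/4-fold degeneracy classes, K2P per class, fixed 1/3 : 2/3 two-fold weights |
| LPB | counting | flexible transition/transversion treatment of two-fold sites |
| MLWL | counting | LWL + inverted two-fold (arginine/ATA) sites + data-estimated κ weighting |
| MLPB | counting | LPB + inverted two-fold sites |
| YN | approximate | codon-frequency (F3x4) and κ-weighted sites, iterative ω weighting, K2P |
| MYN | approximate | YN with separate purine (A↔G) and pyrimidine (C↔T) transition rates, TN93 |
| GY | maximum likelihood | 61-state codon model, P(t) = exp(Qt), MLE of (t, κ, ω) |

Consistency is measured per gene by two divergence indexes over the
eight estimates — sd/mean and range/mean — compared between Ka and Ks
with a Wilcoxon rank-sum test, and by the **shared-gene percentage**:
the overlap of the top (or bottom) `floor(cutoff·n)` genes ranked by two
methods, normalized by the set size. Genes are classified as
slow/intermediate/fast-evolving as the bottom/middle/top 10% of the Ka
ranking (NA Ka counts as 0). A Markov codon-model simulator with
exactly computable expected Ka/Ks provides ground truth.

## Worked example

```r
library(KaKsEval)

sim <- simulateMethodTable(60, nCodons = 200, t = 0.5, kappa = 2,
                           omegaRange = c(0.05, 0.5), seed = 7)
tab <- filterCompleteGenes(sim$table)
tab
#> MethodTable: 60 genes x 8 methods (NG, LWL, MLWL, LPB, MLPB, YN, MYN, GY)
#>   NA entries: ka 0, ks 0, omega 0

estimateKaKs(sim$alignments[[1]])[, c("method", "ka", "ks", "omega")]
#>   method     ka    ks omega
#> 1     NG 0.0982 0.359 0.273
#> 2    LWL 0.1006 0.354 0.284
#> 3   MLWL 0.1060 0.296 0.358
#> 4    LPB 0.1075 0.293 0.367
#> 5   MLPB 0.1060 0.297 0.357
#> 6     YN 0.1065 0.290 0.368
#> 7    MYN 0.1074 0.290 0.370
#> 8     GY 0.1076 0.294 0.366
# generating truth for this gene: ka 0.0989, ks 0.342, omega 0.289

div <- divergenceTable(tab)
compareDivergence(div, "sd")
#> $statistic 342   $p.value 2.01e-14
#> $median_ka 0.0322   $median_ks 0.0726
```

The eight methods agree closely on Ka (median cross-method divergence
index 0.032) and much less on Ks (0.073); the rank-sum p-value says the
gap is systematic. That is the package's central observable: **Ka is the
more consistent statistic for ranking genes by evolutionary rate.**

```r
sharedGenePercentage(tab, "ks", reference = "GY", other = "NG",
                     cutoff = 0.10, tail = "fast")
#> [1] 83.33333

cls <- classifyByKa(data.frame(gene_id = geneIds(tab),
                               ka = kaMatrix(tab)[, "GY"]))
table(cls$class)
#>  slow intermediate  fast unclassified
#>     6            6     6           42
```

Real alignments enter through `readPairwiseAlignments()` (AXT blocks or
consecutively paired FASTA records) or `backtranslate()` (protein
alignment + CDS), are quality-checked with `qcPair()`/`qcDataset()`, and
filtered into codon alignments with `buildCodonAlignment()`. Enrichment
of a class against an annotation table (`enrich()`: Fisher exact + Holm,
threshold 0.1) and expression-by-class comparisons
(`compareExpressionByClass()`, TPM units) complete the workflow. Shell
users can drive everything through
`Rscript inst/scripts/kaks.R <subcommand> ...`.

See `vignettes/kaks-methods.Rmd` for the models, conventions and design
decisions.

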