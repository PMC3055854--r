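---
title: "Estimating Ka and Ks with eight methods and measuring their agreement"
author: "KaKsEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Ka and Ks with eight methods and measuring their agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KaKsEval)
```

## The problem

For a pair of orthologous protein-coding sequences, Ka is the number of
nonsynonymous substitutions per nonsynonymous site and Ks the number of
synonymous substitutions per synonymous site; their ratio omega = Ka/Ks
measures selection strength (below 1: purifying; above 1: positive
selection). Many estimators of these quantities coexist, from simple
counting schemes to full maximum-likelihood codon models, and they can
disagree substantially — more for Ks than for Ka. This package implements
eight widely used pairwise estimators behind one interface, quantifies
their cross-method agreement, and classifies genes into fast-,
intermediately- and slow-evolving groups by Ka percentile, with
enrichment and expression comparisons downstream. A codon-model simulator
with exactly computable expected rates provides ground truth for every
claim the package makes about its own estimators.

## The eight estimators

All estimators consume a `CodonAlignment`: an in-frame pair of sequences
from which codon columns containing gaps, ambiguous bases or stop codons
have been removed whole (the least-assumption treatment of ambiguity —
partial codons cannot be scored by any of the methods).

**NG** counts synonymous sites per codon as the number of synonymous
single-base changes divided by three (changes to stop codons count as
nonsynonymous), averages site totals between the two sequences so that
N + S = 3 x (number of codons) exactly, enumerates all orderings of the
differing positions of each codon pair with equal weight (orderings that
pass through a stop codon are discarded; if every ordering is blocked,
all are retained so differences are never dropped), and corrects the
synonymous and nonsynonymous difference proportions separately with the
one-parameter Jukes-Cantor formula d = -(3/4) log(1 - 4p/3).

**LWL** stratifies sites into non-degenerate (L0), two-fold (L2) and
four-fold (L4) classes — a position is four-fold if all three alternative
bases are synonymous, non-degenerate if none is, two-fold otherwise (the
isoleucine three-fold position folds into the two-fold class) — and
applies the Kimura two-parameter decomposition per class, giving
transition (A_i) and transversion (B_i) distance components. Two-fold
sites get the fixed weights 1/3 synonymous : 2/3 nonsynonymous:

Ks = (L2 A2 + L4 (A4 + B4)) / (L2/3 + L4),
Ka = (L2 B2 + L0 (A0 + B0)) / (L0 + 2 L2/3).

**LPB** uses the same site classes but avoids the fixed weight by
treating the transition and transversion components of two-fold sites
flexibly: Ks = (L2 A2 + L4 A4)/(L2 + L4) + B4 and
Ka = (L0 B0 + L2 B2)/(L0 + L2) + A0. LWL and LPB coincide exactly when
B = 2A in every class, i.e. when transitions carry no rate excess
(kappa = 1); the package's convergence test simulates at kappa = 1 for
this reason.

**MLWL and MLPB** correct the parent methods at the codon positions where
the standard two-fold logic inverts: every sense-codon position whose
synonymous alternatives are all transversions. That is the first position
of the arginine codons AGA, AGG, CGA and CGG (AGA&harr;CGA and
AGG&harr;CGG are synonymous transversions) plus the third position of
isoleucine ATA, where the transition ATA&rarr;ATG changes the amino acid
while the transversions are silent. These positions form an "inverted"
two-fold class whose transversions feed the synonymous pool and whose
transitions feed the nonsynonymous pool. MLWL additionally estimates the
transition/transversion rate ratio kappa from the K2P-corrected distances
pooled over all sites and weights the synonymous opportunity of a normal
two-fold site as kappa/(kappa + 2) (recovering the LWL 1/3 at kappa = 1);
an undefined kappa falls back to 2 with a warning.

**YN** is an iterative approximate method: (1) kappa is estimated from
nucleotide differences at positions whose degeneracy class agrees between
the two sequences and is 0- or 4-fold, via the K2P decomposition;
(2) synonymous/nonsynonymous sites are counted by mutational opportunity,
each single-base change weighted by the F3x4 positional frequency of the
target base times the kappa factor; (3) differences are counted by
pathway enumeration with pathway weights proportional to the product of
step weights (target-base frequency x kappa factor x omega for
nonsynonymous steps); (4) the synonymous and nonsynonymous difference
classes are corrected with K2P; (5) omega is iterated to relative
convergence 1e-8 (at most 100 iterations; running out sets NA flags).

**MYN** follows the same skeleton but separates the purine (A&harr;G) and
pyrimidine (C&harr;T) transition classes throughout: kappa_R and kappa_Y
are estimated with the Tamura-Nei (TN93) decomposition, which also
replaces K2P in step (4). The TN93 components use the alignment-wide base
frequencies; frequencies restricted to each site class would be noisier
at realistic alignment lengths, which is the trade-off accepted here.

**GY** is full maximum likelihood on a 61-state codon model. The
generator assigns rate pi_j x {1, kappa, omega, omega kappa} to single
base changes (synonymous/nonsynonymous x transversion/transition), zero
to multi-base changes, and is scaled to one expected substitution per
codon per unit t, so t is reported in substitutions per codon. The
pairwise likelihood sum(log(pi_i P(t)_ij)) is maximized over log(t),
log(kappa), log(omega) with bounded quasi-Newton from three fixed starts
(pairwise surfaces are occasionally flat in omega at low divergence, and
the multi-start costs little). The matrix exponential is computed through
the eigensystem of the symmetrized reversible generator, which is exact
for this model class and much faster than a general-purpose algorithm in
the optimizer's inner loop.

### Site-definition convention

The conversion from model parameters to Ka/Ks uses
mutational-opportunity site fractions: the synonymous/nonsynonymous site
split comes from the omega = 1 generator (same kappa and frequencies),
and Ka = t rho_N / (3 f_N), Ks = t rho_S / (3 f_S), where rho are the
flux fractions at the fitted omega. Excluding omega from the site
definition matches the convention of the counting methods, which is what
makes cross-method comparison meaningful; the simulator's
`expectedRates()` uses the identical convention, so parameter-recovery
checks are exact in expectation.

### NA semantics

Saturation (a non-positive logarithm argument) and zero denominators set
NA flags; they never raise errors. Ks = 0 with Ka > 0 yields an NA omega
rather than infinity. Ka = 0 with Ks > 0 is the value 0, not NA.

## Consistency statistics

For each gene the package collects the eight Ka (and Ks, omega) values
as a group and computes two divergence indexes: the sample standard
deviation (n-1 denominator; the convention is stated because the source
procedure does not fix it, and the second index is convention-free)
normalized by the mean, and the range (max - min) normalized by the
mean. Genes with any NA in Ka or Ks across the eight methods are
eliminated before divergence analysis. The Ka and Ks index samples are
compared with a two-sided Wilcoxon rank-sum test (exact for small
samples without ties, normal approximation with tie correction
otherwise).

The shared-gene percentage ranks genes by one statistic under two
methods, takes the top (fast) or bottom (slow) floor(cutoff x n) genes
under each, and reports the intersection as a percentage of the set
size. Canonical cut-offs are 5, 10, 20, 30, 40 and 50 percent; ranking
ties are broken stably by gene id so boundary membership is
deterministic.

## Classification, network, enrichment

Genes are sorted ascending by Ka with NA treated as 0 (NA values are
typically produced by identical gene pairs, so they belong at the slow
end; this NA rule applies to classification only — consistency analyses
eliminate NA genes instead). With k = floor(0.10 x n): ranks 1..k are
slow, ranks n-k+1..n are fast, and the k genes centered on the median
rank (window starting at ceiling((n-k)/2)) are intermediate. The
centered window is the symmetric, deterministic reading of "middle 10%";
any contiguous middle window would be defensible, but only the centered
one is permutation-stable and unambiguous.

The species network connects species pairs by the number of shared
fast- (or slow-) evolving genes divided by the total number of shared
genes. The retention rule "largest two coefficients for each pair" is
ambiguous between per-species and per-pair readings; the default keeps,
per species and class, the two largest incident coefficients (ties
broken stably), and a `retention = "per_pair"` switch instead keeps the
single best class edge per pair. Neither reading is asserted as the
original; both are exported.

Enrichment uses a two-sided Fisher exact test per category (the
"probability not exceeding the observed table" convention) with Holm
step-down correction within each annotation level, threshold 0.1 applied
to the adjusted p-value by default (`useAdjusted = FALSE` switches to
raw, since the source procedure does not say which it thresholded), and
a direction filter so that only over-represented categories are called
enriched. The background defaults to all genes with an estimated Ka.
Expression comparisons are two-sided rank-sum tests of
transcripts-per-million values between classes, with per-class means and
medians reported (right-skewed expression makes the mean exceed the
median in every class).

## The simulator

`simulatePair()` draws ancestral codons i.i.d. from the stationary law
pi (default: F3x4 from uniform base composition, which renormalizes to
the uniform distribution over the 61 sense codons) and evolves two
independent lineages for t/2 each under the scaled generator — the
symmetric two-lineage design is equivalent to one lineage of length t by
reversibility and is stated explicitly to avoid divergence-unit
confusion. `expectedRates()` returns the exact model-implied Ka and Ks
under the same site convention as the estimators.
`simulateMethodTable()` draws per-gene omega from uniform(0.05, 0.5) by
default — ortholog pairs are predominantly under purifying selection and
this range keeps most Ka/Ks well below 1 — and derives per-gene child
seeds from the root seed by one `sample.int()` call, so per-gene results
are reproducible regardless of iteration order. Estimator NA values are
kept in the table so NA-handling paths stay exercised.

What the simulator does **not** emulate: insertions/deletions and
alignment error, among-site rate variation, codon-position-specific GC
evolution, CpG hypermutability, and selection heterogeneity along the
sequence. Passing recovery tests therefore demonstrate correctness of
the estimators under their own model class, not robustness to real-data
pathologies; the cross-method consistency results mirror the qualitative
behaviour reported for genome-scale ortholog sets (Ka more stable than
Ks across methods, Ks agreement decaying with divergence) without
reproducing any genome-specific number.

## Study conditions and problem sizes

The test suite fixes its simulation conditions once: a 500-gene table of
300-codon alignments at t = 0.5 substitutions per codon, kappa = 2,
omega ~ uniform(0.05, 0.5) for the consistency checks; 100 replicates of
500-codon pairs at (t = 0.3, kappa = 2, omega = 0.25) for parameter
recovery (GY median omega within 15%, counting-method median Ka within
20% of truth); a divergence sweep t in {0.1, 0.3, 0.6, 1.0, 1.5} with
100 genes per level, spanning primate-like to bird-like distances, where
NA attrition at the top of the range is expected and handled by the
NA-elimination rule. The acceptance script runs a 150-gene, 200-codon
version of the same pipeline; these sizes were chosen to make the full
analysis comfortably reproducible on a laptop while keeping every
directional result far from its decision boundary.

## A worked example

```{r example, eval = FALSE}
sim <- simulateMethodTable(60, nCodons = 200, t = 0.5, kappa = 2,
                           omegaRange = c(0.05, 0.5), seed = 7)
tab <- filterCompleteGenes(sim$table)
div <- divergenceTable(tab)
compareDivergence(div, "sd")
sharedGenePercentage(tab, "ks", reference = "GY", other = "NG",
                     cutoff = 0.10, tail = "fast")
cls <- classifyByKa(data.frame(gene_id = geneIds(tab),
                               ka = kaMatrix(tab)[, "GY"]))
head(cls)
```

## Known limitations

Pairwise estimates only: no phylogeny, no branch- or site-model
likelihood-ratio machinery. Gamma-distributed rate variants of the
counting methods are out of scope. The YN/MYN implementations follow the
published iterative skeleton (kappa from degeneracy-stratified sites,
frequency-weighted opportunities, omega-weighted pathways, K2P/TN93
correction) rather than reproducing any particular release of the
original programs line by line; their estimates agree with GY and with
the simulator's truth well within the documented tolerances, which is
the property the cross-method analysis needs. At divergences beyond
roughly one substitution per codon the counting methods saturate first
and return NA at increasing rates — this attrition is real signal, not
failure, and is surfaced rather than masked.
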