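# equiqtl

Cis/trans eQTL discovery and quality control for outbred cohorts with
family structure.

`equiqtl` re-implements, as a tested and reusable R pipeline, an
expression-QTL analysis of the kind run on peripheral blood mononuclear
cells from outbred livestock cohorts: tens of individuals, two half-sib
families plus unrelated animals, RNA-seq gene counts, and dense imputed
SNPs. It is aimed at quantitative geneticists who want every step of such
an analysis — filtering, scanning, diagnostics, downstream enrichment —
as plain functions they can test and rerun, rather than a chain of
external tools.

## What it computes

**Additive linear eQTL scan.** For residual expression *y* and allele
dosage *m* (0/1/2), each (SNP, gene) pair is scored under

    y = μ + m·u + ε

by simple linear regression, using the correlation identity
*t* = *r*·√(n−2)/√(1−r²) so the full SNP×gene grid is one matrix
cross-product. A pair is **cis** when the SNP lies within 1 Mb (inclusive)
of the gene's transcription start site on the same chromosome, otherwise
**trans**; Benjamini–Hochberg FDRs are controlled separately within the
two streams, and the lowest-FDR eSNP per gene is the gene's
representative eQTL.

**Expression preparation.** Genes are filtered by an iterative pairwise
Kolmogorov–Smirnov procedure: for every pair of samples, candidate read-count
cutoffs 0, 2, …, 300 are scanned, dropping genes whose pair-mean
normalized count falls below the cutoff and recomputing the two-sample KS
D between the samples' expression profiles; iteration stops at the first
local minimum of D that improves on the starting D by more than 1e-4.
The per-pair cutoffs are averaged, genes below the mean cutoff are
removed, and the rest are normalized (median-of-ratios size factors),
variance-flattened (log2(normalized + 1)), and residualized on known
covariates plus principal-component latent factors.

**Confidence classification.** Every significant eQTL is re-fit;
individuals with Cook's distance > 0.5 **and** leverage > 2p/n are
outliers, and a four-component omnibus (skewness, kurtosis, link
function, heteroscedasticity — each χ²(1), summed to χ²(4)) tests the
linear-model assumptions. An eQTL with outliers or a rejected omnibus is
labelled **low confidence**, otherwise **high**.

**Downstream analyses.** Cross-treatment gene sharing, −log10 p matrices,
eSNP distance distributions against a random-2-Mb-window null,
TSS-proximity enrichment (one-sample KS against Uniform(−1 Mb, +1 Mb)),
trans-regulatory-hotspot detection (per-SNP binomial enrichment over the
tag-SNP background), and a pooled two-proportion z-test on genic
(5'UTR/exon/intron/3'UTR) eSNP fractions.

**LD and tag SNPs.** Haplotype D, D′ and r², plus greedy windowed tag-SNP
selection (MAF > 0.05, r² ≥ 0.99 within ±100 kb).

**Case-control GWAS.** Per-SNP logistic regression of disease status on
intercept + age + sex + Fam1 + Fam2 + dosage, Wald-tested on the dosage
term, with overlap reporting against the cis eSNP tables and
expression→disease logistic models with protected surrogate variables.

**Synthetic cohorts.** A first-class generator produces phased genotypes
with tunable LD and half-sib family structure, negative-binomial counts
with planted cis effects, a trans hotspot, latent batch factors,
low-expression noise genes, planted outliers, a binary phenotype — and a
ground-truth set for recovery testing.

## Worked example

```r
library(equiqtl)

cfg <- sim_config(seed = 7, n_chroms = 2, n_snps = 200, n_genes = 150,
                  n_noise_genes = 50, n_cis_effects = 10, cis_fold = 1.6)
sim <- simulate_cohort(cfg)
sim
#> Simulated eQTL cohort: 82 individuals ( 50 unrelated, 17 fam1, 15 fam2 ), 400 SNPs, 200 genes
#>   planted cis effects: 10

ks <- ks_cutoff_cohort(sim$counts[, 1:12])   # subset of samples for speed
ks
#> KS read-count cutoff over 66 sample pairs
#>   mean cutoff: 3.68  median cutoff: 2
#>   unresolved pairs: 29
#>   genes retained: 154

expr  <- vst(sim$counts[ks$genes_retained, ])
resid <- residualize(expr, sim$covariates, k_factors = 1)
tab   <- eqtl_scan(resid, sim$genotypes, sim$genes)
best  <- add_confidence(best_per_gene(tab), resid, sim$genotypes)
summary(best)
#> eQTL scan: 154 tested pairs ( 151 cis / 3 trans )
#> significant at FDR < 0.05 : 12 cis, 0 trans
#> confidence among significant: high 12 / low 0 / unset 0

sig <- best[best$fdr < 0.05, ]
sum(sim$truth$cis_effects$gene %in% sig$gene)
#> [1] 10        # all ten planted effects recovered
```

The mean KS cutoff (3.68) sits just above the simulated noise genes'
baseline, so the 50 noise genes are removed and almost all expressed
genes survive. The scan then finds 12 significant cis genes at FDR <
0.05: the 10 planted effects plus two borderline calls, all labelled
high confidence because no outlier drives them and the residuals pass
the assumption omnibus.

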