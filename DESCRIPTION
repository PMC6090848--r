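Package: equiqtl
Title: Cis/Trans eQTL Discovery and Quality Control for Outbred Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for expression quantitative trait locus (eQTL)
    discovery in outbred cohorts with family structure, modelled on peripheral
    blood mononuclear cell studies in the horse. Provides low-expression gene
    filtration by an iterative pairwise Kolmogorov-Smirnov cutoff,
    median-of-ratios normalization with a variance-flattening transform,
    covariate and latent-factor residualization, a fast additive linear
    cis/trans eQTL scan with Benjamini-Hochberg false discovery rate control,
    outlier and linear-model-assumption based confidence classification of
    eQTLs, haplotype linkage-disequilibrium and greedy tag-SNP selection,
    trans regulatory hotspot detection, transcription-start-site proximity
    enrichment, and a per-SNP case-control logistic genome-wide association
    scan. Includes a synthetic cohort generator with planted effects and a
    ground-truth set for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
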