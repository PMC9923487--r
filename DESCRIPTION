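Package: poolColorScan
Title: Pool-Seq Allele-Frequency Association Scans for Color Phenotypes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome pooled-sequencing association scans of
    categorical phenotypes such as inner-shell color in pearl oysters.
    Reads multi-pool VCFs carrying per-pool allele depths, applies
    depth/missingness/minor-allele-frequency filters, decomposes biallelic
    block substitutions into SNPs, and tests each SNP with a two-factor
    linear model of allele frequency (phenotype plus geographic site) using
    simultaneous Tukey all-pairs contrasts on both factors with a Bonferroni
    correction. Loci are classified as color-associated, color-specific, or
    geography-associated. Includes a simplified variant-effect annotator
    with SnpEff-style impact categories, descriptive summaries (windowed
    nucleotide diversity, PCA of pool allele frequencies, AF histograms,
    Kruskal-Wallis and pairwise Wilcoxon comparisons), and a two-stage
    pool-seq simulator with planted effects for calibration studies.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
biocViews: Genetics, SNP, Sequencing, StatisticalMethod, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
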