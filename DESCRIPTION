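Package: snpanel
Title: Design and Validation of Low-Density Targeted SNP Genotyping Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and validating low-density targeted SNP
    genotyping panels (liquid-phase capture chips) from population
    resequencing data. Screens background loci by missingness and minor
    allele frequency, breed-specific loci by between-group allele-frequency
    differentiation (delta-MAF), places loci uniformly along chromosomes,
    vets 110-bp capture probes for GC content and genome-wide k-mer
    homology, annotates panel SNPs by genic context and coding consequence,
    and computes panel validation metrics (per-sample detection rate,
    replicate and truth-set genotype concordance, MAF spectrum) together
    with population-structure summaries (PCA, identity-by-state distances,
    neighbor-joining trees with bootstrap support, VanRaden kinship). A
    Balding-Nichols cohort simulator and a synthetic-reference generator
    supply every input the pipeline needs, so the whole workflow runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    ape,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
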