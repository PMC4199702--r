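Package: exHetMap
Title: Genetic Maps for Selfed Recombinant Inbred Populations with
    Excess Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models two-locus genotype frequencies in selfed recombinant
    inbred line (RIL) populations that retain more heterozygosity per
    generation than expected under Mendelian segregation. Implements a
    five-class genotype Markov chain with a heterozygote-viability term,
    maximum-likelihood estimation of pairwise recombination fractions
    under that model, Haldane map construction from adjacent-marker
    estimates, quality-control filters for RIL genotype matrices
    (missingness, duplicate individuals, segregation distortion under a
    non-Mendelian null, tight double-recombination masking), a genotype
    simulator matching the model, VCF import for biparental populations,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
biocViews: Genetics, GeneticVariability, SNP, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
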