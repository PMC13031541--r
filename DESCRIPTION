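Package: KaryoCline
Title: Inversion Karyotyping, Diagnostic PCR-RFLP Marker Design, and
    Latitudinal Clines of Arrangement Frequency
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and karyotypes polymorphic chromosomal inversions from
    hard-called genotype matrices using sliding-window principal component
    analysis along a chromosome, with automated three-cluster karyotype
    assignment checked against heterozygosity. Computes Hudson's FST
    (ratio-of-averages) per site and in windows, pairwise haplotype
    divergence, and epsilon = 0 minimum spanning networks. Designs diagnostic
    PCR-RFLP assays from karyotype-fixed coding SNPs by in-silico restriction
    digestion, and scores marker-versus-karyotype concordance. Models clines
    of arrangement frequency along latitude or temperature with aggregated
    binomial regression (logit link), tests Hardy-Weinberg equilibrium of
    karyotype counts, and fits quadratic thermal performance curves of
    egg-to-adult viability with closed-form extraction of thermal traits.
    Includes a synthetic-data module generating genotype, cline, marker-region
    and viability datasets with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    car,
    ape,
    jsonlite
biocViews: PopulationGenetics, SNP, PrincipalComponent, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
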