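Package: BreedGenomics
Title: Genomic Characterization of Rare Livestock Breeds and Selection of
    Breed-Distinctive SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genomic characterization of numerically small
    livestock breeds from SNP-array genotypes: quality control and merging of
    PLINK/VCF genotype data, windowed nucleotide diversity and Tajima's D,
    runs of homozygosity and ROH-based inbreeding, genomic relationship
    matrices (VanRaden and allelic-similarity) with derived inbreeding
    coefficients, pedigree inbreeding and generation accounting, LD-based
    historical effective population size with linear extrapolation to the
    present, between-breed relatedness (IBS distances, bootstrap
    neighbor-joining consensus trees, Weir-Cockerham Fst, maximum-likelihood
    admixture with cross-validated K), and an end-to-end pipeline that selects
    and validates a small panel of SNPs distinguishing a focal breed from all
    others via pairwise-Fst preselection and per-chromosome canonical
    discriminant analysis. A multi-breed genotype simulator with known truth
    (drift model, Wright-Fisher forward simulation, pedigree gene-drop,
    admixture mixing) supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'admixture.R'
    'diversity.R'
    'genotype-io.R'
    'grm.R'
    'ne.R'
    'relatedness.R'
    'panel.R'
    'panel-validate.R'
    'roh.R'
    'pipeline.R'
    'simulate.R'
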