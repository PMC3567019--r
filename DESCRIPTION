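Package: arraypopgen
Title: Population Genetics of Genome-Wide SNP Array Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis of diploid biallelic SNP genotype panels from
    multi-population diversity studies: PLINK text import/export and
    chip-style quality control, diversity summaries (proportion of
    polymorphic loci, expected heterozygosity, allelic richness by
    rarefaction), allele-sharing distances and neighbor-joining trees,
    LD pruning and principal component analysis of population structure,
    Weir-Cockerham F_ST, linkage-disequilibrium decay with the Sved
    hyperbolic model, runs-of-homozygosity detection, and a Bayesian
    F_ST-outlier selection scan with reversible-jump MCMC. Includes a
    seed-deterministic multi-population genotype simulator
    (Balding-Nichols divergence, tunable LD decay, planted autozygous
    tracts, admixture, planted outlier loci) and a pipeline driver that
    reproduces the full study design on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
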