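Package: irradgbs
Title: Mutation and Recombination Screening from Genotyping-by-Sequencing
    of Irradiated Plant Progeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of reduced-representation
    (genotyping-by-sequencing) variant tables from radiation mutagenesis
    experiments in plants.  Screens induced single-base substitutions and
    1-2 bp insertions/deletions in mutant lines against a consensus of
    non-irradiated controls; reports mutation densities per 10 Mb of
    mapped sequence, strand-collapsed substitution spectra,
    exon/intron/intergenic context, and a Mendelian segregation-loss
    back-correction between selfing generations.  Counts meiotic
    recombination events in backcross progeny from zygosity switches of
    quality-filtered SNP markers, with singleton exclusion to suppress
    genotyping error.  Includes a synthetic genotype-by-sequencing data
    generator (mapped-region genome, biparental cross, Poisson crossover
    meiosis, induced mutations, negative-binomial depth and read-level
    genotyping error) with full ground truth, so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
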