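Package: forensicpanel
Title: Forensic Efficiency and Population Genetic Statistics for NGS Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for characterising forensic marker panels
    (autosomal, X- and Y-chromosomal STRs, identity and ancestry SNPs, and
    mitochondrial control-region sequences) in population samples. Computes
    per-locus and combined forensic efficiency parameters (heterozygosities,
    polymorphism information content, match and discrimination probabilities,
    exclusion probabilities, X-chromosomal mean exclusion chances), exact
    Hardy-Weinberg and permutation linkage-disequilibrium tests with
    Bonferroni bookkeeping, an IBD-coefficient kinship likelihood-ratio
    simulation engine, mitochondrial diversity indices with neutrality tests
    and mismatch-distribution expansion fitting, and between-population
    comparison statistics (pairwise FST, haplogroup Z-scores, informativeness
    for assignment). A seeded synthetic-data generator (Dirichlet allele
    frequencies, Hardy-Weinberg genotypes, Balding-Nichols population
    structure, gene-dropped relative pairs over optionally linked loci, and
    coalescent haploid sequence samples under constant-size and
    sudden-expansion demographies) exercises every stage without access to
    raw casework genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
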