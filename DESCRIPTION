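Package: ovigene
Title: Candidate-Gene Polymorphism, Expression and Litter-Size Association
    Analysis for Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-locus candidate-gene studies in livestock,
    built around SMAD-family polymorphisms in Tibetan sheep. Computes
    genotype and allele frequencies, gene-diversity indices (homozygosity,
    heterozygosity, effective allele number, Botstein's polymorphism
    information content) and Hardy-Weinberg chi-square tests from genotype
    tallies; fits a fixed-effects parity-by-genotype linear model for litter
    size with Type III partial F-tests; performs Livak 2^-ddCt relative
    expression analysis across tissues with one-way ANOVA and compact letter
    display; characterizes cloned cDNAs (longest ORF, translation, protein
    molecular weight and isoelectric point, pairwise percent-identity
    matrices, neighbor-joining phylogenies); and generates synthetic
    genotype, phenotype, quantification-cycle and homolog-family data with
    the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    seqinr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
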