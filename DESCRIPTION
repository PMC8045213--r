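Package: homeoscope
Title: Homeolog Expression Inheritance and Bias Analysis for Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative transcriptome analysis of allopolyploids and their
    diploid progenitors from gene-level read counts. Partitions allotetraploid
    sequencing fragments into parental homeolog bins via diagnostic SNPs,
    quantifies expression (FPKM, TMM normalization), calls differential
    expression with a negative-binomial exact test, classifies inheritance of
    parental expression into the twelve-state scheme (intermediate,
    expression-level dominance, transgressive, conserved), computes relative
    homeolog contribution (Rh) and homeolog expression bias (Rh versus the
    parental ratio Rp, Fisher's exact test), accounts for silent or lost
    homeologs, and analyses species-specific and coexpressed ortholog
    families. Includes a seeded negative-binomial simulator that emits
    ground-truth labels for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
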