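Package: hetdnamap
Title: Heteroduplex DNA Tract Mapping in Nuclease-Induced Mitotic Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of heteroduplex DNA (hetDNA) in
    noncrossover products of mitotic double-strand-break repair in yeast.
    Provides a generative model of repair products (synthesis-dependent
    strand annealing, double Holliday junction dissolution, crossovers,
    and polymerase-proofreading removal of break-proximal mismatches), a
    barcoded amplicon read simulator emulating circular consensus
    sequencing of recombinant colonies, and the analysis pipeline that
    demultiplexes reads, calls the two sequence species per colony,
    classifies SNPs as recipient/donor/heteroduplex, delineates
    gene-conversion and hetDNA tracts, and summarizes cohorts. A small
    statistics layer implements 2x2 chi-square contingency tests with
    Yates correction, the Mann-Whitney U test with exact enumeration for
    small samples, Wilson score intervals, and Southern-blot
    recipient:donor ratio arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
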