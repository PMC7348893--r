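Package: parboundary
Title: Locating the Pseudoautosomal Boundary on Young Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate the boundary between the non-recombining region
    of a Y chromosome (NRY) and the recombining pseudoautosomal region (PAR)
    from genetic-cross segregation and wild-population polymorphism data,
    with the dioecious plant Silene latifolia as the motivating system.
    Identifies Y-linked SNPs from father-to-son co-segregation in a mapping
    family, scans wild females for leaked Y alleles as evidence of rare
    recombination in male meiosis, classifies genes into fully sex-linked,
    partially sex-linked ("fuzzy boundary") and pseudoautosomal categories,
    and computes sex-stratified diversity statistics (nucleotide diversity,
    Weir-Cockerham F_ST between the sexes, Tajima's D). Includes a forward
    simulator of an XY genetic cross plus wild panel with tunable X-Y
    gametolog divergence and male-recombination leakage, VCF import/export,
    and cross-study genetic-map integration from homology-search hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
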