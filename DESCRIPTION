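Package: thermoglyco
Title: TMT Proteome and N-Glycoproteome Differential Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tandem-mass-tag (TMT) labelled proteome and
    N-glycoproteome experiments across culture conditions. Implements reporter-ion
    ratio quantitation with median-ratio normalization over unique peptides, protein
    roll-up by the median of unique-peptide ratios, protein-corrected N-glycosite
    occupancy ratios, fold-change plus Student t-test differential calling with
    three-way Venn partitioning, N-X-S/T sequon detection and flanking-residue
    occupancy matrices, amino-acid composition comparison of protein sets, and
    two-tailed Fisher exact functional enrichment with clustered heatmaps. Ships a
    seeded synthetic-data generator with ground truth so the whole pipeline is
    testable end to end.
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
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
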