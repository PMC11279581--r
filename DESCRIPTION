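Package: cyclopep
Title: Topology, Ring Ontology and Potency Statistics for Small Cyclic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small (<= 25 residue) cyclic antimicrobial
    peptides: a controlled ontology of ring-closing intrachain bonds and the
    rings they form, classification of disulfide-bonded chain topology
    (lasso-like vs hairpin-like for one bond; ladder-like, string-of-rings,
    crossed-rings for several), exhaustive enumeration of cysteine pairing
    schemes as a chord-diagram combinatorics oracle, the distribution of
    i-spaced amino-acid pairs (DiSAAP) with composition-preserving
    permutation and analytic null models, amino-acid composition enrichment
    against a background, and a signed log2 MIC-ratio statistic for paired
    linear/cyclic peptides on a two-fold dilution scale. Includes a seeded
    generator of database-like peptide records with planted structure so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
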