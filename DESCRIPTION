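Package: codonStability
Title: Codon Optimality and mRNA Stability/Synthesis Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the genome-wide association between codon
    optimality and mRNA kinetics in yeasts. Computes per-codon rank
    correlations between codon occurrence and mRNA half-lives (CSC) or
    synthesis rates (CPC), tRNA adaptation index (tAI) weights from tRNA
    gene copy numbers with wobble-pairing penalties, gene-level geometric
    mean tAI and percent-optimal-codon content, sign-partition chi-square
    tests against binary codon-optimality classifications, steady-state
    conversions between half-lives, synthesis rates and abundance,
    Spearman partial correlations controlling for abundance, frameshift
    controls, motif-optimality rank-sum tests, cross-dataset comparison
    utilities, and a synthetic-data generator with tunable
    optimality-expression coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'codon-tables.R'
    'codonStability-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'codon-core.R'
    'comparison.R'
    'kinetics.R'
    'motifs.R'
    'optimality.R'
    'simulate.R'
    'pipeline.R'
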