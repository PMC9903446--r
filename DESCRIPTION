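Package: chimeraCMS
Title: Survey Analysis of the Chimeric Mitochondrial CMS Locus B-atp6-orfH79 in Wild Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population surveys of the chimeric mitochondrial
    cytoplasmic-male-sterility (CMS) locus B-atp6-orfH79 and its sequence
    variants in wild rice (Oryza rufipogon). Collapses sequenced amplicons
    into haplotypes with per-population counts, annotates the chimeric
    architecture (B-atp6 / downstream / variable spacer / ORF segments,
    mirror-repeat junction motifs, COXII prefix), builds dot-notation
    variable-site matrices and global-alignment identity tables, translates
    ORF haplotypes into protein haplotypes, partitions molecular variance by
    a two-level hierarchical AMOVA with permutation tests for the
    Phi-statistics, and infers maximum-likelihood phylogenies under the
    HKY85 substitution model with neighbor-joining starting trees and NNI
    hill climbing. A synthetic survey generator reproduces the study design
    with ground-truth labels so the whole pipeline runs and is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
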