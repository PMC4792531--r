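Package: genetreekit
Title: Gene-Tree Merging, Reconciliation and Gene-Family Evolution for ncRNA Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for species-tree-aware analysis of non-coding RNA gene
    families: reading and writing annotated gene trees (Newick/NHX), LCA
    reconciliation with duplication and loss inference, duplication-loss
    parsimony rooting, duplication confidence scores, consensus merging of
    multiple candidate gene trees (speciation-first, then minimal losses,
    then bootstrap), orthologue/paralogue classification with synteny-based
    quality control, K tree-score ranking of candidate trees, supertree
    handling of large families, and birth-death estimation of gene gain and
    loss rates on an ultrametric species tree. Includes simulators for gene
    trees under duplication-loss, perturbed candidate trees, birth-death
    family-size profiles and synteny fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools,
    optparse
Config/testthat/edition: 3
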