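Package: m6APhylo
Title: Evolutionary Tracing of the RNA N6-Methyladenosine Modification
    Machinery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the evolutionary history of gene
    families such as the RNA N6-methyladenosine (m6A) writer, reader and
    eraser proteins across the three domains of life. The package
    screens candidate homologues with local alignment and Karlin-Altschul
    E-values, removes redundancy by greedy identity clustering, filters
    by required catalytic motifs, aligns and trims families with an
    explicit column-retention rule, infers neighbor-joining gene trees
    with nonparametric bootstrap support, reconciles gene trees against a
    rooted species tree to label duplications, orthologues, paralogues
    and xenologues (horizontal transfers), infers gene gains and
    lineage-specific losses by Dollo parsimony, classifies
    methyltransferase catalytic motifs, and compares protein structures
    by optimal (Kabsch) superposition with iterative outlier rejection.
    A synthetic-evolution simulator generates gene families with known
    duplication/loss/transfer histories so every inference stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, SequenceMatching, StructuralPrediction
RoxygenNote: 7.3.3
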