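Package: structEC
Title: Structure-Based Enzyme Function Annotation from Alignment Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates predicted protein structural models with Enzyme
    Commission (EC) numbers from ensembles of structural-alignment hits
    against an annotated experimental-structure library. Models are first
    gated on AlphaFold confidence scores (pTM, mean pLDDT), then matched
    against library chains via TM-score-ranked structural alignments.
    Enzyme/non-enzyme classification uses the Kullback-Leibler divergence
    of the hit-set EC distribution against the library background, with a
    Monte-Carlo significance test; a strict-majority consensus rule assigns
    a full EC number or hierarchical prefix. Residue-level active-site and
    binding-site evidence from UniProt feature annotations is transferred
    onto model residues through the alignment correspondences, yielding
    per-residue feature and conservation counts. Includes parsers for
    UniProtKB flat files and US-align output, a toy-scale superposition and
    TM-score engine, and a deterministic synthetic-fixture generator so the
    whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralPrediction, FunctionalPrediction, Proteomics,
    Annotation, Software
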