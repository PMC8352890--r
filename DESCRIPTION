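Package: imcorr
Title: Correlative Intima-Media Gene Expression Analysis for Flow-Induced
    Vascular Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate intima-to-media signaling genes
    from paired-compartment RNA-seq of arteries exposed to different wall
    shear stress (WSS). Implements RPKM normalization, tissue-purity quality
    control for laser-microdissected intima and media, negative-binomial
    differential expression with an exact-style conditional test, an
    all-pairs Pearson correlation screen between intimal and medial
    differentially expressed genes, extracellular-product candidate
    selection, hypergeometric gene-ontology over-representation with
    occurrence pooling and semantic-similarity term reduction, and
    WSS dose-response shape classification. A synthetic-data generator
    plants signal genes, coupled medial responders, and tissue
    cross-contamination with serialized ground truth so that every stage
    can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
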