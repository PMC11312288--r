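Package: microsig
Title: Microglial Expression Signature Comparison and Validation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparing transcriptomic signatures of
    microglial populations across studies. Implements two-group differential
    expression with FDR/fold-change filtering, pre-ranked permutation
    gene-set enrichment, Euclidean-distance and absolute-cosine
    cross-correlation matrices over population signature vectors with
    classical multidimensional scaling and average-linkage clustering, and
    comparative-Ct (delta-delta-Ct) qPCR quantification. Ships a seeded
    synthetic-data generator emulating a two-condition microarray study with
    planted effects, block-correlated signature collections, and qPCR plates,
    plus plain-text readers/writers and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
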