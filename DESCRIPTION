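Package: crfref
Title: Ranking Biomedical References for Gene-Disease Curation by
    Conclusiveness, Richness, and Focus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks biomedical abstracts by how conclusively,
    richly, and focusedly they treat a given gene-disease pair, to triage
    candidate references for curators of gene-disease association
    databases. Provides dictionary-based gene/disease mention matching
    against alias thesauri, thirteen conclusiveness/richness/focus
    factors, classic retrieval baselines (Okapi BM25, a tf-idf vector
    space scorer, a proximity-boosted BM25, and position-and-frequency
    flags), a pairwise linear ranking SVM for integrating factors, a
    mean-average-precision and precision-at-X evaluation harness with
    k-fold cross-validation and dual significance testing, and a
    synthetic corpus generator with planted relevance structure for
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
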