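Package: lsitf
Title: Transcription Factor Ranking from Biomedical Literature by Latent
    Semantic Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies and ranks candidate regulatory transcription factors
    for a set of differentially expressed genes by mining per-gene collections
    of curated PubMed abstracts. Gene documents are parsed into a sparse
    term-by-gene matrix, weighted with either term-frequency (tf-normal) or
    log-entropy schemes, and factored by truncated singular value
    decomposition so that gene-gene literature association is the cosine
    between low-rank gene vectors. Each transcription factor receives a
    literature-enrichment p-value from a right-tailed one-sample t-test of
    its associations with the query gene set against its mean association
    with the whole gene population. Includes a shared-PMID co-occurrence
    baseline, Welch-test selection of differentially expressed genes,
    tie-aware ROC/AUC evaluation against gold-standard factor sets, and a
    synthetic corpus generator with planted explicit and implicit
    associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
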