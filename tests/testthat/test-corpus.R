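test_that("PMID specificity filter removes promiscuous citations strictly above the threshold", {
  # one PMID cited by 11 genes, one by exactly 10, plus gene-specific PMIDs
  genes <- sprintf("g%02d", 1:11)
  mapping <- lapply(seq_along(genes), function(i) {
    p <- c("shared11", paste0("own", i))
    if (i <= 10) p <- c(p, "shared10")
    p
  })
  names(mapping) <- genes

  out <- filter_pmids(mapping, max_genes_per_pmid = 10)
  expect_false(any(vapply(out, function(p) "shared11" %in% p, logical(1))))
  expect_equal(sum(vapply(out, function(p) "shared10" %in% p, logical(1))), 10)
  expect_true(all(vapply(seq_along(genes), function(i) {
    paste0("own", i) %in% out[[genes[i]]]
  }, logical(1))))
})

test_that("genes emptied by the PMID filter are dropped and the filter is idempotent", {
  mapping <- c(list(lonely = "shared"),
               setNames(lapply(1:11, function(i) c("shared", paste0("p", i))),
                        paste0("g", 1:11)))
  out <- filter_pmids(mapping, 10)
  expect_false("lonely" %in% names(out))
  expect_identical(filter_pmids(out, 10), out)

  expect_error(filter_pmids(list()), "no corpus")
})

test_that("gene documents concatenate retained abstracts in mapping order", {
  abstracts <- data.frame(pmid = c("p1", "p2", "p3"),
                          title = c("alpha", "beta", "gamma"),
                          abstract = c("", "", "delta"))
  docs <- build_gene_documents(list(gA = c("p1", "p2"), gB = "p3",
                                    gC = c("p2", "p1")),
                               abstracts)
  txt <- setNames(vapply(docs, `[[`, character(1), "text"),
                  vapply(docs, `[[`, character(1), "gene_id"))
  expect_equal(txt[["gA"]], "alpha beta")
  expect_equal(txt[["gB"]], "gamma delta")   # single abstract: that text
  expect_equal(txt[["gC"]], "beta alpha")    # input order preserved
})

test_that("two genes sharing a retained PMID both contain its text", {
  abstracts <- c(p1 = "shared words", p2 = "unique words")
  docs <- build_gene_documents(list(gA = c("p1", "p2"), gB = "p1"), abstracts)
  expect_match(docs[[1]]$text, "shared words")
  expect_match(docs[[2]]$text, "shared words")
})

test_that("a PMID missing from the abstracts is an error naming it, or skipped on request", {
  abstracts <- c(p1 = "alpha")
  expect_error(build_gene_documents(list(gA = c("p1", "p999")), abstracts),
               "p999")
  docs <- build_gene_documents(list(gA = c("p1", "p999")), abstracts,
                               missing_pmid = "skip")
  expect_equal(docs[[1]]$text, "alpha")
})

test_that("tokenizer lowercases, keeps hyphens/underscores, splits on punctuation", {
  expect_equal(tokenize("NF-kappaB binds DNA."),
               c(binds = 1L, dna = 1L, "nf-kappab" = 1L)[
                 sort(c("binds", "dna", "nf-kappab"))])
  expect_equal(tokenize("the THE the", stoplist = "the"), integer(0))
  expect_equal(tokenize("Stat5a/b signaling; signaling"),
               c(b = 1L, signaling = 2L, stat5a = 1L))
  # leading/trailing hyphens stripped; numeric tokens and underscores kept
  expect_equal(tokenize("-like p53 gene_x"),
               c(gene_x = 1L, like = 1L, p53 = 1L))
  expect_equal(tokenize(""), integer(0))
})

test_that("term-by-gene matrix counts tokens per document", {
  m <- build_term_gene_matrix(make_docs(c("a b", "b c")))
  expect_equal(dim(m$counts), c(3L, 2L))
  expect_equal(unname(Matrix::colSums(m$counts)), c(2, 2))
  expect_equal(m$terms, c("a", "b", "c"))
  expect_equal(as.numeric(m$counts["b", ]), c(1, 1))
})

test_that("all-stoplist documents are dropped with a warning; all-empty corpus errors", {
  docs <- make_docs(c("real words here", "the the the"))
  expect_warning(m <- build_term_gene_matrix(docs, stoplist = "the"),
                 "dropping 1 gene")
  expect_equal(m$gene_ids, "g01")
  expect_error(
    suppressWarnings(build_term_gene_matrix(make_docs("the the"),
                                            stoplist = "the")),
    "empty bag of words")
})

test_that("matrix construction matches an independent naive recount on a synthetic corpus", {
  corpus <- generate_corpus(small_spec(seed = 42))
  stoplist <- read_stoplist()
  docs <- build_gene_documents(filter_pmids(corpus$gene_to_pmids),
                               corpus$abstracts)
  m <- build_term_gene_matrix(docs, stoplist)
  expect_gte(length(m$gene_ids), 50)

  for (j in seq_along(docs)) {
    expected <- naive_counts(docs[[j]]$text, stoplist)
    col <- m$counts[, docs[[j]]$gene_id]
    col <- col[col > 0]
    expect_equal(as.integer(col[names(expected)]), unname(expected),
                 info = docs[[j]]$gene_id)
    # column sum equals the document's retained token total
    expect_equal(sum(col), sum(expected))
  }
  # vocabulary hygiene
  expect_false(any(m$terms %in% stoplist))
  expect_false(any(m$terms == ""))
  expect_false(anyDuplicated(m$terms) > 0)
})
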