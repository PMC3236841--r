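# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Wrap raw texts into gene_document objects (bypassing abstract assembly).
make_docs <- function(texts, genes = sprintf("g%02d", seq_along(texts))) {
  Map(function(g, txt) {
    structure(list(gene_id = g, pmids = paste0("p_", g), text = txt),
              class = "gene_document")
  }, genes, texts)
}

# Build a term_gene_matrix whose counts equal `counts` exactly, by routing
# synthetic documents through the real constructor. Terms must sort in row
# order and counts must have no all-zero row or column.
make_tgm <- function(counts,
                     terms = sprintf("w%02d", seq_len(nrow(counts))),
                     genes = sprintf("g%02d", seq_len(ncol(counts)))) {
  stopifnot(all(rowSums(counts) > 0), all(colSums(counts) > 0),
            !is.unsorted(terms))
  docs <- lapply(seq_len(ncol(counts)), function(j) {
    words <- rep(terms, counts[, j])
    structure(list(gene_id = genes[j], pmids = paste0("p", j),
                   text = paste(words, collapse = " ")),
              class = "gene_document")
  })
  build_term_gene_matrix(docs)
}

# Random count matrix with no all-zero row or column.
random_counts <- function(n_terms, n_genes, seed, lambda = 1.2) {
  set.seed(seed)
  repeat {
    m <- matrix(stats::rpois(n_terms * n_genes, lambda), n_terms, n_genes)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# A small synthetic corpus spec that keeps unit tests fast.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(n_genes = 50, n_tfs = 8, n_topics = 4,
                 vocab_size_per_topic = 30, shared_vocab_size = 40,
                 docs_per_gene = c(1, 3), planted_geneset_size = 10,
                 words_per_doc = c(15, 30), seed = seed, ...)
}

# Independent naive recount of token frequencies: extraction-based
# (gregexpr) rather than the package's substitution-based tokenizer.
naive_counts <- function(text, stoplist = character()) {
  x <- tolower(text)
  toks <- regmatches(x, gregexpr("[[:alnum:]_-]+", x))[[1]]
  toks <- sub("^-+", "", sub("-+$", "", toks))
  toks <- toks[toks != "" & !(toks %in% stoplist)]
  if (length(toks) == 0) return(integer(0))
  tab <- table(toks)
  structure(as.integer(tab), names = names(tab))
}

# Brute-force ordered-pair AUC (Mann-Whitney form): fraction of
# (relevant, irrelevant) pairs ranked correctly, ties (same group) half.
pair_auc <- function(ranked, gold, tie_groups = seq_along(ranked)) {
  pos <- stats::setNames(tie_groups, ranked)
  rel <- ranked[ranked %in% gold]
  irr <- setdiff(ranked, rel)
  cmp <- outer(pos[rel], pos[irr], function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}
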