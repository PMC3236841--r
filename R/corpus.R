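#' Filter non-specific PMIDs from a gene-to-PMID mapping
#'
#' Abstracts cited by many genes (large sequencing or survey papers) carry
#' little gene-specific functional information. This drops every PMID that is
#' referenced by more than `max_genes_per_pmid` genes, then drops genes whose
#' PMID set becomes empty.
#'
#' @param gene_to_pmids Named list; names are gene identifiers, elements are
#'   character vectors of PMIDs.
#' @param max_genes_per_pmid PMIDs referenced by strictly more genes than this
#'   are removed (default 10; a PMID cited by exactly 10 genes is kept).
#' @return Named list of the same shape; genes emptied by the filter are
#'   absent. The operation is idempotent.
#' @export
filter_pmids <- function(gene_to_pmids, max_genes_per_pmid = 10) {
  if (length(gene_to_pmids) == 0L) {
    stop("empty gene-to-PMID mapping: no corpus to build")
  }
  if (is.null(names(gene_to_pmids)) || anyNA(names(gene_to_pmids)) ||
      any(names(gene_to_pmids) == "")) {
    stop("gene_to_pmids must be a named list keyed by gene identifier")
  }
  stopifnot(max_genes_per_pmid >= 1)
  sets <- lapply(gene_to_pmids, function(p) unique(as.character(p)))
  counts <- table(unlist(sets, use.names = FALSE))
  promiscuous <- names(counts)[counts > max_genes_per_pmid]
  kept <- lapply(sets, function(p) p[!(p %in% promiscuous)])
  kept[lengths(kept) > 0L]
}

#' Assemble one concatenated literature document per gene
#'
#' Each gene's document is the concatenation (single-space separated, in the
#' order the PMIDs appear in the mapping) of the title-plus-abstract text of
#' its retained citations.
#'
#' @param filtered_map Named list gene_id -> character vector of PMIDs,
#'   typically the output of [filter_pmids()].
#' @param abstracts Either a data frame with columns `pmid`, `title`,
#'   `abstract`, or a named character vector mapping PMID to full text.
#' @param missing_pmid `"error"` (default) to fail on a PMID absent from
#'   `abstracts`, or `"skip"` to drop it (genes left with no text are dropped).
#' @return List of `gene_document` objects, each with fields `gene_id`,
#'   `pmids` and `text`.
#' @export
build_gene_documents <- function(filtered_map, abstracts,
                                 missing_pmid = c("error", "skip")) {
  missing_pmid <- match.arg(missing_pmid)
  if (length(filtered_map) == 0L) stop("no genes in filtered mapping")
  texts <- abstract_texts(abstracts)
  docs <- vector("list", length(filtered_map))
  keep <- logical(length(filtered_map))
  for (i in seq_along(filtered_map)) {
    gene <- names(filtered_map)[i]
    pmids <- as.character(filtered_map[[i]])
    absent <- setdiff(pmids, names(texts))
    if (length(absent) > 0L) {
      if (missing_pmid == "error") {
        stop(sprintf("gene '%s': PMID(s) %s not found in abstracts",
                     gene, paste(absent, collapse = ", ")))
      }
      pmids <- setdiff(pmids, absent)
    }
    if (length(pmids) == 0L) next
    docs[[i]] <- structure(
      list(gene_id = gene, pmids = pmids,
           text = paste(texts[pmids], collapse = " ")),
      class = "gene_document")
    keep[i] <- TRUE
  }
  docs[keep]
}

## Normalise the two accepted abstract representations to a pmid -> text map.
abstract_texts <- function(abstracts) {
  if (is.data.frame(abstracts)) {
    req <- c("pmid", "title", "abstract")
    if (!all(req %in% names(abstracts))) {
      stop("abstracts data frame needs columns pmid, title, abstract")
    }
    pm <- as.character(abstracts$pmid)
    if (anyDuplicated(pm)) stop("duplicate PMIDs in abstracts")
    txt <- trimws(paste(abstracts$title, abstracts$abstract))
    names(txt) <- pm
    txt
  } else if (is.character(abstracts) && !is.null(names(abstracts))) {
    if (anyDuplicated(names(abstracts))) stop("duplicate PMIDs in abstracts")
    abstracts
  } else {
    stop("abstracts must be a data frame (pmid, title, abstract) or a named character vector")
  }
}

#' Tokenize free text into lowercased term counts
#'
#' Case is ignored; every character that is not alphanumeric, `-` or `_` is
#' treated as a separator; leading/trailing hyphens are stripped from tokens
#' (`-like` becomes `like`); stoplist members and empty tokens are removed.
#' Purely numeric tokens are retained.
#'
#' @param text Character scalar (may be empty).
#' @param stoplist Character vector of lowercase words to discard.
#' @return Named integer vector of token counts (empty for empty text).
#' @export
tokenize <- function(text, stoplist = character()) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(integer(0))
  x <- tolower(text)
  x <- gsub("[^[:alnum:]_-]+", " ", x)
  toks <- strsplit(trimws(x), " +", fixed = FALSE)[[1L]]
  toks <- gsub("^-+|-+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (length(stoplist) > 0L) toks <- toks[!(toks %in% stoplist)]
  if (length(toks) == 0L) return(integer(0))
  tab <- table(toks)
  structure(as.integer(tab), names = names(tab))
}

#' Build the sparse raw term-by-gene count matrix
#'
#' Rows are vocabulary terms (sorted), columns are genes in document order;
#' entry (i, j) is the frequency of term i in gene-document j. Genes whose
#' documents tokenize to nothing (e.g. all-stoplist text) are dropped with a
#' warning, so the matrix has no all-zero column; the vocabulary is the union
#' of observed tokens, so it has no all-zero row.
#'
#' @param docs List of `gene_document` objects from [build_gene_documents()].
#' @param stoplist Character vector of lowercase words to discard.
#' @return A `term_gene_matrix`: list with `terms`, `gene_ids` and `counts`
#'   (a sparse [Matrix::dgCMatrix-class] with dimnames).
#' @export
build_term_gene_matrix <- function(docs, stoplist = character()) {
  if (length(docs) == 0L) stop("no gene documents supplied")
  gene_ids <- unname(vapply(docs, function(d) d$gene_id, character(1)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers in documents")
  counts <- lapply(docs, function(d) tokenize(d$text, stoplist))
  empty <- lengths(counts) == 0L
  if (all(empty)) stop("every gene document tokenized to an empty bag of words")
  if (any(empty)) {
    warning(sprintf("dropping %d gene(s) with empty documents after tokenization: %s",
                    sum(empty), paste(gene_ids[empty], collapse = ", ")))
    counts <- counts[!empty]
    gene_ids <- gene_ids[!empty]
  }
  terms <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  i <- unlist(lapply(counts, function(ct) match(names(ct), terms)),
              use.names = FALSE)
  j <- rep.int(seq_along(counts), lengths(counts))
  x <- unlist(counts, use.names = FALSE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                            dims = c(length(terms), length(gene_ids)),
                            dimnames = list(terms, gene_ids))
  structure(list(terms = terms, gene_ids = gene_ids, counts = m),
            class = "term_gene_matrix")
}

#' @export
print.term_gene_matrix <- function(x, ...) {
  cat(sprintf("term-by-gene count matrix: %d terms x %d genes, %d nonzeros\n",
              length(x$terms), length(x$gene_ids),
              length(x$counts@x)))
  invisible(x)
}
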