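#' Read a gene-to-PMID mapping (gene2pubmed dialect)
#'
#' Two tab-separated columns, `gene_id` and `pmid`, one pair per line; lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return Named list gene_id -> character vector of PMIDs, in file order.
#' @export
read_gene2pubmed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          colClasses = "character",
                          col.names = c("gene_id", "pmid"),
                          quote = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty gene-to-PMID mapping file: ", path)
  split(df$pmid, factor(df$gene_id, levels = unique(df$gene_id)))
}

#' Write a gene-to-PMID mapping
#' @param gene_to_pmids Named list gene_id -> PMIDs.
#' @param path Output file path.
#' @export
write_gene2pubmed <- function(gene_to_pmids, path) {
  df <- data.frame(
    gene_id = rep(names(gene_to_pmids), lengths(gene_to_pmids)),
    pmid = unlist(gene_to_pmids, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read abstracts (TSV: pmid, title, abstract)
#'
#' Three tab-separated columns with no header; literal tabs/newlines inside
#' text are not allowed (they are replaced by spaces on write).
#'
#' @param path File path.
#' @return Data frame with columns `pmid`, `title`, `abstract`.
#' @export
read_abstracts <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "", quote = "",
                          colClasses = "character",
                          col.names = c("pmid", "title", "abstract"),
                          stringsAsFactors = FALSE, fill = TRUE)
  if (anyDuplicated(df$pmid)) stop("duplicate PMIDs in ", path)
  df
}

#' Write abstracts as TSV
#' @param abstracts Data frame with columns `pmid`, `title`, `abstract`.
#' @param path Output file path.
#' @export
write_abstracts <- function(abstracts, path) {
  clean <- function(x) gsub("[\t\r\n]+", " ", x)
  df <- data.frame(pmid = abstracts$pmid, title = clean(abstracts$title),
                   abstract = clean(abstracts$abstract))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a stoplist (one lowercase word per line, '#' comments allowed)
#' @param path File path; default is the stoplist shipped with the package, a
#'   compact list of common English function words in the role of the classic
#'   SMART stoplist.
#' @return Character vector of words.
#' @export
read_stoplist <- function(path = system.file("extdata", "stoplist.txt",
                                             package = "lsitf")) {
  words <- readLines(path, warn = FALSE)
  words <- trimws(words)
  words <- words[nzchar(words) & !startsWith(words, "#")]
  tolower(words)
}

#' Read a list of gene identifiers (one per line, '#' comments allowed)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gold-standard TF set
#'
#' Plain text, one TF id per line; an optional header line `#label=<name>`
#' names the stimulant.
#'
#' @param path File path.
#' @return A `gold_standard`: list with `label` and `relevant_tfs`.
#' @export
read_gold_standard <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  label_line <- grep("^#label=", lines, value = TRUE)
  label <- if (length(label_line) > 0) sub("^#label=", "", label_line[1]) else NA_character_
  tfs <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(tfs) == 0L) stop("gold standard file has no TF ids: ", path)
  structure(list(label = label, relevant_tfs = unique(tfs)),
            class = "gold_standard")
}

#' Write a gold-standard TF set
#' @param gold A `gold_standard` or character vector of TF ids.
#' @param path Output path.
#' @param label Stimulant label (ignored if `gold` is a `gold_standard`).
#' @export
write_gold_standard <- function(gold, path, label = NA_character_) {
  if (inherits(gold, "gold_standard")) {
    label <- gold$label
    gold <- gold$relevant_tfs
  }
  header <- if (!is.na(label)) sprintf("#label=%s", label) else character(0)
  writeLines(c(header, gold), path)
  invisible(path)
}

#' Serialize a term-by-gene count matrix (MatrixMarket + sidecars)
#'
#' Writes `counts.mtx`, `terms.txt` and `gene_ids.txt` into `dir`.
#'
#' @param M A `term_gene_matrix`.
#' @param dir Output directory (created if needed).
#' @export
write_term_gene_matrix <- function(M, dir) {
  check_term_gene_matrix(M)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(M$counts, file.path(dir, "counts.mtx"))
  writeLines(M$terms, file.path(dir, "terms.txt"))
  writeLines(M$gene_ids, file.path(dir, "gene_ids.txt"))
  invisible(dir)
}

#' Read a term-by-gene count matrix written by [write_term_gene_matrix()]
#' @param dir Directory path.
#' @return A `term_gene_matrix`.
#' @export
read_term_gene_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  terms <- readLines(file.path(dir, "terms.txt"))
  gene_ids <- readLines(file.path(dir, "gene_ids.txt"))
  dimnames(m) <- list(terms, gene_ids)
  structure(list(terms = terms, gene_ids = gene_ids, counts = m),
            class = "term_gene_matrix")
}

#' Serialize a weighted matrix (MatrixMarket + sidecars + JSON metadata)
#'
#' Writes `weights.mtx`, `terms.txt`, `gene_ids.txt`, `global_weights.txt`
#' (one value per term) and `meta.json` (scheme) into `dir`.
#'
#' @param W A `weighted_matrix`.
#' @param dir Output directory.
#' @export
write_weighted_matrix <- function(W, dir) {
  stopifnot(inherits(W, "weighted_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(W$weights, file.path(dir, "weights.mtx"))
  writeLines(W$terms, file.path(dir, "terms.txt"))
  writeLines(W$gene_ids, file.path(dir, "gene_ids.txt"))
  writeLines(format(W$global_weights, digits = 17),
             file.path(dir, "global_weights.txt"))
  jsonlite::write_json(list(scheme = W$scheme), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a weighted matrix written by [write_weighted_matrix()]
#' @param dir Directory path.
#' @return A `weighted_matrix`.
#' @export
read_weighted_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "weights.mtx")), "CsparseMatrix")
  terms <- readLines(file.path(dir, "terms.txt"))
  gene_ids <- readLines(file.path(dir, "gene_ids.txt"))
  g <- as.numeric(readLines(file.path(dir, "global_weights.txt")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  dimnames(m) <- list(terms, gene_ids)
  structure(list(terms = terms, gene_ids = gene_ids, weights = m,
                 global_weights = stats::setNames(g, terms),
                 scheme = meta$scheme),
            class = "weighted_matrix")
}

#' Serialize an LSI model to a directory of text files
#'
#' Writes `singular_values.txt`, `gene_vectors.tsv`, `term_vectors.tsv`,
#' `gene_ids.txt`, `terms.txt` and `meta.json` (scheme, k, requested k).
#'
#' @param model An `lsi_model`.
#' @param dir Output directory.
#' @export
write_lsi_model <- function(model, dir) {
  stopifnot(inherits(model, "lsi_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(format(model$singular_values, digits = 17),
             file.path(dir, "singular_values.txt"))
  utils::write.table(model$gene_vectors, file.path(dir, "gene_vectors.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  utils::write.table(model$term_vectors, file.path(dir, "term_vectors.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  writeLines(model$gene_ids, file.path(dir, "gene_ids.txt"))
  writeLines(model$terms, file.path(dir, "terms.txt"))
  jsonlite::write_json(list(scheme = model$scheme, k = model$k,
                            requested_k = model$requested_k),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an LSI model written by [write_lsi_model()]
#' @param dir Directory path.
#' @return An `lsi_model`.
#' @export
read_lsi_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  read_vecs <- function(file, ids) {
    m <- as.matrix(utils::read.table(file, sep = "\t", row.names = 1,
                                     colClasses = c("character", rep("numeric", meta$k))))
    colnames(m) <- NULL
    m[ids, , drop = FALSE]
  }
  gene_ids <- readLines(file.path(dir, "gene_ids.txt"))
  terms <- readLines(file.path(dir, "terms.txt"))
  structure(list(
    k = as.integer(meta$k), requested_k = as.integer(meta$requested_k),
    singular_values = as.numeric(readLines(file.path(dir, "singular_values.txt"))),
    gene_vectors = read_vecs(file.path(dir, "gene_vectors.tsv"), gene_ids),
    term_vectors = read_vecs(file.path(dir, "term_vectors.tsv"), terms),
    gene_ids = gene_ids, terms = terms, scheme = meta$scheme),
    class = "lsi_model")
}

#' Write a ranked TF enrichment table as TSV
#' @param ranked Ranked data frame from [rank_tfs()] / [enrich_tfs()].
#' @param path Output path.
#' @export
write_enrichment <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ROC curve (TSV of vertices + JSON summary)
#' @param roc A `roc_curve`.
#' @param path Output TSV path; the JSON summary goes to `<path>.json`.
#' @param model Model name recorded in the summary.
#' @export
write_roc <- function(roc, path, model = "model") {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(model = model, auc = roc$auc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
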