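#' Shared-PMID co-occurrence association model
#'
#' Benchmark association model: the score between two genes is the number of
#' curated PMIDs their abstract sets share. The same specificity filter used
#' for corpus construction (PMIDs cited by more than `max_genes_per_pmid`
#' genes removed) is applied before scoring.
#'
#' @param gene_to_pmids Named list gene_id -> character vector of PMIDs.
#' @param max_genes_per_pmid Passed to [filter_pmids()]; use `Inf` to skip
#'   filtering.
#' @return A `cooccurrence_model` holding the filtered mapping.
#' @export
cooccurrence_model <- function(gene_to_pmids, max_genes_per_pmid = 10) {
  filtered <- if (is.finite(max_genes_per_pmid)) {
    filter_pmids(gene_to_pmids, max_genes_per_pmid)
  } else {
    lapply(gene_to_pmids, function(p) unique(as.character(p)))
  }
  if (length(filtered) == 0L) stop("no genes survive the PMID filter")
  structure(list(gene_to_pmids = filtered,
                 gene_ids = names(filtered)),
            class = "cooccurrence_model")
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat(sprintf("co-occurrence model: %d genes, %d distinct PMIDs\n",
              length(x$gene_ids),
              length(unique(unlist(x$gene_to_pmids, use.names = FALSE)))))
  invisible(x)
}

#' Number of PMIDs shared by two genes
#'
#' @param model A `cooccurrence_model`.
#' @param gene_a,gene_b Gene identifiers present in the model.
#' @return Non-negative integer; symmetric, and equal to the size of the
#'   gene's own PMID set when `gene_a == gene_b`.
#' @export
cooccurrence_score <- function(model, gene_a, gene_b) {
  check_genes_known(model$gene_ids, c(gene_a, gene_b))
  length(intersect(model$gene_to_pmids[[gene_a]],
                   model$gene_to_pmids[[gene_b]]))
}

#' @export
association_profile.cooccurrence_model <- function(model, query_gene, targets) {
  check_genes_known(model$gene_ids, c(query_gene, targets))
  q <- model$gene_to_pmids[[query_gene]]
  scores <- vapply(targets,
                   function(t) length(intersect(q, model$gene_to_pmids[[t]])),
                   numeric(1))
  stats::setNames(as.numeric(scores), targets)
}
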