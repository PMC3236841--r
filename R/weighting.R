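#' Term-frequency (tf-normal) weighting
#'
#' Local weight is the raw frequency, global weight is 1; every column is then
#' scaled to unit Euclidean norm. Emphasises explicit (directly shared term)
#' associations between gene documents.
#'
#' @param M A `term_gene_matrix` from [build_term_gene_matrix()].
#' @return A `weighted_matrix`: list with `terms`, `gene_ids`, `weights`
#'   (sparse, unit-norm columns), `global_weights` and `scheme = "tf-normal"`.
#' @export
weight_tf_normal <- function(M) {
  check_term_gene_matrix(M)
  g <- rep(1, length(M$terms))
  names(g) <- M$terms
  new_weighted_matrix(M, normalize_columns(M$counts), g, "tf-normal")
}

#' Log-entropy weighting
#'
#' Local weight `l_ij = log(1 + f_ij)`; global weight
#' `g_i = 1 + sum_j p_ij log(p_ij) / log(n)` with `p_ij = f_ij / sum_j f_ij`
#' the term's distribution over the n gene documents (0 log 0 taken as 0).
#' `g_i` is 1 for a term confined to a single document and 0 for a term spread
#' uniformly over all documents, so common terms are discounted and
#' document-discriminating terms promoted — the property that lets truncated
#' SVD surface implicit associations. Columns of `g_i * l_ij` are scaled to
#' unit Euclidean norm.
#'
#' @inheritParams weight_tf_normal
#' @return A `weighted_matrix` with `scheme = "log-entropy"` and the per-term
#'   `global_weights` in `[0, 1]`.
#' @export
weight_log_entropy <- function(M) {
  check_term_gene_matrix(M)
  n <- length(M$gene_ids)
  if (n < 2L) stop("log-entropy weighting needs at least 2 gene documents")
  f <- M$counts
  row_tot <- Matrix::rowSums(f)
  ft <- as(f, "TsparseMatrix")
  p <- ft@x / row_tot[ft@i + 1L]
  plogp <- p * log(p)                     # p > 0 on the support; 0 log 0 absent
  ent <- rep(0, nrow(f))
  agg <- tapply(plogp, ft@i, sum)
  ent[as.integer(names(agg)) + 1L] <- agg
  g <- 1 + ent / log(n)
  names(g) <- M$terms
  l <- f
  l@x <- log1p(l@x)
  w <- Matrix::Diagonal(x = g) %*% l
  new_weighted_matrix(M, normalize_columns(w), g, "log-entropy")
}

normalize_columns <- function(m) {
  norms <- sqrt(Matrix::colSums(m^2))
  if (any(norms == 0)) {
    stop("cannot normalize: column(s) with zero norm: ",
         paste(colnames(m)[norms == 0], collapse = ", "))
  }
  m %*% Matrix::Diagonal(x = 1 / norms)
}

new_weighted_matrix <- function(M, w, g, scheme) {
  w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  dimnames(w) <- list(M$terms, M$gene_ids)
  structure(list(terms = M$terms, gene_ids = M$gene_ids, weights = w,
                 global_weights = g, scheme = scheme),
            class = "weighted_matrix")
}

check_term_gene_matrix <- function(M) {
  if (!inherits(M, "term_gene_matrix")) {
    stop("expected a term_gene_matrix (see build_term_gene_matrix)")
  }
  invisible(M)
}

#' @export
print.weighted_matrix <- function(x, ...) {
  cat(sprintf("%s weighted matrix: %d terms x %d genes (unit-norm columns)\n",
              x$scheme, length(x$terms), length(x$gene_ids)))
  invisible(x)
}
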