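#' Fit a truncated-SVD latent semantic model of a weighted term-by-gene matrix
#'
#' Computes the singular value decomposition of the weighted matrix and keeps
#' the top `k` triplets. Genes are represented by the rows of `V_k diag(S_k)`
#' (document coordinates scaled by singular values), the representation used
#' for cosine association queries. If `k` exceeds the effective rank it is
#' clamped with a warning and the effective rank recorded.
#'
#' The decomposition is computed densely by LAPACK, so results are exact and
#' deterministic; this is intended for corpora up to a few thousand genes.
#' Sign ambiguity is resolved by forcing the largest-magnitude component of
#' each left singular vector to be non-negative (cosines are unaffected).
#'
#' @param W A `weighted_matrix` from [weight_tf_normal()] or
#'   [weight_log_entropy()].
#' @param k Number of latent dimensions to retain (default 500, the rank used
#'   for genome-scale corpora; clamped on small ones).
#' @return An `lsi_model`: list with `k` (effective), `requested_k`,
#'   `singular_values`, `gene_vectors` (genes x k), `term_vectors`
#'   (terms x k), `gene_ids`, `terms`, `scheme`.
#' @export
fit_lsi <- function(W, k = 500) {
  if (!inherits(W, "weighted_matrix")) stop("expected a weighted_matrix")
  stopifnot(length(k) == 1L, k >= 1)
  a <- as.matrix(W$weights)
  sv <- svd(a)
  tol <- max(dim(a)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  if (r == 0L) stop("weighted matrix has zero effective rank")
  k_eff <- as.integer(min(k, r))
  if (k_eff < k) {
    warning(sprintf("k = %d exceeds effective rank %d; clamped to %d",
                    k, r, k_eff))
  }
  u <- sv$u[, seq_len(k_eff), drop = FALSE]
  v <- sv$v[, seq_len(k_eff), drop = FALSE]
  d <- sv$d[seq_len(k_eff)]
  # sign convention: largest-|.| component of each left singular vector >= 0
  for (j in seq_len(k_eff)) {
    pivot <- which.max(abs(u[, j]))
    if (u[pivot, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  gene_vectors <- sweep(v, 2L, d, `*`)
  rownames(gene_vectors) <- W$gene_ids
  rownames(u) <- W$terms
  structure(list(k = k_eff, requested_k = as.integer(k),
                 singular_values = d, gene_vectors = gene_vectors,
                 term_vectors = u, gene_ids = W$gene_ids, terms = W$terms,
                 scheme = W$scheme),
            class = "lsi_model")
}

#' @export
print.lsi_model <- function(x, ...) {
  cat(sprintf("LSI model (%s weighting): %d genes, %d terms, rank k = %d\n",
              x$scheme, length(x$gene_ids), length(x$terms), x$k))
  invisible(x)
}

#' Cosine literature association between two genes
#'
#' The association is the cosine of the angle between the two genes' latent
#' vectors, clamped to `[-1, 1]` against rounding. A gene whose latent vector
#' is numerically zero gets association 0 (with a warning).
#'
#' @param model An `lsi_model`.
#' @param gene_a,gene_b Gene identifiers present in the model.
#' @return Numeric scalar in `[-1, 1]`; symmetric in its arguments, and 1 for
#'   `gene_a == gene_b` when the gene's vector is nonzero.
#' @export
cosine <- function(model, gene_a, gene_b) {
  as.numeric(association_profile(model, gene_a, gene_b))
}

#' Association scores of one gene against a set of target genes
#'
#' Generic batch form of the pairwise association score: for an `lsi_model`
#' the cosine between latent gene vectors; for a `cooccurrence_model` the
#' number of shared PMIDs.
#'
#' @param model An `lsi_model` or `cooccurrence_model`.
#' @param query_gene Gene identifier.
#' @param targets Character vector of gene identifiers (may be empty).
#' @return Named numeric vector of scores in target order.
#' @export
association_profile <- function(model, query_gene, targets) {
  UseMethod("association_profile")
}

#' @export
association_profile.lsi_model <- function(model, query_gene, targets) {
  check_genes_known(model$gene_ids, c(query_gene, targets))
  if (length(targets) == 0L) return(stats::setNames(numeric(0), character(0)))
  q <- model$gene_vectors[query_gene, ]
  m <- model$gene_vectors[targets, , drop = FALSE]
  qn <- sqrt(sum(q^2))
  tn <- sqrt(rowSums(m^2))
  zero <- c(qn, tn) == 0
  if (any(zero)) {
    warning("zero latent vector(s) encountered; their cosines are reported as 0")
  }
  denom <- qn * tn
  scores <- as.numeric(m %*% q)
  scores <- ifelse(denom == 0, 0, scores / ifelse(denom == 0, 1, denom))
  scores <- pmin(1, pmax(-1, scores))
  stats::setNames(scores, targets)
}

check_genes_known <- function(known, ids) {
  unknown <- setdiff(unique(ids), known)
  if (length(unknown) > 0L) {
    stop("unknown gene identifier(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
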