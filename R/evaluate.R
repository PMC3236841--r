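#' Construct an expression table with two condition groups
#'
#' @param values Numeric matrix, genes x samples.
#' @param groups Factor (or coercible) of length `ncol(values)` with exactly
#'   two levels; the FIRST level is the control/reference group, the second
#'   the treated group. Each group needs at least 2 samples.
#' @param gene_ids Gene identifiers (default: rownames of `values`).
#' @return An `expression_table`.
#' @export
expression_table <- function(values, groups, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) stop("gene_ids required (or rownames on values)")
  if (anyNA(gene_ids) || anyDuplicated(gene_ids)) {
    stop("gene_ids must be complete and unique")
  }
  stopifnot(length(gene_ids) == nrow(values))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(values)) {
    stop("groups must be a two-level factor, one label per sample column")
  }
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  rownames(values) <- gene_ids
  structure(list(values = values, groups = groups, gene_ids = gene_ids),
            class = "expression_table")
}

#' Select differentially expressed genes (Welch t-test + fold change)
#'
#' A gene is selected when its Welch two-sample t-test p-value is below
#' `alpha` and its fold change exceeds `fold_threshold` strictly, in either
#' direction (fold change = `max(r, 1/r)` with `r` the ratio of linear-scale
#' group means, treated over control). Genes with a non-positive control mean
#' are excluded with a warning since the ratio is undefined. Genes with zero
#' variance in both groups get p = 1 when the group means are equal and p = 0
#' otherwise.
#'
#' @param expr An `expression_table`; the first group level is control.
#' @param fold_threshold Strict fold-change threshold (default 2).
#' @param alpha Welch-test significance level (default 0.05).
#' @return Character vector of selected gene ids, with the full per-gene
#'   statistics data frame attached as attribute `"stats"`.
#' @export
select_degs <- function(expr, fold_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_table"),
            fold_threshold >= 1, alpha > 0, alpha <= 1)
  ctrl <- expr$values[, expr$groups == levels(expr$groups)[1L], drop = FALSE]
  trt <- expr$values[, expr$groups == levels(expr$groups)[2L], drop = FALSE]
  mean_c <- rowMeans(ctrl)
  mean_t <- rowMeans(trt)
  pvals <- vapply(seq_len(nrow(expr$values)), function(i) {
    welch_p(trt[i, ], ctrl[i, ])
  }, numeric(1))
  ratio <- mean_t / mean_c
  fold <- pmax(ratio, 1 / ratio)
  usable <- mean_c > 0
  if (!all(usable)) {
    warning(sprintf("excluding %d gene(s) with non-positive control mean",
                    sum(!usable)))
  }
  selected <- usable & pvals < alpha & fold > fold_threshold
  stats <- data.frame(gene_id = expr$gene_ids, mean_control = mean_c,
                      mean_treated = mean_t, ratio = ratio, fold = fold,
                      p_value = pvals, selected = selected,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(expr$gene_ids[selected], stats = stats)
}

## Welch p-value with a guard for zero-variance groups, where t.test() fails.
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' ROC curve of a TF ranking against a gold standard
#'
#' Sweeps a rank cutoff over the ranking: at each cutoff the true-positive
#' rate is the fraction of gold-standard TFs ranked at or above it, and the
#' false-positive rate the fraction of non-gold TFs. Within a tie group the
#' internal order is arbitrary, so the cutoff may only fall at group
#' boundaries (one ROC vertex per tie group); the trapezoidal area then scores
#' tied (gold, non-gold) pairs as half-correct, keeping the AUC equal to the
#' tie-aware Mann-Whitney pair statistic.
#'
#' @param ranked_tfs Either a character vector of TF ids ordered best-first,
#'   or a ranked data frame from [rank_tfs()] (whose `tie_group` column is
#'   then used).
#' @param gold Character vector of relevant TF ids; must be a non-empty
#'   proper subset of the ranking. A `gold_standard` object (see
#'   [read_gold_standard()]) is also accepted.
#' @param tie_groups Optional non-decreasing integer vector, one entry per
#'   ranked TF; defaults to one group per TF (no ties).
#' @return A `roc_curve`: list with `points` (data frame `cutoff`, `fpr`,
#'   `tpr` from (0,0) to (1,1)), `auc`, `n_relevant`, `n_total`.
#' @export
roc_curve <- function(ranked_tfs, gold, tie_groups = NULL) {
  if (is.data.frame(ranked_tfs)) {
    if (is.null(tie_groups) && "tie_group" %in% names(ranked_tfs)) {
      tie_groups <- ranked_tfs$tie_group
    }
    ranked_tfs <- ranked_tfs$tf_id
  }
  if (inherits(gold, "gold_standard")) gold <- gold$relevant_tfs
  gold <- unique(as.character(gold))
  n <- length(ranked_tfs)
  if (anyDuplicated(ranked_tfs)) stop("ranked list contains duplicates")
  absent <- setdiff(gold, ranked_tfs)
  if (length(absent) > 0L) {
    stop("gold-standard TF(s) absent from the ranking: ",
         paste(absent, collapse = ", "))
  }
  n_rel <- length(gold)
  if (n_rel == 0L || n_rel == n) {
    stop("gold standard must be a non-empty proper subset of the ranking")
  }
  if (is.null(tie_groups)) tie_groups <- seq_len(n)
  stopifnot(length(tie_groups) == n, !is.unsorted(tie_groups))
  rel <- ranked_tfs %in% gold
  ends <- cumsum(rle(as.integer(tie_groups))$lengths)
  tp <- cumsum(rel)[ends]
  fp <- (ends - tp)
  tpr <- c(0, tp / n_rel)
  fpr <- c(0, fp / (n - n_rel))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(cutoff = c(0L, ends), fpr = fpr, tpr = tpr),
                 auc = auc, n_relevant = n_rel, n_total = n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d ranked items, %d relevant, AUC = %.4f\n",
              x$n_total, x$n_relevant, x$auc))
  invisible(x)
}

#' Compare several TF rankings against one gold standard
#'
#' @param rankings Named list; each element a ranking accepted by
#'   [roc_curve()] (character vector or ranked data frame).
#' @param gold As in [roc_curve()].
#' @return A `model_evaluation`: list with `curves` (named list of
#'   `roc_curve`) and `auc_table` (data frame `model`, `auc`).
#' @export
evaluate_models <- function(rankings, gold) {
  stopifnot(is.list(rankings), length(rankings) > 0L,
            !is.null(names(rankings)), all(nzchar(names(rankings))))
  curves <- lapply(rankings, roc_curve, gold = gold)
  structure(list(curves = curves,
                 auc_table = data.frame(
                   model = names(curves),
                   auc = vapply(curves, `[[`, numeric(1), "auc"),
                   row.names = NULL, stringsAsFactors = FALSE)),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("model comparison (AUC against gold standard):\n")
  print(x$auc_table, row.names = FALSE)
  invisible(x)
}
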