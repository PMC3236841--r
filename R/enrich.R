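#' Assemble the observed and population association samples for one TF
#'
#' For a transcription factor `tf_id`, collects its association scores with
#' every gene in the query set (`t_G`) and with every gene in the population
#' except itself (`t_P`; the TF's self-association is excluded). If the TF is
#' itself a member of the query set it is removed from `t_G` by default, for
#' the same reason its self-association is excluded from `t_P`.
#'
#' @param model An `lsi_model` or `cooccurrence_model`.
#' @param tf_id Transcription factor identifier (must be in `population`).
#' @param query_genes Character vector of query (e.g. differentially
#'   expressed) gene identifiers; at least 2 after any self-removal.
#' @param population Character vector of all gene identifiers forming the
#'   reference population (includes the TFs).
#' @param remove_self_from_query Drop `tf_id` from the query set if present
#'   (default TRUE).
#' @return An `association_sample`: list with `tf_id`, `t_G`, `t_P`, `mu`
#'   (mean of `t_P`), `s` (sample sd of `t_G`), `n_G`, `N`.
#' @export
build_association_sample <- function(model, tf_id, query_genes, population,
                                     remove_self_from_query = TRUE) {
  stopifnot(length(tf_id) == 1L)
  if (!(tf_id %in% population)) {
    stop(sprintf("TF '%s' is not in the population gene set", tf_id))
  }
  qg <- unique(as.character(query_genes))
  if (remove_self_from_query) qg <- setdiff(qg, tf_id)
  if (length(qg) < 2L) {
    stop(sprintf("query set for TF '%s' has %d gene(s) after self-removal; need >= 2 for the t-test",
                 tf_id, length(qg)))
  }
  pop <- setdiff(unique(as.character(population)), tf_id)
  t_G <- association_profile(model, tf_id, qg)
  t_P <- association_profile(model, tf_id, pop)
  structure(list(tf_id = tf_id, t_G = t_G, t_P = t_P,
                 mu = mean(t_P), s = stats::sd(t_G),
                 n_G = length(qg), N = length(pop) + 1L),
            class = "association_sample")
}

#' Literature-enrichment p-value for one TF
#'
#' Right-tailed one-sample Student's t-test of the TF's query-set association
#' scores against its population mean association `mu`:
#' `t = (mean(t_G) - mu) / (s / sqrt(n_G))` with `n_G - 1` degrees of freedom;
#' the p-value is the upper-tail probability. When the observed scores have
#' zero variance (`s = 0`) the p-value is 1 if `mean(t_G) <= mu` — this is how
#' TFs sharing no PMID with any query gene come out of the co-occurrence
#' baseline — and the smallest representable positive value if
#' `mean(t_G) > mu`.
#'
#' @param sample An `association_sample` from [build_association_sample()].
#' @param alpha Significance level used only to set the `significant` flag
#'   (default 0.05); ranking never thresholds on it.
#' @return One-row data frame: `tf_id`, `n_G`, `mean_observed`,
#'   `population_mean`, `t_stat`, `p_value`, `significant`.
#' @export
enrichment_pvalue <- function(sample, alpha = 0.05) {
  stopifnot(inherits(sample, "association_sample"), alpha > 0, alpha < 1)
  m <- mean(sample$t_G)
  if (sample$s == 0) {
    # zero-variance observed sample: below the population mean (e.g. all-zero
    # co-occurrence scores against a positive population mean) gives p = 1,
    # above it the smallest positive value, exactly at it the symmetric-null
    # limit 0.5
    t_stat <- if (m > sample$mu) Inf else if (m < sample$mu) -Inf else 0
    p <- if (m > sample$mu) .Machine$double.xmin else if (m < sample$mu) 1 else 0.5
  } else {
    t_stat <- (m - sample$mu) / (sample$s / sqrt(sample$n_G))
    p <- stats::pt(t_stat, df = sample$n_G - 1L, lower.tail = FALSE)
    if (p == 0) p <- .Machine$double.xmin   # keep p in (0, 1]
  }
  data.frame(tf_id = sample$tf_id, n_G = sample$n_G, mean_observed = m,
             population_mean = sample$mu, t_stat = t_stat, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Enrichment p-values and ranking for a set of TFs
#'
#' Convenience wrapper: builds the association sample and p-value for every
#' TF, then ranks.
#'
#' @inheritParams build_association_sample
#' @param tf_ids Character vector of TF identifiers (the TF universe).
#' @param alpha Significance level for the `significant` flag.
#' @return Ranked data frame as returned by [rank_tfs()].
#' @export
enrich_tfs <- function(model, tf_ids, query_genes, population,
                       alpha = 0.05, remove_self_from_query = TRUE) {
  stopifnot(length(tf_ids) > 0L)
  rows <- lapply(tf_ids, function(tf) {
    s <- build_association_sample(model, tf, query_genes, population,
                                  remove_self_from_query = remove_self_from_query)
    enrichment_pvalue(s, alpha = alpha)
  })
  rank_tfs(do.call(rbind, rows))
}

#' Rank TFs by enrichment p-value
#'
#' Sorts ascending by p-value, breaking ties by descending mean observed
#' association and then lexicographically by TF identifier. Rows tied on both
#' p-value and mean observed association (where the final order is arbitrary)
#' share a `tie_group` id so reports and ROC curves can treat them as a block.
#'
#' @param results Data frame with columns `tf_id`, `p_value`, `mean_observed`
#'   (one row per TF), e.g. rbind-ed output of [enrichment_pvalue()].
#' @return The same data frame sorted, with columns `rank` (1..nrow) and
#'   `tie_group` (non-decreasing integer) appended.
#' @export
rank_tfs <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("tf_id", "p_value", "mean_observed") %in% names(results)))
  if (anyDuplicated(results$tf_id)) {
    stop("duplicate tf_id in results: ",
         paste(unique(results$tf_id[duplicated(results$tf_id)]), collapse = ", "))
  }
  ord <- order(results$p_value, -results$mean_observed, results$tf_id)
  out <- results[ord, , drop = FALSE]
  new_block <- c(TRUE, diff(out$p_value) != 0 | diff(out$mean_observed) != 0)
  out$rank <- seq_len(nrow(out))
  out$tie_group <- cumsum(new_block)
  rownames(out) <- NULL
  out
}
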