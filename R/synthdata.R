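#' Specification of a synthetic literature corpus
#'
#' Describes a topic-structured bag-of-words corpus with a planted query gene
#' set and three kinds of TFs: *explicit* TFs write about the planted topic
#' and share PMIDs with planted genes; *implicit* TFs write about a bridge
#' topic that co-occurs with the planted topic only inside intermediate
#' ("bridge") genes' documents, and share zero PMIDs with planted genes;
#' the remaining TFs write about unrelated topics. This makes explicit
#' associations detectable by co-occurrence, implicit ones only by latent
#' semantic structure.
#'
#' @param n_genes Number of non-TF genes (default 800).
#' @param n_tfs Number of TFs (default 100); TFs are genes too and are part of
#'   the population.
#' @param n_topics Number of topic vocabularies, at least 3: topic 1 is the
#'   planted topic, topic 2 the bridge topic, the rest background topics
#'   (default 8).
#' @param vocab_size_per_topic Words per topic vocabulary (default 120).
#' @param shared_vocab_size Words in the shared background vocabulary used by
#'   every document (default 300).
#' @param docs_per_gene Integer `c(min, max)` for the per-gene abstract count;
#'   counts are drawn with probability proportional to 1/d, giving the skew
#'   toward single-abstract genes seen in curated collections (default 1..8).
#' @param explicit_tf_fraction,implicit_tf_fraction Fractions of the TF
#'   universe planted as explicitly / implicitly associated (defaults 0.1
#'   each; their sum must be <= 1).
#' @param planted_geneset_size Size of the planted query gene set (default 40).
#' @param pmid_overlap_rate Fraction of an explicit TF's abstracts shared
#'   (same PMID) with planted genes (default 0.5).
#' @param bridge_gene_fraction Fraction of genes acting as bridges mixing the
#'   planted and bridge topics (default 0.1).
#' @param background_word_rate Probability that a word is drawn from the
#'   shared vocabulary instead of the document's topic (default 0.35).
#' @param words_per_doc Integer `c(min, max)` words per abstract (default
#'   40..80).
#' @param seed Integer RNG seed; generation is a pure function of the spec.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 800, n_tfs = 100, n_topics = 8,
                           vocab_size_per_topic = 120, shared_vocab_size = 300,
                           docs_per_gene = c(1, 8),
                           explicit_tf_fraction = 0.1,
                           implicit_tf_fraction = 0.1,
                           planted_geneset_size = 40,
                           pmid_overlap_rate = 0.5,
                           bridge_gene_fraction = 0.1,
                           background_word_rate = 0.35,
                           words_per_doc = c(40, 80),
                           seed = 1) {
  spec <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
               n_topics = as.integer(n_topics),
               vocab_size_per_topic = as.integer(vocab_size_per_topic),
               shared_vocab_size = as.integer(shared_vocab_size),
               docs_per_gene = as.integer(docs_per_gene),
               explicit_tf_fraction = explicit_tf_fraction,
               implicit_tf_fraction = implicit_tf_fraction,
               planted_geneset_size = as.integer(planted_geneset_size),
               pmid_overlap_rate = pmid_overlap_rate,
               bridge_gene_fraction = bridge_gene_fraction,
               background_word_rate = background_word_rate,
               words_per_doc = as.integer(words_per_doc),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes > 0, n_tfs > 0, n_topics >= 3,
              vocab_size_per_topic > 0, shared_vocab_size > 0,
              length(docs_per_gene) == 2L, docs_per_gene[1] >= 1,
              docs_per_gene[2] >= docs_per_gene[1],
              explicit_tf_fraction >= 0, implicit_tf_fraction >= 0,
              explicit_tf_fraction + implicit_tf_fraction <= 1,
              planted_geneset_size > 0, planted_geneset_size < n_genes,
              pmid_overlap_rate >= 0, pmid_overlap_rate <= 1,
              bridge_gene_fraction >= 0, bridge_gene_fraction < 1,
              background_word_rate >= 0, background_word_rate < 1,
              length(words_per_doc) == 2L, words_per_doc[1] >= 1,
              words_per_doc[2] >= words_per_doc[1])
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic gene-literature corpus with planted associations
#'
#' Deterministic given the spec (which carries the seed). Every gene and TF
#' gets 1 or more abstracts; each abstract is a bag of words drawn from the
#' entity's topic mixture plus shared background vocabulary. Explicit TFs'
#' abstracts are partly the very same PMIDs as planted genes' abstracts;
#' implicit TFs get fresh PMIDs only, so their co-occurrence score with every
#' planted gene is 0 by construction.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `gene_to_pmids` (named list over genes and TFs),
#'   `abstracts` (data frame `pmid`, `title`, `abstract`), and `truth`
#'   (`synthetic_truth`: `planted_gene_set`, `relevant_tfs` data frame with
#'   `tf_id` and `mode`, `tf_ids`, `topics` named list of per-entity topic
#'   mixtures, `spec`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$pmid_overlap_rate > 0 && spec$planted_geneset_size == 0) {
    stop("infeasible spec: PMID overlap requested but no planted genes")
  }
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  tfs <- sprintf("tf%03d", seq_len(spec$n_tfs))
  planted <- genes[seq_len(spec$planted_geneset_size)]
  n_bridge <- round(spec$bridge_gene_fraction * spec$n_genes)
  bridge <- if (n_bridge > 0) {
    genes[spec$planted_geneset_size + seq_len(n_bridge)]
  } else character(0)
  if (spec$planted_geneset_size + n_bridge > spec$n_genes) {
    stop("infeasible spec: planted set plus bridge genes exceed n_genes")
  }
  others <- setdiff(genes, c(planted, bridge))

  n_exp <- round(spec$explicit_tf_fraction * spec$n_tfs)
  n_imp <- round(spec$implicit_tf_fraction * spec$n_tfs)
  explicit_tfs <- tfs[seq_len(n_exp)]
  implicit_tfs <- tfs[n_exp + seq_len(n_imp)]
  other_tfs <- tfs[-seq_len(n_exp + n_imp)]

  background_topics <- seq(3L, spec$n_topics)
  # topic mixture per entity: named numeric vector of topic weights
  mixtures <- c(
    stats::setNames(rep(list(c("1" = 1)), length(planted)), planted),
    stats::setNames(rep(list(c("1" = 0.5, "2" = 0.5)), length(bridge)), bridge),
    stats::setNames(lapply(seq_along(others), function(i) {
      t <- background_topics[((i - 1L) %% length(background_topics)) + 1L]
      stats::setNames(1, t)
    }), others),
    stats::setNames(rep(list(c("1" = 1)), length(explicit_tfs)), explicit_tfs),
    stats::setNames(rep(list(c("2" = 1)), length(implicit_tfs)), implicit_tfs),
    stats::setNames(lapply(seq_along(other_tfs), function(i) {
      t <- background_topics[((i - 1L) %% length(background_topics)) + 1L]
      stats::setNames(1, t)
    }), other_tfs)
  )

  topic_vocab <- lapply(seq_len(spec$n_topics), function(t) {
    sprintf("topic%02dword%03d", t, seq_len(spec$vocab_size_per_topic))
  })
  shared_vocab <- sprintf("common%03d", seq_len(spec$shared_vocab_size))

  d_range <- seq(spec$docs_per_gene[1], spec$docs_per_gene[2])
  d_prob <- 1 / d_range
  vocab_mat <- do.call(rbind, topic_vocab)   # topics x words, for fast lookup

  make_doc <- function(mix) {
    nw <- sample(seq(spec$words_per_doc[1], spec$words_per_doc[2]), 1L)
    bg <- stats::runif(nw) < spec$background_word_rate
    words <- character(nw)
    n_bg <- sum(bg)
    if (n_bg > 0) words[bg] <- sample(shared_vocab, n_bg, replace = TRUE)
    n_tp <- nw - n_bg
    if (n_tp > 0) {
      topics <- as.integer(names(mix))[
        sample.int(length(mix), n_tp, replace = TRUE, prob = mix)]
      word_idx <- sample.int(spec$vocab_size_per_topic, n_tp, replace = TRUE)
      words[!bg] <- vocab_mat[cbind(topics, word_idx)]
    }
    words
  }

  entities <- c(genes, tfs)
  pmid_counter <- 0L
  gene_to_pmids <- vector("list", length(entities))
  names(gene_to_pmids) <- entities
  pmid_ids <- character(0)
  pmid_title <- character(0)
  pmid_abstract <- character(0)

  emit_doc <- function(mix) {
    words <- make_doc(mix)
    pmid_counter <<- pmid_counter + 1L
    pmid <- sprintf("p%06d", pmid_counter)
    nt <- min(5L, length(words))
    pmid_ids <<- c(pmid_ids, pmid)
    pmid_title <<- c(pmid_title, paste(words[seq_len(nt)], collapse = " "))
    pmid_abstract <<- c(pmid_abstract,
                        paste(words[-seq_len(nt)], collapse = " "))
    pmid
  }

  # genes, implicit TFs and unrelated TFs: fresh PMIDs only
  for (id in c(genes, implicit_tfs, other_tfs)) {
    d <- sample(d_range, 1L, prob = d_prob)
    gene_to_pmids[[id]] <- vapply(seq_len(d), function(...) {
      emit_doc(mixtures[[id]])
    }, character(1))
  }
  # implicit TFs co-occur with bridge genes only: a fraction of their
  # (pure bridge-topic) abstracts are also referenced by a random bridge
  # gene. Their co-occurrence with every planted gene stays exactly zero,
  # while their population mean co-occurrence is positive.
  if (length(bridge) > 0 && spec$pmid_overlap_rate > 0) {
    for (id in implicit_tfs) {
      own <- gene_to_pmids[[id]]
      n_shared <- min(length(own),
                      max(1L, round(spec$pmid_overlap_rate * length(own))))
      shared <- sample(own, n_shared)
      hosts <- sample(bridge, n_shared, replace = TRUE)
      for (q in seq_len(n_shared)) {
        gene_to_pmids[[hosts[q]]] <- c(gene_to_pmids[[hosts[q]]], shared[q])
      }
    }
  }
  planted_pool <- unlist(gene_to_pmids[planted], use.names = FALSE)
  # explicit TFs: a fraction of their abstracts are shared planted-gene PMIDs
  for (id in explicit_tfs) {
    d <- sample(d_range, 1L, prob = d_prob)
    n_shared <- if (spec$pmid_overlap_rate > 0) {
      max(1L, round(spec$pmid_overlap_rate * d))
    } else 0L
    n_shared <- min(n_shared, length(planted_pool))
    shared <- if (n_shared > 0) sample(planted_pool, n_shared) else character(0)
    fresh <- vapply(seq_len(d - n_shared), function(...) {
      emit_doc(mixtures[[id]])
    }, character(1))
    gene_to_pmids[[id]] <- c(shared, fresh)
  }

  abstracts <- data.frame(pmid = pmid_ids, title = pmid_title,
                          abstract = pmid_abstract, stringsAsFactors = FALSE)
  truth <- structure(
    list(planted_gene_set = planted,
         relevant_tfs = data.frame(
           tf_id = c(explicit_tfs, implicit_tfs),
           mode = rep(c("explicit", "implicit"),
                      c(length(explicit_tfs), length(implicit_tfs))),
           stringsAsFactors = FALSE),
         tf_ids = tfs, gene_ids = genes, topics = mixtures, spec = spec),
    class = "synthetic_truth")
  list(gene_to_pmids = gene_to_pmids, abstracts = abstracts, truth = truth)
}

#' Generate a synthetic two-condition expression table
#'
#' Planted genes get a treated/control mean ratio of `fold`; all other genes
#' (and the TFs) ratio 1. Per-sample values carry multiplicative lognormal
#' noise of scale `noise_sd` (0 gives exact group means, so the planted set is
#' recovered exactly by [select_degs()] for any `fold` above the threshold).
#'
#' @param truth A `synthetic_truth` from [generate_corpus()].
#' @param n_samples_per_group Samples per condition (default 4).
#' @param fold Treated/control ratio for planted genes, > 1 (default 4).
#' @param noise_sd Standard deviation of the log-scale noise, >= 0
#'   (default 0.25).
#' @param seed Integer RNG seed.
#' @return An `expression_table` over all genes and TFs, with group levels
#'   `control`, `treated`.
#' @export
generate_expression <- function(truth, n_samples_per_group = 4, fold = 4,
                                noise_sd = 0.25, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), fold > 1, noise_sd >= 0,
            n_samples_per_group >= 2)
  set.seed(as.integer(seed))
  ids <- c(truth$gene_ids, truth$tf_ids)
  n <- length(ids)
  m <- as.integer(n_samples_per_group)
  base <- exp(stats::rnorm(n, mean = log(100), sd = 0.8))
  ratio <- ifelse(ids %in% truth$planted_gene_set, fold, 1)
  noise <- function() {
    if (noise_sd == 0) matrix(1, n, m)
    else matrix(exp(stats::rnorm(n * m, sd = noise_sd)), n, m)
  }
  ctrl <- base * noise()
  trt <- (base * ratio) * noise()
  values <- cbind(ctrl, trt)
  colnames(values) <- c(sprintf("control_%d", seq_len(m)),
                        sprintf("treated_%d", seq_len(m)))
  expression_table(values,
                   groups = factor(rep(c("control", "treated"), each = m),
                                   levels = c("control", "treated")),
                   gene_ids = ids)
}

#' End-to-end recovery benchmark on one synthetic corpus
#'
#' Generates a corpus, runs the log-entropy LSI pipeline and the
#' co-occurrence baseline against the planted gene set, and evaluates the TF
#' ranking against the planted relevant TFs. The default `k` sits below the
#' corpus' topic count: latent semantic models expose implicit associations
#' only when the truncation rank is below the structural rank of the
#' collection (the genome-scale analogue being a rank of a few hundred
#' against hundreds of thousands of terms).
#'
#' @param seed Integer seed for the corpus spec.
#' @param k LSI truncation rank (default 6, for the default 8-topic spec).
#' @param spec A `synthetic_spec`; defaults to `synthetic_spec(seed = seed)`.
#' @return List with `lsi_auc`, `cooccurrence_auc`, `implicit_lsi_p`
#'   (vector over implicit TFs), `implicit_cooccurrence_p`, and the two
#'   ranked data frames (`lsi_ranking`, `cooccurrence_ranking`).
#' @export
run_synthetic_benchmark <- function(seed = 1, k = 6,
                                    spec = synthetic_spec(seed = seed)) {
  corpus <- generate_corpus(spec)
  filtered <- filter_pmids(corpus$gene_to_pmids)
  docs <- build_gene_documents(filtered, corpus$abstracts)
  tgm <- build_term_gene_matrix(docs, read_stoplist())
  model <- fit_lsi(weight_log_entropy(tgm), k = k)
  truth <- corpus$truth
  ranked <- enrich_tfs(model, truth$tf_ids, truth$planted_gene_set,
                       tgm$gene_ids)
  cm <- cooccurrence_model(corpus$gene_to_pmids)
  ranked_co <- enrich_tfs(cm, truth$tf_ids, truth$planted_gene_set,
                          tgm$gene_ids)
  rel <- truth$relevant_tfs
  implicit <- rel$tf_id[rel$mode == "implicit"]
  list(lsi_auc = roc_curve(ranked, rel$tf_id)$auc,
       cooccurrence_auc = roc_curve(ranked_co, rel$tf_id)$auc,
       implicit_lsi_p = stats::setNames(
         ranked$p_value[match(implicit, ranked$tf_id)], implicit),
       implicit_cooccurrence_p = stats::setNames(
         ranked_co$p_value[match(implicit, ranked_co$tf_id)], implicit),
       lsi_ranking = ranked, cooccurrence_ranking = ranked_co,
       truth = truth)
}
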