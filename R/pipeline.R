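#' Configuration for the end-to-end TF ranking pipeline
#'
#' Inputs may be given as file paths (the TSV dialects documented in the
#' reader functions) or as in-memory objects of the corresponding type.
#'
#' @param gene2pubmed Path to a gene-to-PMID TSV, or a named list.
#' @param abstracts Path to an abstracts TSV, or a data frame
#'   (`pmid`, `title`, `abstract`).
#' @param tf_list Path to a TF id list, or a character vector.
#' @param out_dir Output directory for all artifacts.
#' @param query_genes Path or character vector of query gene ids; omit when
#'   `expression` is given (the query set is then selected by [select_degs()]).
#' @param expression Optional `expression_table` for DEG selection.
#' @param stoplist Path or character vector; default is the packaged stoplist.
#' @param gold Optional path to a gold-standard file or a `gold_standard` /
#'   character vector, enabling ROC evaluation.
#' @param schemes Weighting schemes to run (default both).
#' @param k LSI rank (default 500; clamped on small corpora).
#' @param alpha Significance level for the enrichment flag and DEG selection.
#' @param fold_threshold Fold-change threshold for DEG selection.
#' @param max_genes_per_pmid PMID specificity filter threshold.
#' @param remove_self_from_query Drop a TF from the query set when scoring it.
#' @param run_cooccurrence Also rank TFs with the co-occurrence baseline.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(gene2pubmed, abstracts, tf_list, out_dir,
                            query_genes = NULL, expression = NULL,
                            stoplist = NULL, gold = NULL,
                            schemes = c("log-entropy", "tf-normal"),
                            k = 500, alpha = 0.05, fold_threshold = 2,
                            max_genes_per_pmid = 10,
                            remove_self_from_query = TRUE,
                            run_cooccurrence = TRUE, seed = 1) {
  schemes <- match.arg(schemes, c("log-entropy", "tf-normal"),
                       several.ok = TRUE)
  stopifnot(k >= 1, alpha > 0, alpha < 1, fold_threshold >= 1,
            max_genes_per_pmid >= 1)
  if (is.null(query_genes) && is.null(expression)) {
    stop("provide either query_genes or an expression table for DEG selection")
  }
  structure(list(gene2pubmed = gene2pubmed, abstracts = abstracts,
                 tf_list = tf_list, out_dir = out_dir,
                 query_genes = query_genes, expression = expression,
                 stoplist = stoplist, gold = gold, schemes = schemes,
                 k = as.integer(k), alpha = alpha,
                 fold_threshold = fold_threshold,
                 max_genes_per_pmid = max_genes_per_pmid,
                 remove_self_from_query = remove_self_from_query,
                 run_cooccurrence = run_cooccurrence,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments; input
#' fields must be file paths (relative paths are resolved against the YAML
#' file's directory).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  }
  for (f in c("gene2pubmed", "abstracts", "tf_list", "query_genes",
              "stoplist", "gold")) {
    cfg[[f]] <- resolve(cfg[[f]])
  }
  cfg$out_dir <- if (is.null(cfg$out_dir)) file.path(base, "lsitf_out") else resolve(cfg$out_dir)
  do.call(pipeline_config, cfg)
}

#' Run the full literature-based TF ranking workflow
#'
#' Stages: PMID filtering, gene-document assembly, term-by-gene matrix,
#' weighting, truncated SVD, TF enrichment and ranking for each requested
#' scheme; optionally the co-occurrence baseline and ROC evaluation against a
#' gold standard. Every intermediate artifact is written under
#' `config$out_dir` together with `manifest.json` recording parameters and
#' per-stage counts. Reruns with the same config are identical.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) list with `rankings` (named list of ranked data
#'   frames), `evaluation` (a `model_evaluation` or NULL), `query_genes`,
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  gene_map <- if (is.character(config$gene2pubmed) && length(config$gene2pubmed) == 1L) {
    read_gene2pubmed(config$gene2pubmed)
  } else config$gene2pubmed
  abstracts <- if (is.character(config$abstracts) && length(config$abstracts) == 1L) {
    read_abstracts(config$abstracts)
  } else config$abstracts
  tf_ids <- if (is.character(config$tf_list) && length(config$tf_list) == 1L &&
                file.exists(config$tf_list)) {
    read_gene_list(config$tf_list)
  } else as.character(config$tf_list)
  stoplist <- if (is.null(config$stoplist)) {
    read_stoplist()
  } else if (length(config$stoplist) == 1L && file.exists(config$stoplist)) {
    read_stoplist(config$stoplist)
  } else tolower(as.character(config$stoplist))

  say("[corpus] %d genes, %d abstracts in", length(gene_map), nrow(abstracts))
  filtered <- filter_pmids(gene_map, config$max_genes_per_pmid)
  n_pmids_in <- length(unique(unlist(gene_map, use.names = FALSE)))
  n_pmids_kept <- length(unique(unlist(filtered, use.names = FALSE)))
  say("[corpus] PMID filter (> %d genes): %d -> %d PMIDs, %d -> %d genes",
      config$max_genes_per_pmid, n_pmids_in, n_pmids_kept,
      length(gene_map), length(filtered))
  docs <- build_gene_documents(filtered, abstracts)
  tgm <- build_term_gene_matrix(docs, stoplist)
  say("[corpus] term-by-gene matrix: %d terms x %d genes",
      length(tgm$terms), length(tgm$gene_ids))
  write_term_gene_matrix(tgm, file.path(out, "term_gene_matrix"))

  population <- tgm$gene_ids
  tf_universe <- intersect(tf_ids, population)
  if (length(tf_universe) < length(tf_ids)) {
    say("[enrich] %d of %d TFs have no literature document and are not ranked",
        length(tf_ids) - length(tf_universe), length(tf_ids))
  }

  if (!is.null(config$expression)) {
    qg <- select_degs(config$expression, config$fold_threshold, config$alpha)
    say("[deg] Welch test + %g-fold filter selected %d genes",
        config$fold_threshold, length(qg))
    writeLines(qg, file.path(out, "query_genes.txt"))
  } else {
    qg <- if (length(config$query_genes) == 1L && file.exists(config$query_genes)) {
      read_gene_list(config$query_genes)
    } else as.character(config$query_genes)
  }
  query <- intersect(qg, population)
  if (length(query) < length(qg)) {
    say("[enrich] %d query gene(s) absent from the corpus ignored",
        length(qg) - length(query))
  }

  rankings <- list()
  for (scheme in config$schemes) {
    w <- if (scheme == "log-entropy") weight_log_entropy(tgm) else weight_tf_normal(tgm)
    write_weighted_matrix(w, file.path(out, paste0("weighted_", scheme)))
    model <- withCallingHandlers(
      fit_lsi(w, k = config$k),
      warning = function(cond) {
        say("[lsi] %s", conditionMessage(cond))
        invokeRestart("muffleWarning")
      })
    say("[lsi] %s model fitted, effective k = %d", scheme, model$k)
    write_lsi_model(model, file.path(out, paste0("lsi_", scheme)))
    ranked <- enrich_tfs(model, tf_universe, query, population,
                         alpha = config$alpha,
                         remove_self_from_query = config$remove_self_from_query)
    write_enrichment(ranked, file.path(out, paste0("ranking_", scheme, ".tsv")))
    rankings[[scheme]] <- ranked
  }

  if (config$run_cooccurrence) {
    cm <- cooccurrence_model(gene_map, config$max_genes_per_pmid)
    co_universe <- intersect(tf_universe, cm$gene_ids)
    co_query <- intersect(query, cm$gene_ids)
    ranked <- enrich_tfs(cm, co_universe, co_query, intersect(population, cm$gene_ids),
                         alpha = config$alpha,
                         remove_self_from_query = config$remove_self_from_query)
    write_enrichment(ranked, file.path(out, "ranking_cooccurrence.tsv"))
    rankings[["cooccurrence"]] <- ranked
    say("[cooccur] baseline ranking over %d TFs", nrow(ranked))
  }

  evaluation <- NULL
  if (!is.null(config$gold)) {
    gold <- if (is.character(config$gold) && length(config$gold) == 1L &&
                file.exists(config$gold)) {
      read_gold_standard(config$gold)
    } else config$gold
    gold_ids <- if (inherits(gold, "gold_standard")) gold$relevant_tfs else as.character(gold)
    usable <- lapply(rankings, function(r) {
      g <- intersect(gold_ids, r$tf_id)
      if (length(g) < length(gold_ids)) {
        say("[evaluate] %d gold TF(s) outside the ranked universe ignored",
            length(gold_ids) - length(g))
      }
      g
    })
    evaluation <- structure(list(
      curves = Map(function(r, g) roc_curve(r, g), rankings, usable),
      auc_table = NULL), class = "model_evaluation")
    evaluation$auc_table <- data.frame(
      model = names(evaluation$curves),
      auc = vapply(evaluation$curves, `[[`, numeric(1), "auc"),
      row.names = NULL, stringsAsFactors = FALSE)
    for (nm in names(evaluation$curves)) {
      write_roc(evaluation$curves[[nm]],
                file.path(out, paste0("roc_", nm, ".tsv")), model = nm)
      say("[evaluate] %s AUC = %.4f", nm, evaluation$curves[[nm]]$auc)
    }
  }

  manifest <- list(
    parameters = list(schemes = config$schemes, k = config$k,
                      alpha = config$alpha,
                      fold_threshold = config$fold_threshold,
                      max_genes_per_pmid = config$max_genes_per_pmid,
                      remove_self_from_query = config$remove_self_from_query,
                      seed = config$seed),
    counts = list(genes_in = length(gene_map),
                  genes_after_pmid_filter = length(filtered),
                  genes_dropped_by_pmid_filter = length(gene_map) - length(filtered),
                  genes_ranked_over_population = length(population),
                  pmids_in = n_pmids_in, pmids_kept = n_pmids_kept,
                  vocabulary_size = length(tgm$terms),
                  tf_universe = length(tf_universe),
                  query_genes = length(query)),
    versions = list(lsitf = as.character(utils::packageVersion("lsitf")),
                    r = as.character(getRversion())))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(rankings = rankings, evaluation = evaluation,
                 query_genes = query, manifest = manifest, out_dir = out))
}
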