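# A small deterministic LSI model shared by the sampling tests.
toy_model <- function(seed = 6, n_terms = 15, n_genes = 10) {
  fit_lsi(weight_log_entropy(make_tgm(random_counts(n_terms, n_genes, seed))),
          k = n_genes)
}

test_that("association sample excludes the TF's self-association from the population", {
  model <- toy_model()
  pop <- model$gene_ids
  s <- build_association_sample(model, "g05", c("g01", "g02", "g03"), pop)
  expect_length(s$t_P, length(pop) - 1)
  expect_false("g05" %in% names(s$t_P))
  expect_equal(s$N, length(pop))
  expect_equal(s$mu, mean(s$t_P))
})

test_that("a TF inside the query set is removed from the observed sample by default", {
  model <- toy_model()
  query <- c("g01", "g02", "g03", "g04", "g05")
  s <- build_association_sample(model, "g05", query, model$gene_ids)
  expect_equal(s$n_G, 4L)
  expect_false("g05" %in% names(s$t_G))
  s_keep <- build_association_sample(model, "g05", query, model$gene_ids,
                                     remove_self_from_query = FALSE)
  expect_equal(s_keep$n_G, 5L)
  expect_error(build_association_sample(model, "g01", c("g01", "g02"),
                                        model$gene_ids),
               ">= 2")
})

test_that("association sample entries match direct per-pair scoring", {
  model <- toy_model()
  query <- c("g02", "g07", "g09")
  s <- build_association_sample(model, "g01", query, model$gene_ids)
  for (g in query) expect_equal(unname(s$t_G[g]), cosine(model, "g01", g))
  for (g in names(s$t_P)) expect_equal(unname(s$t_P[g]), cosine(model, "g01", g))
})

test_that("the right-tailed one-sample t-test matches its textbook form", {
  sample_of <- function(t_G, mu) {
    structure(list(tf_id = "tf", t_G = t_G, t_P = mu, mu = mu,
                   s = sd(t_G), n_G = length(t_G), N = 100L),
              class = "association_sample")
  }
  r <- enrichment_pvalue(sample_of(c(0.3, 0.5, 0.4, 0.6), mu = 0.2))
  ref <- t.test(c(0.3, 0.5, 0.4, 0.6), mu = 0.2, alternative = "greater")
  expect_equal(r$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  # observed scores all equal to the population mean: symmetric null
  r0 <- enrichment_pvalue(sample_of(c(0.2, 0.2, 0.2), mu = 0.2))
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 0.5)

  # all-zero observed scores against a positive population mean
  r1 <- enrichment_pvalue(sample_of(c(0, 0, 0), mu = 0.04))
  expect_equal(r1$p_value, 1)

  # zero-variance sample strictly above the mean
  r2 <- enrichment_pvalue(sample_of(c(0.5, 0.5), mu = 0.2))
  expect_equal(r2$p_value, .Machine$double.xmin)

  set.seed(31)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.05, 1))
    mu <- runif(1, -1, 1)
    ours <- enrichment_pvalue(sample_of(x, mu))$p_value
    ref <- t.test(x, mu = mu, alternative = "greater")$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("the t-statistic is location invariant and the p-value monotone in the observed mean", {
  x <- c(0.1, 0.25, 0.3, 0.18, 0.22)
  mk <- function(t_G, mu) {
    structure(list(tf_id = "tf", t_G = t_G, t_P = mu, mu = mu, s = sd(t_G),
                   n_G = length(t_G), N = 50L),
              class = "association_sample")
  }
  base <- enrichment_pvalue(mk(x, 0.15))
  for (delta in c(-0.4, 0.3, 2)) {
    shifted <- enrichment_pvalue(mk(x + delta, 0.15 + delta))
    expect_equal(shifted$t_stat, base$t_stat, tolerance = 1e-12)
  }
  # raising every observation (mean up, s fixed) strictly lowers p
  ps <- sapply(seq(0, 0.5, by = 0.1), function(d) {
    enrichment_pvalue(mk(x + d, 0.15))$p_value
  })
  expect_true(all(diff(ps) < 0))
  # tail limits
  expect_lt(enrichment_pvalue(mk(x + 50, 0.15))$p_value, 1e-10)
  expect_gt(enrichment_pvalue(mk(x - 50, 0.15))$p_value, 1 - 1e-10)
})

test_that("ranking sorts by p-value with mean-observed and id tie-breaks", {
  res <- data.frame(tf_id = c("tfA", "tfB", "tfC"),
                    p_value = c(0.01, 0.20, 0.01),
                    mean_observed = c(0.5, 0.1, 0.3))
  ranked <- rank_tfs(res)
  expect_equal(ranked$tf_id, c("tfA", "tfC", "tfB"))
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$tie_group, 1:3)

  # fully tied rows share a tie group and are ordered lexicographically
  tied <- data.frame(tf_id = c("tfZ", "tfY", "tfA"),
                     p_value = c(1, 1, 0.2), mean_observed = c(0, 0, 0.1))
  rt <- rank_tfs(tied)
  expect_equal(rt$tf_id, c("tfA", "tfY", "tfZ"))
  expect_equal(rt$tie_group, c(1L, 2L, 2L))

  expect_error(rank_tfs(data.frame(tf_id = c("a", "a"),
                                   p_value = c(0.1, 0.2),
                                   mean_observed = c(0, 0))),
               "duplicate")
})

test_that("ranking of random results is a valid stable sort", {
  set.seed(17)
  res <- data.frame(tf_id = sprintf("tf%03d", 1:100),
                    p_value = sample(round(runif(100), 2), replace = TRUE),
                    mean_observed = round(runif(100), 1))
  ranked <- rank_tfs(res)
  expect_setequal(ranked$tf_id, res$tf_id)
  expect_equal(ranked$rank, 1:100)
  expect_false(is.unsorted(ranked$p_value))
  for (i in 2:100) {
    if (ranked$p_value[i] == ranked$p_value[i - 1]) {
      expect_lte(ranked$mean_observed[i], ranked$mean_observed[i - 1])
      if (ranked$mean_observed[i] == ranked$mean_observed[i - 1]) {
        expect_true(ranked$tf_id[i] > ranked$tf_id[i - 1])
        expect_equal(ranked$tie_group[i], ranked$tie_group[i - 1])
      } else {
        expect_gt(ranked$tie_group[i], ranked$tie_group[i - 1])
      }
    }
  }
})
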