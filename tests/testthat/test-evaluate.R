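test_that("expression tables validate group structure", {
  vals <- matrix(1:12, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_s3_class(expression_table(vals, rep(c("c", "t"), each = 2)),
                  "expression_table")
  expect_error(expression_table(vals, c("c", "t", "t", "t")),
               "at least 2 samples")
  expect_error(expression_table(vals, rep("c", 4)), "two-level")
  expect_error(expression_table(unname(vals), rep(c("c", "t"), each = 2)),
               "gene_ids")
})

test_that("DEG selection applies Welch test and strict fold-change rule", {
  set.seed(12)
  n <- 50
  planted <- sprintf("g%02d", 1:20)
  ids <- sprintf("g%02d", 1:n)
  base <- runif(n, 50, 150)
  fold <- ifelse(ids %in% planted, 4, 1)
  noise <- function() matrix(exp(rnorm(n * 4, sd = 0.05)), n, 4)
  vals <- cbind(base * noise(), base * fold * noise())
  expr <- expression_table(vals, rep(c("control", "treated"), each = 4),
                           gene_ids = ids)
  degs <- select_degs(expr)
  expect_setequal(as.character(degs), planted)

  stats <- attr(degs, "stats")
  expect_equal(stats$gene_id, ids)
  expect_true(all(stats$p_value[stats$selected] < 0.05))
  expect_true(all(stats$fold[stats$selected] > 2))
})

test_that("identical, exactly-2-fold, and non-positive-control genes are excluded", {
  vals <- rbind(flat = c(5, 5, 5, 5, 5, 5),
                exact2 = c(10, 10, 10, 20, 20, 20),
                up = c(10, 10, 10, 90, 110, 100),
                down4 = c(100, 104, 96, 25, 26, 24),
                badctrl = c(0, 0, 0, 10, 11, 12))
  expr <- expression_table(vals, rep(c("control", "treated"), each = 3))
  expect_warning(degs <- select_degs(expr), "non-positive control mean")
  # down-regulated genes count: 4-fold down is a > 2-fold change
  expect_setequal(as.character(degs), c("up", "down4"))

  # degenerate no-filter case keeps every gene with a positive control mean
  set.seed(3)
  vals2 <- matrix(runif(40, 1, 10), 10, 4)
  rownames(vals2) <- paste0("g", 1:10)
  expr2 <- expression_table(vals2, rep(c("control", "treated"), each = 2))
  expect_setequal(as.character(select_degs(expr2, fold_threshold = 1, alpha = 1)),
                  rownames(vals2))
})

test_that("ROC boundary rankings give AUC exactly 1 and 0", {
  universe <- sprintf("tf%03d", 1:433)
  gold <- universe[1:100]
  expect_equal(roc_curve(universe, gold)$auc, 1)
  expect_equal(roc_curve(rev(universe), gold)$auc, 0)
  roc <- roc_curve(universe, gold)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_false(is.unsorted(roc$points$fpr))
  expect_false(is.unsorted(roc$points$tpr))
})

test_that("AUC equals the brute-force ordered-pair fraction", {
  set.seed(14)
  universe <- sprintf("tf%02d", 1:20)
  gold <- sample(universe, 5)
  for (i in 1:10) {
    ranking <- sample(universe)
    expect_equal(roc_curve(ranking, gold)$auc, pair_auc(ranking, gold))
  }
})

test_that("tie groups collapse to single ROC vertices and score tied pairs as half", {
  universe <- sprintf("tf%02d", 1:10)
  gold <- c("tf01", "tf02", "tf03")
  # ranks 1-2 distinct, the remaining 8 TFs all tied (e.g. p = 1 block)
  groups <- c(1L, 2L, rep(3L, 8))
  ranking <- c("tf01", "tf04", universe[-c(1, 4)])
  roc <- roc_curve(ranking, gold, tie_groups = groups)
  expect_equal(nrow(roc$points), 4)   # (0,0) + one vertex per tie group
  expect_equal(roc$auc, pair_auc(ranking, gold, tie_groups = groups))
})

test_that("ROC validates its gold standard", {
  universe <- sprintf("tf%02d", 1:6)
  expect_error(roc_curve(universe, c("tf01", "tfXX")), "tfXX")
  expect_error(roc_curve(universe, universe), "proper subset")
  expect_error(roc_curve(universe, character(0)), "proper subset")
})

test_that("model comparison reproduces per-ranking ROC calls and reversal symmetry", {
  set.seed(15)
  universe <- sprintf("tf%02d", 1:30)
  gold <- sample(universe, 8)
  r1 <- sample(universe)
  rankings <- list(a = r1, a_again = r1, reversed = rev(r1),
                   other = sample(universe))
  ev <- evaluate_models(rankings, gold)
  expect_equal(ev$auc_table$model, names(rankings))
  expect_equal(ev$auc_table$auc[1], ev$auc_table$auc[2])
  expect_equal(ev$auc_table$auc[3], 1 - ev$auc_table$auc[1], tolerance = 1e-12)
  for (nm in names(rankings)) {
    expect_equal(ev$curves[[nm]]$auc, roc_curve(rankings[[nm]], gold)$auc)
  }
})

test_that("ranked data frames feed ROC evaluation directly, using their tie groups", {
  res <- data.frame(tf_id = c("tfA", "tfB", "tfC", "tfD"),
                    p_value = c(0.01, 1, 1, 1),
                    mean_observed = c(0.5, 0, 0, 0))
  ranked <- rank_tfs(res)
  roc <- roc_curve(ranked, c("tfA", "tfD"))
  # tfD sits in the tied p = 1 block: its pairs with tfB/tfC count half
  expect_equal(roc$auc, pair_auc(ranked$tf_id, c("tfA", "tfD"),
                                 tie_groups = ranked$tie_group))
  expect_equal(nrow(roc$points), 3)
})
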