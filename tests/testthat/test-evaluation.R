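test_that("confusion counts match hand cases", {
  a <- rep(c("positive", "negative"), each = 4)
  cc <- confusion(a, a)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 4, TN = 4, FP = 0, FN = 0))
  inv <- confusion(rev(a), a)
  expect_equal(unlist(inv[c("TP", "TN", "FP", "FN")]), c(TP = 0, TN = 0, FP = 4, FN = 4))

  actual <- c("positive", "positive", "positive", "positive",
              "negative", "negative", "negative", "negative")
  pred <- c("positive", "positive", "positive", "negative",
            "positive", "positive", "negative", "negative")
  cc <- confusion(pred, actual)
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]), c(TP = 3, FN = 1, FP = 2, TN = 2))
  expect_error(confusion(a[1:3], a), "length")
})

test_that("metrics reproduce the hand-derived case and the extremes", {
  m <- classification_metrics(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(unname(m["Sn"]), 0.75)
  expect_equal(unname(m["Sp"]), 0.5)
  expect_equal(unname(m["ACC"]), 0.625)
  expect_equal(unname(m["MCC"]), 4 / sqrt(240))

  perfect <- classification_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  inverted <- classification_metrics(list(TP = 0, TN = 0, FP = 50, FN = 50))
  expect_equal(unname(inverted[c("ACC", "MCC")]), c(0, -1))

  # zero MCC denominator -> 0; empty positive class -> Sn is NA, not 0
  all_neg_calls <- classification_metrics(list(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_equal(unname(all_neg_calls["MCC"]), 0)
  no_pos <- classification_metrics(list(TP = 0, FN = 0, TN = 4, FP = 2))
  expect_true(is.na(no_pos["Sn"]))
  expect_error(classification_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "empty")
})

test_that("label-convention swap exchanges Sn/Sp and preserves ACC and |MCC|", {
  withr::with_seed(41, {
    actual <- sample(c(1, 0), 50, replace = TRUE)
    pred <- ifelse(runif(50) < 0.3, 1 - actual, actual)
  })
  m1 <- classification_metrics(confusion(pred, actual))
  m2 <- classification_metrics(confusion(1 - pred, 1 - actual))
  expect_equal(unname(m1["Sn"]), unname(m2["Sp"]))
  expect_equal(unname(m1["Sp"]), unname(m2["Sn"]))
  expect_equal(unname(m1["ACC"]), unname(m2["ACC"]))
  expect_equal(abs(unname(m1["MCC"])), abs(unname(m2["MCC"])))
})

test_that("stratified folds are disjoint, covering, balanced and seeded", {
  labs <- rep(c(1, 0), each = 5)
  folds <- stratified_kfold(labs, k = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f, 2L)
    expect_equal(sum(labs[f]), 1)  # 1 positive + 1 negative each
  }
  expect_identical(stratified_kfold(labs, 5, seed = 1), folds)
  expect_false(identical(stratified_kfold(rep(c(1, 0), each = 50), 5, seed = 1),
                         stratified_kfold(rep(c(1, 0), each = 50), 5, seed = 2)))
  expect_error(stratified_kfold(c(1, 1, 0, 0), k = 3), "at least k")
})

test_that("fold invariants hold over random configurations", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n1 <- sample(5:60, 1); n0 <- sample(5:60, 1)
      k <- sample(2:5, 1)
      labs <- sample(rep(c(1, 0), c(n1, n0)))
      folds <- stratified_kfold(labs, k, seed = i)
      all_idx <- sort(unlist(folds))
      expect_identical(all_idx, seq_len(n1 + n0))  # coverage + disjointness
      sizes <- lengths(folds)
      expect_lte(max(sizes) - min(sizes), 1L)
      pos_per_fold <- vapply(folds, function(f) sum(labs[f] == 1), numeric(1))
      expect_lte(max(pos_per_fold) - min(pos_per_fold), 1L)
    }
  })
})

test_that("roc_pr handles extremes, ties, and matches the rank-based oracle", {
  perfect <- roc_pr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(roc_pr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[1], 0)
  expect_equal(unlist(perfect$roc[nrow(perfect$roc), ]), c(fpr = 1, tpr = 1))

  # AUC == Mann-Whitney U / (n1 n0), with ties, on 50 random instances
  withr::with_seed(43, {
    for (i in 1:50) {
      n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
      labs <- c(rep(1, n1), rep(0, n0))
      scores <- round(runif(n1 + n0), 1)  # coarse -> many ties
      auc <- roc_pr(scores, labs)$auc
      w <- suppressWarnings(wilcox.test(scores[labs == 1], scores[labs == 0]))
      expect_equal(auc, unname(w$statistic) / (n1 * n0), tolerance = 1e-9)
    }
  })
  expect_error(roc_pr(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("cross_validate reports fold-consistent averages", {
  sim <- toy_gaussians(n_per = 30, d = 4, delta = 2, seed = 44)
  rep <- cross_validate(sim$X, labels = sim$labels,
                        config = svm_config(seed = 1), k = 5, seed = 1)
  expect_equal(unname(rep$mean["ACC"]), mean(rep$per_fold$ACC))
  expect_equal(unname(rep$mean["MCC"]), mean(rep$per_fold$MCC))
  expect_gte(rep$mean["ACC"], 0.9)  # planted strong signal
  expect_gte(rep$auc, 0.95)
  # determinism
  rep2 <- cross_validate(sim$X, labels = sim$labels,
                         config = svm_config(seed = 1), k = 5, seed = 1)
  expect_identical(rep$scores, rep2$scores)
})

test_that("selection leakage: replication-mode ACC >= nested ACC on null data", {
  # feature selection outside CV overfits the selection signal; nested CV
  # does not.  Tendency check over 10 small seeded null datasets.
  wins <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_pos = 40, n_neg = 40, seed = 700 + s)
    X <- encode_dataset(simulate_dataset(cfg), c("kmer2", "kmer3"))
    labs <- rep(c(1, 0), each = 40)
    svm_cfg <- svm_config(probability = FALSE, seed = 1)
    leaky <- cross_validate(X, labels = labs, selection = list(step = 20),
                            config = svm_cfg, k = 4, seed = s)
    honest <- cross_validate(X, labels = labs, selection = list(step = 20),
                             config = svm_cfg, k = 4, seed = s, nested = TRUE)
    if (leaky$mean["ACC"] >= honest$mean["ACC"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("eval reports serialize to JSON + TSV", {
  sim <- toy_gaussians(n_per = 20, d = 3, delta = 2, seed = 45)
  rep <- cross_validate(sim$X, labels = sim$labels,
                        config = svm_config(seed = 1), k = 4, seed = 1)
  dir <- tempfile()
  write_eval_report(rep, dir)
  j <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
  expect_equal(j$mean$ACC, unname(rep$mean["ACC"]))
  expect_equal(nrow(read.delim(file.path(dir, "roc.tsv"))), nrow(rep$roc))
})

test_that("position_enrichment localizes a planted positional signal", {
  pos <- random_windows(200, seed = 46)
  neg <- random_windows(200, seed = 47)
  same <- position_enrichment(pos, pos)
  expect_true(all(same$diff == 0))
  expect_true(all(same$p_value == 1 | same$freq_pos %in% c(0, 1) |
                    same$p_value > 0.99))

  # per-(class, position) frequencies sum to 1
  enr <- position_enrichment(pos, neg)
  sums <- as.vector(tapply(enr$freq_pos, enr$position, sum))
  expect_equal(sums, rep(1, 41))

  # force A at position 38 in positives
  pos38 <- vapply(pos, function(s) {
    substr(s, 38, 38) <- "A"; s
  }, character(1), USE.NAMES = FALSE)
  enr <- position_enrichment(pos38, neg)
  top <- enr[which.max(enr$diff), ]
  expect_equal(top$position, 38L)
  expect_equal(top$nucleotide, "A")
  expect_lt(top$p_bonferroni, 0.001)
  expect_error(position_enrichment(pos, substr(neg, 1, 30)), "equal length")
})
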