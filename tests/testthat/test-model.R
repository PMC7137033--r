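test_that("the dual solver satisfies the KKT conditions and weak duality", {
  # independent optimality check: feasibility, stationarity gap m - M, and
  # the duality gap between the dual objective and the primal hinge objective
  withr::with_seed(31, {
    n <- 60
    X <- matrix(rnorm(n * 5), n, 5)
    y <- ifelse(X[, 1] + rnorm(n) > 0, 1, -1)
  })
  for (cost in c(0.5, 2)) {
    K <- rnahmc:::.kernel_matrix(X, X, "rbf", 0.2)
    fit <- rnahmc:::cpp_smo(K, y, cost, 1e-4, 1e6, NULL)
    a <- fit$alpha
    expect_true(all(a >= -1e-12 & a <= cost + 1e-12))
    expect_equal(sum(a * y), 0, tolerance = 1e-9)
    # primal objective of the induced function vs dual objective
    f <- as.vector(K %*% (a * y))
    w2 <- sum((a * y) * f)
    primal <- 0.5 * w2 + cost * sum(pmax(0, 1 - y * (f - fit$rho)))
    dual <- sum(a) - 0.5 * w2
    expect_lt(primal - dual, 0.05 * abs(primal) + 0.05)
    expect_gte(primal, dual - 1e-6)
  }
})

test_that("training is deterministic and enforces the feature-name contract", {
  sim <- toy_gaussians(n_per = 25, d = 4, delta = 3, seed = 32)
  cfg <- svm_config(seed = 5)
  m1 <- svm_train(sim$X, sim$labels, cfg)
  m2 <- svm_train(sim$X, sim$labels, cfg)
  expect_identical(predict_scores(m1, sim$X), predict_scores(m2, sim$X))

  Xperm <- sim$X[, c(2, 1, 3, 4)]
  expect_error(predict_scores(m1, Xperm), "feature names")
  expect_error(svm_train(sim$X[1:25, ], sim$labels[1:25], cfg), "both classes")
})

test_that("a separable toy problem is fit perfectly and scored sensibly", {
  withr::with_seed(33, {
    labs <- rep(c("positive", "negative"), each = 30)
    X <- cbind(f1 = (labs == "positive") + rnorm(60, sd = 0.05))
  })
  m <- svm_train(X, labs, svm_config(seed = 1))
  s <- predict_scores(m, X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(as.character(classify(s)), labs)
  expect_gt(mean(s[labs == "positive"]), mean(s[labs == "negative"]))
  # identical input rows get identical scores
  Xdup <- X[c(1, 1, 2), , drop = FALSE]
  sd_ <- predict_scores(m, Xdup)
  expect_identical(sd_[1], sd_[2])
})

test_that("uncalibrated scores fall back to min-max mapped margins", {
  sim <- toy_gaussians(n_per = 20, d = 3, delta = 3, seed = 34)
  m <- svm_train(sim$X, sim$labels, svm_config(probability = FALSE, seed = 1))
  s <- predict_scores(m, sim$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(mean(s[sim$labels == "positive"]), mean(s[sim$labels == "negative"]))
})

test_that("classify applies the strictly-greater-than rule", {
  s <- c(0.7, 0.5, 0.2)
  expect_equal(as.character(classify(s, 0.5)),
               c("positive", "negative", "negative"))
  expect_equal(as.character(classify(c(0, 0.01), 0)),
               c("negative", "positive"))
  expect_equal(as.character(classify(c(0.99, 1), 1)),
               c("negative", "negative"))
  expect_error(classify(s, 1.5), "threshold")
})

test_that("grid_search covers the default 8x8 grid deterministically", {
  sim <- toy_gaussians(n_per = 20, d = 3, delta = 3, seed = 35)
  cfg <- svm_config(probability = FALSE, seed = 1)
  gs <- grid_search(sim$X, sim$labels, cfg, cv_folds = 3, seed = 4)
  expect_equal(nrow(gs$grid), 64L)
  expect_setequal(unique(gs$grid$log2c), -2:5)
  expect_setequal(unique(gs$grid$log2g), -5:2)
  expect_gte(gs$best_acc, 0.95)  # well-separated two-Gaussian toy
  gs2 <- grid_search(sim$X, sim$labels, cfg, cv_folds = 3, seed = 4)
  expect_identical(gs$best_cost, gs2$best_cost)
  expect_identical(gs$best_gamma, gs2$best_gamma)
  expect_identical(gs$grid, gs2$grid)
  expect_equal(gs$best_acc, max(gs$grid$acc))
})

test_that("grid_search tie-break prefers smaller cost then smaller gamma", {
  # a tie is guaranteed by an easy problem where many cells reach 100%
  sim <- toy_gaussians(n_per = 15, d = 2, delta = 6, seed = 36)
  gs <- grid_search(sim$X, sim$labels,
                    svm_config(probability = FALSE, seed = 1),
                    cv_folds = 3, seed = 1)
  top <- gs$grid[gs$grid$acc == gs$best_acc, ]
  expect_equal(gs$best_log2c, min(top$log2c))
  expect_equal(gs$best_log2g,
               min(top$log2g[top$log2c == gs$best_log2c]))
})

test_that("model archives round-trip and refuse version mismatches", {
  sim <- toy_gaussians(n_per = 15, d = 3, delta = 3, seed = 37)
  m <- svm_train(sim$X, sim$labels, svm_config(seed = 1))
  tf <- tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(predict_scores(m2, sim$X), predict_scores(m, sim$X))
  m$format_version <- 99L
  tf2 <- tempfile(fileext = ".rds")
  saveRDS(m, tf2)
  expect_error(load_model(tf2), "version")
  saveRDS(1:3, tf2)
  expect_error(load_model(tf2), "not a model archive")
})

test_that("the kernel-comparison harness produces curves for every kernel", {
  sim <- toy_gaussians(n_per = 20, d = 3, delta = 2, seed = 38)
  out <- compare_kernels(sim$X, sim$labels,
                         config = svm_config(probability = FALSE, seed = 1),
                         cv_folds = 3, seed = 2)
  expect_named(out, c("rbf", "polynomial", "sigmoid"))
  for (k in out) {
    expect_true(k$auc >= 0 && k$auc <= 1)
    expect_equal(k$roc$fpr[1], 0)
    expect_equal(k$roc$tpr[nrow(k$roc)], 1)
  }
})
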