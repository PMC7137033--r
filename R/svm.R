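#' Classifier configuration
#'
#' Configuration for the maximum-margin classifier and its grid search.
#' The hyperparameter grid is searched over integer powers of two:
#' `cost = 2^i` for `i` in `log2_c_range` and `gamma = 2^j` for `j` in
#' `log2_g_range` (defaults -2..5 and -5..2, an 8 x 8 grid).
#'
#' @param kernel One of `"rbf"` (default), `"polynomial"`, `"sigmoid"`.
#' @param cost Penalty parameter C used when no grid search is run.
#' @param gamma Kernel width; `"auto"` means `1 / n_features` (computed on
#'   the standardized matrix).
#' @param coef0,degree Polynomial / sigmoid kernel constants.
#' @param log2_c_range,log2_g_range Integer exponent ranges for grid search.
#' @param probability Fit a Platt sigmoid on cross-validated decision values
#'   so scores are probability-like in `[0,1]` (default TRUE).  With
#'   calibration off, scores are the raw margin min-max mapped to `[0,1]`
#'   on the training margins.
#' @param standardize Zero-mean / unit-variance scaling per feature, fitted
#'   on training data only (default TRUE).  Binary 0/1 and frequency
#'   features live on different scales; an RBF kernel mixes them poorly
#'   without this.
#' @param calibration_folds Internal CV folds for the Platt fit (default 5).
#' @param tol SMO stopping tolerance (default 1e-3).
#' @param max_iter SMO iteration cap; `NULL` selects `max(20000, 200 * n)`.
#' @param seed Integer seed controlling every internal partition.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "polynomial", "sigmoid"), cost = 1,
                       gamma = "auto", coef0 = 0, degree = 3,
                       log2_c_range = -2:5, log2_g_range = -5:2,
                       probability = TRUE, standardize = TRUE,
                       calibration_folds = 5L, tol = 1e-3, max_iter = NULL,
                       seed = 1L) {
  kernel <- match.arg(kernel)
  if (length(log2_c_range) == 0 || length(log2_g_range) == 0) {
    stop("grid ranges must be non-empty")
  }
  structure(list(kernel = kernel, cost = cost, gamma = gamma, coef0 = coef0,
                 degree = degree, log2_c_range = as.integer(log2_c_range),
                 log2_g_range = as.integer(log2_g_range),
                 probability = probability, standardize = standardize,
                 calibration_folds = as.integer(calibration_folds), tol = tol,
                 max_iter = max_iter, seed = as.integer(seed)),
            class = "svm_config")
}

.gamma_value <- function(gamma, d) {
  if (identical(gamma, "auto")) 1 / d else as.numeric(gamma)
}

.y_pm <- function(labels) {
  labels <- as_label_factor(labels)
  ifelse(labels == "positive", 1, -1)
}

# Kernel matrix between the rows of A and the rows of B (both n x d).
.kernel_matrix <- function(A, B, kernel, gamma, coef0 = 0, degree = 3) {
  G <- tcrossprod(A, B)
  switch(kernel,
    rbf = cpp_rbf_kernel(G, rowSums(A^2), rowSums(B^2), gamma),
    polynomial = (gamma * G + coef0)^degree,
    sigmoid = tanh(gamma * G + coef0),
    stop("unknown kernel: ", kernel))
}

.standardizer <- function(X, enabled) {
  if (!enabled) {
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, `-`), 2, std$scale, `/`)
}

.smo_max_iter <- function(config, n) {
  if (is.null(config$max_iter)) max(20000L, 200L * n) else
    as.integer(config$max_iter)
}

# Fit the dual on a precomputed kernel; thin wrapper kept separate so the
# selection and grid-search loops can reuse externally built kernels.
.fit_kernel <- function(K, y_pm, cost, config, alpha0 = NULL) {
  cpp_smo(K, y_pm, cost, config$tol, .smo_max_iter(config, length(y_pm)),
          alpha0)
}

# Platt sigmoid P(y=1|f) = 1 / (1 + exp(A f + B)), fitted by the regularised
# Newton iteration of Lin, Lin & Weng (2007) on decision values `dec` with
# 0/1 targets `y01`.
.platt_fit <- function(dec, y01) {
  prior1 <- sum(y01 == 1); prior0 <- sum(y01 == 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fApB <- dec * A + B
  fval <- sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
                     (t - 1) * fApB + log1p(exp(fApB))))
  sigma <- 1e-12; max_it <- 100; min_step <- 1e-10
  for (it in seq_len(max_it)) {
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec * dec * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      nA <- A + step * dA; nB <- B + step * dB
      nfApB <- dec * nA + nB
      nf <- sum(ifelse(nfApB >= 0, t * nfApB + log1p(exp(-nfApB)),
                       (t - 1) * nfApB + log1p(exp(nfApB))))
      if (nf < fval + 1e-4 * step * gd) {
        A <- nA; B <- nB; fval <- nf; fApB <- nfApB
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(A = A, B = B)
}

.platt_apply <- function(calib, dec) {
  fApB <- dec * calib$A + calib$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train the kernel classifier
#'
#' Standardization parameters and (when `config$probability`) the Platt
#' calibration are learned from the given training data only.  Calibration
#' decision values come from an internal seeded stratified CV so the sigmoid
#' is not fitted on resubstitution margins.
#'
#' @param X Feature matrix (samples x named features).
#' @param labels Binary labels (see [as_label_factor()]).
#' @param config An [svm_config()].
#' @param cost,gamma Hyperparameters; default from `config` (use the values
#'   chosen by [grid_search()] here).
#' @return An object of class `svm_model`.
#' @export
svm_train <- function(X, labels, config = svm_config(), cost = config$cost,
                      gamma = config$gamma) {
  labels <- as_label_factor(labels)
  if (length(unique(labels)) < 2) stop("training data must contain both classes")
  y <- .y_pm(labels)
  std <- .standardizer(X, config$standardize)
  Xs <- .apply_standardizer(X, std)
  g <- .gamma_value(gamma, ncol(X))
  K <- .kernel_matrix(Xs, Xs, config$kernel, g, config$coef0, config$degree)
  fit <- .fit_kernel(K, y, cost, config)
  sv <- which(fit$alpha > 1e-12)
  dec_train <- as.vector(K %*% (fit$alpha * y)) - fit$rho

  calib <- NULL
  if (config$probability) {
    dec_cv <- dec_train
    if (config$calibration_folds >= 2 &&
        min(table(labels)) >= config$calibration_folds) {
      folds <- stratified_kfold(labels, k = config$calibration_folds,
                                seed = config$seed)
      dec_cv <- numeric(length(y))
      for (f in folds) {
        Kf <- K[-f, -f, drop = FALSE]
        ff <- .fit_kernel(Kf, y[-f], cost, config)
        dec_cv[f] <- as.vector(K[f, -f, drop = FALSE] %*%
                                 (ff$alpha * y[-f])) - ff$rho
      }
    }
    calib <- .platt_fit(dec_cv, as.integer(labels == "positive"))
  }

  structure(list(config = config, cost = cost, gamma = g,
                 kernel = config$kernel, coef0 = config$coef0,
                 degree = config$degree, std = std,
                 sv = Xs[sv, , drop = FALSE], coefs = (fit$alpha * y)[sv],
                 rho = fit$rho, calibration = calib,
                 train_dec_range = range(dec_train),
                 feature_names = colnames(X), n_train = nrow(X),
                 format_version = 1L),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %s kernel, C = %g, gamma = %g, %d SVs, %d features%s\n",
              x$kernel, x$cost, x$gamma, nrow(x$sv), length(x$feature_names),
              if (is.null(x$calibration)) "" else ", Platt-calibrated"))
  invisible(x)
}

.decision_values <- function(model, X) {
  if (is.null(colnames(X)) ||
      !identical(colnames(X), model$feature_names)) {
    stop("feature names of the input do not match the training features")
  }
  Xs <- .apply_standardizer(X, model$std)
  K <- .kernel_matrix(Xs, model$sv, model$kernel, model$gamma, model$coef0,
                      model$degree)
  as.vector(K %*% model$coefs) - model$rho
}

#' Predict scores in [0, 1]
#'
#' With calibration on (the default), scores are Platt probabilities; with
#' calibration off, the raw margin is min-max mapped to `[0,1]` using the
#' training margin range (a documented fallback, not a probability).
#'
#' @param model An `svm_model`.
#' @param X Feature matrix whose column names match the training features.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, X) {
  dec <- .decision_values(model, X)
  if (!is.null(model$calibration)) {
    return(.platt_apply(model$calibration, dec))
  }
  r <- model$train_dec_range
  span <- max(r[2] - r[1], .Machine$double.eps)
  pmin(pmax((dec - r[1]) / span, 0), 1)
}

#' @export
predict.svm_model <- function(object, newdata, type = c("score", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  s <- predict_scores(object, newdata)
  if (type == "score") s else classify(s, threshold)
}

#' Threshold scores into class calls
#'
#' Strictly-greater-than rule: a score exactly equal to the threshold is
#' called negative.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return Factor with levels `c("negative", "positive")`.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  factor(ifelse(scores > threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Grid search for (cost, gamma)
#'
#' Evaluates every `(2^i, 2^j)` pair over the config's integer log2 ranges by
#' mean cross-validated accuracy on one seeded stratified partition (shared
#' by all cells, so scores are comparable).  Ties prefer smaller cost, then
#' smaller gamma.
#'
#' @inheritParams svm_train
#' @param cv_folds Number of folds (default 5).
#' @param seed Seed for the fold partition (default from `config`).
#' @return An object of class `grid_search`: `best_cost`, `best_gamma`,
#'   `best_acc`, and `grid`, a data.frame of `(log2c, log2g, acc)` for every
#'   cell.
#' @export
grid_search <- function(X, labels, config = svm_config(), cv_folds = 5L,
                        seed = config$seed) {
  labels <- as_label_factor(labels)
  y <- .y_pm(labels)
  folds <- stratified_kfold(labels, k = cv_folds, seed = seed)
  cells <- expand.grid(log2g = config$log2_g_range,
                       log2c = config$log2_c_range)  # c varies slowest
  acc_sum <- numeric(nrow(cells))
  n_test <- 0L
  for (f in folds) {
    tr <- setdiff(seq_along(y), f)
    std <- .standardizer(X[tr, , drop = FALSE], config$standardize)
    A <- .apply_standardizer(X[tr, , drop = FALSE], std)
    B <- .apply_standardizer(X[f, , drop = FALSE], std)
    Gtr <- tcrossprod(A); Gte <- tcrossprod(B, A)
    ntr <- rowSums(A^2); nte <- rowSums(B^2)
    D2tr <- cpp_sqdist(Gtr, ntr, ntr)
    D2te <- cpp_sqdist(Gte, nte, ntr)
    n_test <- n_test + length(f)
    for (ci in seq_len(nrow(cells))) {
      cost <- 2^cells$log2c[ci]; g <- 2^cells$log2g[ci]
      Ktr <- switch(config$kernel,
        rbf = exp(-g * D2tr),
        polynomial = (g * Gtr + config$coef0)^config$degree,
        sigmoid = tanh(g * Gtr + config$coef0))
      Kte <- switch(config$kernel,
        rbf = exp(-g * D2te),
        polynomial = (g * Gte + config$coef0)^config$degree,
        sigmoid = tanh(g * Gte + config$coef0))
      fit <- .fit_kernel(Ktr, y[tr], cost, config)
      dec <- as.vector(Kte %*% (fit$alpha * y[tr])) - fit$rho
      acc_sum[ci] <- acc_sum[ci] + sum((dec > 0) == (y[f] > 0))
    }
  }
  grid <- data.frame(log2c = cells$log2c, log2g = cells$log2g,
                     acc = acc_sum / n_test)
  # ties -> smaller c then smaller g: scan in (c asc, g asc) order
  ord <- order(grid$log2c, grid$log2g)
  best <- ord[which.max(grid$acc[ord])]
  structure(list(best_cost = 2^grid$log2c[best],
                 best_gamma = 2^grid$log2g[best],
                 best_log2c = grid$log2c[best], best_log2g = grid$log2g[best],
                 best_acc = grid$acc[best], grid = grid, cv_folds = cv_folds,
                 seed = seed),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %d cells; best log2c = %d, log2g = %d (CV ACC %.4f)\n",
              nrow(x$grid), x$best_log2c, x$best_log2g, x$best_acc))
  invisible(x)
}

#' Save / load a trained model archive
#'
#' Single-file archive carrying the config, standardization parameters,
#' fitted state, feature names and a format version; loading refuses a
#' mismatched version.
#'
#' @param model An `svm_model`.
#' @param path Archive path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "svm_model")) stop("not a model archive: ", path)
  if (!identical(model$format_version, 1L)) {
    stop("unsupported model archive version: ", model$format_version)
  }
  model
}

#' Compare kernel functions on identical folds
#'
#' Runs seeded stratified CV once per kernel on the same partition, pools
#' held-out decision scores, and reports ROC / PR / AUC per kernel.
#'
#' @inheritParams grid_search
#' @param kernels Kernels to compare.
#' @return Named list per kernel with `acc`, `auc`, `roc`, `pr`.
#' @export
compare_kernels <- function(X, labels,
                            kernels = c("rbf", "polynomial", "sigmoid"),
                            config = svm_config(), cv_folds = 5L,
                            seed = config$seed) {
  labels <- as_label_factor(labels)
  y <- .y_pm(labels)
  folds <- stratified_kfold(labels, k = cv_folds, seed = seed)
  out <- list()
  for (kern in kernels) {
    cfg <- config; cfg$kernel <- kern
    scores <- numeric(length(y))
    for (f in folds) {
      tr <- setdiff(seq_along(y), f)
      m <- svm_train(X[tr, , drop = FALSE], labels[tr], cfg)
      scores[f] <- predict_scores(m, X[f, , drop = FALSE])
    }
    curves <- roc_pr(scores, labels)
    acc <- mean((scores > 0.5) == (labels == "positive"))
    out[[kern]] <- list(acc = acc, auc = curves$auc, roc = curves$roc,
                        pr = curves$pr)
  }
  out
}
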