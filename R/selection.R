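#' Per-feature one-way ANOVA F-values
#'
#' For each feature, the ratio of between-class to within-class mean squares
#' with `df_B = K - 1` and `df_w = N - K` (here K = 2 classes).  A feature
#' constant within each class but differing between classes gets an `Inf`
#' sentinel (it separates perfectly, so it ranks above every finite value);
#' a globally constant feature gets 0.
#'
#' @param X Feature matrix (samples x features).
#' @param labels Binary labels.
#' @return Numeric vector of F-values, one per column of `X`.
#' @export
anova_f_values <- function(X, labels) {
  labels <- as_label_factor(labels)
  n1 <- sum(labels == "positive"); n0 <- sum(labels == "negative")
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 samples")
  N <- n1 + n0
  gm <- colMeans(X)
  m1 <- colMeans(X[labels == "positive", , drop = FALSE])
  m0 <- colMeans(X[labels == "negative", , drop = FALSE])
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums(sweep(X[labels == "positive", , drop = FALSE], 2, m1)^2) +
         colSums(sweep(X[labels == "negative", , drop = FALSE], 2, m0)^2)
  f <- (ssb / 1) / (ssw / (N - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssb == 0] <- 0
  unname(f)
}

#' Rank features by F-value
#'
#' Stable descending sort; ties broken by ascending original index, so the
#' ranking is a deterministic function of the F-values.
#'
#' @param f_values Numeric F-values (may contain the `Inf` sentinel).
#' @return Object of class `feature_ranking`: `order` (feature indices,
#'   most important first) and `f_values` (as given).
#' @export
rank_features <- function(f_values) {
  ord <- order(-f_values, seq_along(f_values))
  structure(list(order = ord, f_values = f_values), class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features; top F = %g\n",
              length(x$order), x$f_values[x$order[1]]))
  invisible(x)
}

#' Top-ranked features as a table
#'
#' @param ranking A `feature_ranking`.
#' @param names Feature names parallel to the original feature indices.
#' @param top_n Number of rows (default 20).
#' @param path Optional TSV output path.
#' @return data.frame with columns `rank`, `feature`, `f_value`.
#' @export
top_features <- function(ranking, names, top_n = 20L, path = NULL) {
  stopifnot(top_n <= length(ranking$order))
  idx <- ranking$order[seq_len(top_n)]
  out <- data.frame(rank = seq_len(top_n), feature = names[idx],
                    f_value = ranking$f_values[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# Mean CV accuracy for nested ranking prefixes.  The fold partition is fixed
# across prefixes so trajectory differences reflect the feature set, not
# partition noise.  Squared distances / inner products are grown
# incrementally as columns are added, and each SMO solve warm-starts from
# the previous prefix's solution.
.cv_accuracy_prefixes <- function(X_ord, y_pm, sizes, folds, config) {
  acc_sum <- matrix(0, nrow = length(sizes), ncol = 1)
  n_test <- 0L
  for (f in folds) {
    tr <- setdiff(seq_along(y_pm), f)
    std <- .standardizer(X_ord[tr, , drop = FALSE], config$standardize)
    A <- .apply_standardizer(X_ord[tr, , drop = FALSE], std)
    B <- .apply_standardizer(X_ord[f, , drop = FALSE], std)
    ntr <- length(tr); nte <- length(f)
    n_test <- n_test + nte
    Gtr <- matrix(0, ntr, ntr); Gte <- matrix(0, nte, ntr)
    prev <- 0L
    alpha <- NULL
    for (si in seq_along(sizes)) {
      cols <- (prev + 1L):sizes[si]
      Ab <- A[, cols, drop = FALSE]; Bb <- B[, cols, drop = FALSE]
      Gtr <- Gtr + tcrossprod(Ab)
      Gte <- Gte + tcrossprod(Bb, Ab)
      prev <- sizes[si]
      g <- .gamma_value(config$gamma, sizes[si])
      dtr <- diag(Gtr)
      dte <- if (si == 1) rowSums(Bb^2) else dte + rowSums(Bb^2)
      Ktr <- switch(config$kernel,
        rbf = cpp_rbf_kernel(Gtr, dtr, dtr, g),
        polynomial = (g * Gtr + config$coef0)^config$degree,
        sigmoid = tanh(g * Gtr + config$coef0))
      Kte <- switch(config$kernel,
        rbf = cpp_rbf_kernel(Gte, dte, dtr, g),
        polynomial = (g * Gte + config$coef0)^config$degree,
        sigmoid = tanh(g * Gte + config$coef0))
      fit <- cpp_smo(Ktr, y_pm[tr], config$cost, config$tol,
                     .smo_max_iter(config, ntr), alpha)
      alpha <- fit$alpha
      dec <- as.vector(Kte %*% (fit$alpha * y_pm[tr])) - fit$rho
      acc_sum[si] <- acc_sum[si] + sum((dec > 0) == (y_pm[f] > 0))
    }
  }
  as.vector(acc_sum) / n_test
}

#' Sequential forward search over a feature ranking
#'
#' Grows nested prefixes of the ranking (most important first) in blocks of
#' `step` features (default 10), scoring each prefix by mean CV accuracy of
#' the classifier on one fixed seeded partition, and returns the prefix with
#' the best accuracy (ties: smallest prefix).  The final prefix is always
#' the full dimension even when it is not a multiple of `step`.
#'
#' With `refine = TRUE`, a second pass evaluates every size within one step
#' of the coarse optimum, recovering optima (such as a 26-feature subset)
#' that a pure block schedule cannot express.
#'
#' @param X Feature matrix.
#' @param labels Binary labels.
#' @param ranking A [rank_features()] result (default: ranking computed from
#'   `anova_f_values(X, labels)`).
#' @param step Block size (default 10; 1 gives an exhaustive prefix scan).
#' @param cv_folds CV folds used for scoring (default 5).
#' @param config An [svm_config()]; its fixed `cost`/`gamma` are used (no
#'   per-prefix grid search).
#' @param seed Seed for the fold partition.
#' @param refine Add a step-1 scan around the coarse optimum (default FALSE).
#' @return Object of class `sfs_result`: `trajectory` (data.frame of
#'   `size`, `acc`, sorted by size), `optimal_size`, `optimal_indices`
#'   (a prefix of `ranking$order`), `optimal_acc`.
#' @export
sfs_select <- function(X, labels, ranking = NULL, step = 10L, cv_folds = 5L,
                       config = svm_config(), seed = 1L, refine = FALSE) {
  stopifnot(step >= 1, cv_folds >= 2)
  labels <- as_label_factor(labels)
  if (is.null(ranking)) ranking <- rank_features(anova_f_values(X, labels))
  d <- ncol(X)
  y <- .y_pm(labels)
  X_ord <- X[, ranking$order, drop = FALSE]
  folds <- stratified_kfold(labels, k = cv_folds, seed = seed)
  sizes <- unique(c(seq(min(step, d), d, by = step), d))
  acc <- .cv_accuracy_prefixes(X_ord, y, sizes, folds, config)
  if (refine) {
    coarse_best <- sizes[which.max(acc)]
    extra <- setdiff(max(1, coarse_best - step + 1):min(d, coarse_best + step - 1),
                     sizes)
    if (length(extra)) {
      acc2 <- .cv_accuracy_prefixes(X_ord, y, extra, folds, config)
      sizes <- c(sizes, extra); acc <- c(acc, acc2)
      ord <- order(sizes); sizes <- sizes[ord]; acc <- acc[ord]
    }
  }
  best <- which.max(acc)  # sizes ascending: first max = smallest prefix
  structure(list(trajectory = data.frame(size = sizes, acc = acc),
                 optimal_size = sizes[best],
                 optimal_indices = ranking$order[seq_len(sizes[best])],
                 optimal_acc = acc[best], step = step, cv_folds = cv_folds,
                 seed = seed, refine = refine),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d prefixes evaluated; optimum: %d features, CV ACC %.4f\n",
              nrow(x$trajectory), x$optimal_size, x$optimal_acc))
  invisible(x)
}
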