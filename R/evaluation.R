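#' Confusion counts
#'
#' @param predicted,actual Binary label vectors of equal length (any form
#'   accepted by [as_label_factor()]).
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length")
  }
  p <- as_label_factor(predicted) == "positive"
  a <- as_label_factor(actual) == "positive"
  structure(list(TP = sum(p & a), TN = sum(!p & !a),
                 FP = sum(p & !a), FN = sum(!p & a)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/N`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A zero factor in the MCC denominator yields `MCC = 0` (standard
#' convention); an undefined Sn or Sp (empty class) is reported as `NA`,
#' not 0.
#'
#' @param counts A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named numeric vector `c(Sn, Sp, ACC, MCC)`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  N <- TP + TN + FP + FN
  if (N == 0) stop("empty confusion counts")
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / N
  den2 <- as.double(TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  mcc <- if (den2 > 0) {
    (as.double(TP) * TN - as.double(FP) * FN) / sqrt(den2)
  } else 0
  c(Sn = sn, Sp = sp, ACC = acc, MCC = mcc)
}

#' Seeded stratified k-fold partition
#'
#' Folds are disjoint, cover all indices, differ in size by at most one,
#' and hold per-class proportions within one sample of the global
#' proportions (per-class round-robin assignment with a rotating offset).
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` integer index vectors.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as_label_factor(labels)
  if (any(table(labels) < k)) {
    stop("each class must have at least k = ", k, " members")
  }
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  unname(split(seq_along(labels), assign))
}

#' ROC curve, PR curve and AUC from scores
#'
#' Threshold sweep over the distinct score values (ties grouped into one
#' sweep point); AUC by trapezoidal integration of the ROC.  The ROC starts
#' at (0,0) and ends at (1,1).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return List with `roc` (data.frame `fpr`, `tpr`), `pr` (data.frame
#'   `recall`, `precision`) and `auc`.
#' @export
roc_pr <- function(scores, labels) {
  y <- as_label_factor(labels) == "positive"
  P <- sum(y); Nn <- sum(!y)
  if (P == 0 || Nn == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # one sweep point per distinct score: index of its last occurrence
  keep <- sort(length(s) - which(!duplicated(rev(s))) + 1L)
  tp <- cumsum(yy)[keep]; fp <- cumsum(!yy)[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Nn)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  precision <- tp / (tp + fp)
  recall <- tp / P
  pr <- data.frame(recall = c(0, recall), precision = c(precision[1], precision))
  list(roc = data.frame(fpr = fpr, tpr = tpr), pr = pr, auc = auc)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold CV.  Per fold the classifier is trained on k-1 folds
#' and scored on the held-out fold; per-fold Sn/Sp/ACC/MCC are averaged
#' arithmetically, and held-out scores are pooled across folds for the
#' ROC / PR curves.
#'
#' Two selection protocols are supported.  With `nested = FALSE` (the
#' historical protocol of this predictor family) feature selection is run
#' once on the full dataset before CV, which leaks selection information
#' into the estimate; `nested = TRUE` repeats ranking + forward search
#' inside every training fold and is the statistically honest option.
#'
#' @param dataset A `labeled_dataset`, or a feature matrix (then `labels`
#'   must be given and `descriptors` is ignored).
#' @param labels Labels when `dataset` is a matrix.
#' @param descriptors Descriptor set for encoding (see [encode_dataset()]).
#' @param selection `NULL` for no feature selection, or a list of arguments
#'   for [sfs_select()] (e.g. `list(step = 10, refine = TRUE)`).
#' @param features Optional fixed feature subset (names or indices),
#'   mutually exclusive with `selection`.
#' @param config An [svm_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed controlling the partition and everything downstream.
#' @param nested Run selection inside each training fold (default FALSE).
#' @param threshold Score threshold for class calls (default 0.5).
#' @return Object of class `eval_report`: `per_fold` (data.frame), `mean`
#'   (named vector), `roc`, `pr`, `auc`, `scores`, `labels`,
#'   `selected_sizes`.
#' @export
cross_validate <- function(dataset, labels = NULL,
                           descriptors = c("binary", "kmer2", "kmer3"),
                           selection = NULL, features = NULL,
                           config = svm_config(), k = 5L, seed = 1L,
                           nested = FALSE, threshold = 0.5) {
  if (inherits(dataset, "labeled_dataset")) {
    X <- encode_dataset(dataset, descriptors)
    labels <- dataset$labels
  } else {
    X <- dataset
    if (is.null(labels)) stop("labels required when dataset is a matrix")
    labels <- as_label_factor(labels)
  }
  if (!is.null(selection) && !is.null(features)) {
    stop("give either `selection` or `features`, not both")
  }
  if (!is.null(features)) X <- X[, features, drop = FALSE]

  sel_args <- function(Xs, ls, extra_seed) {
    do.call(sfs_select, c(list(X = Xs, labels = ls, config = config,
                               seed = extra_seed), selection))
  }
  selected_sizes <- integer(0)
  if (!is.null(selection) && !nested) {
    sel <- sel_args(X, labels, seed)
    X <- X[, sel$optimal_indices, drop = FALSE]
    selected_sizes <- sel$optimal_size
  }

  folds <- stratified_kfold(labels, k = k, seed = seed)
  scores <- numeric(length(labels))
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    f <- folds[[i]]
    tr <- setdiff(seq_along(labels), f)
    if (length(unique(labels[tr])) < 2) stop("training part of fold ", i,
                                             " is single-class")
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[f, , drop = FALSE]
    if (!is.null(selection) && nested) {
      sel <- sel_args(Xtr, labels[tr], seed + i)
      Xtr <- Xtr[, sel$optimal_indices, drop = FALSE]
      Xte <- Xte[, sel$optimal_indices, drop = FALSE]
      selected_sizes <- c(selected_sizes, sel$optimal_size)
    }
    m <- svm_train(Xtr, labels[tr], config)
    sc <- predict_scores(m, Xte)
    scores[f] <- sc
    calls <- if (config$probability) classify(sc, threshold) else
      factor(ifelse(.decision_values(m, Xte) > 0, "positive", "negative"),
             levels = c("negative", "positive"))
    per_fold[[i]] <- classification_metrics(confusion(calls, labels[f]))
  }
  per_fold <- data.frame(fold = seq_len(k), do.call(rbind, per_fold))
  mean_metrics <- colMeans(per_fold[, c("Sn", "Sp", "ACC", "MCC")])
  curves <- roc_pr(scores, labels)
  structure(list(per_fold = per_fold, mean = mean_metrics,
                 roc = curves$roc, pr = curves$pr, auc = curves$auc,
                 scores = scores, labels = labels,
                 selected_sizes = selected_sizes, k = k, seed = seed,
                 nested = nested),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV%s: ACC %.4f, Sn %.4f, Sp %.4f, MCC %.4f, AUC %.4f\n",
              x$k, if (x$nested) " (nested selection)" else "",
              x$mean["ACC"], x$mean["Sn"], x$mean["Sp"], x$mean["MCC"], x$auc))
  invisible(x)
}

#' Write an evaluation report to files
#'
#' `metrics.json` (per-fold + mean metrics, AUC), `roc.tsv`, `pr.tsv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(per_fold = report$per_fold, mean = as.list(report$mean),
         auc = report$auc, k = report$k, seed = report$seed,
         nested = report$nested,
         selected_sizes = report$selected_sizes),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write.table(report$roc, file.path(dir, "roc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$pr, file.path(dir, "pr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Positional nucleotide enrichment between two window sets
#'
#' Numeric analog of a two-sample logo: per position and nucleotide, the
#' frequency in positives, in negatives, their difference, and a
#' two-proportion z-test p-value (plus Bonferroni correction across all
#' `L x 4` tests).
#'
#' @param positives,negatives Character vectors of equal-length windows, or
#'   a single `labeled_dataset` as `positives` (then `negatives` is taken
#'   from its labels).
#' @return data.frame with columns `position`, `nucleotide`, `freq_pos`,
#'   `freq_neg`, `diff`, `p_value`, `p_bonferroni`.
#' @export
position_enrichment <- function(positives, negatives = NULL) {
  if (inherits(positives, "labeled_dataset")) {
    ds <- positives
    negatives <- ds$seqs[ds$labels == "negative"]
    positives <- ds$seqs[ds$labels == "positive"]
  }
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("both sets must be non-empty")
  }
  L <- nchar(positives[[1]])
  if (any(nchar(c(positives, negatives)) != L)) {
    stop("all windows must have equal length")
  }
  count_mat <- function(seqs) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                           use.names = FALSE), nrow = length(seqs),
                    byrow = TRUE)
    vapply(.RNA_ALPHABET, function(nt) colSums(chars == nt),
           numeric(L))  # L x 4
  }
  cp <- count_mat(positives); cn <- count_mat(negatives)
  np <- length(positives); nn <- length(negatives)
  fp <- cp / np; fn <- cn / nn
  pooled <- (cp + cn) / (np + nn)
  se <- sqrt(pooled * (1 - pooled) * (1 / np + 1 / nn))
  z <- (fp - fn) / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0] <- 1  # identical, degenerate proportion
  out <- data.frame(
    position = rep(seq_len(L), times = 4),
    nucleotide = rep(.RNA_ALPHABET, each = L),
    freq_pos = as.vector(fp), freq_neg = as.vector(fn),
    diff = as.vector(fp - fn), p_value = as.vector(p),
    stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out[order(out$position, out$nucleotide), , drop = FALSE]
}
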