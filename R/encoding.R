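#' All k-mers over the RNA alphabet in lexicographic order
#'
#' Lexicographic over `A < C < G < U`, first character most significant:
#' `AA, AC, AG, AU, CA, ...` for k = 2.
#'
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1)
  out <- .RNA_ALPHABET
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, .RNA_ALPHABET, paste0)))
  out
}

.as_seq <- function(window) {
  if (inherits(window, "site_window")) window$seq else as.character(window)
}

#' k-mer spectrum of a window
#'
#' Occurrence frequency of every length-k substring, scanned with step 1.
#' The denominator is the number of k-windows, `L - k + 1`, so the spectrum
#' sums to exactly 1 for any valid window.
#'
#' @param window A `site_window` or sequence string over `{A,C,G,U}`.
#' @param k k-mer length, `1 <= k < L`.
#' @return Named numeric vector of length `4^k` (names from [kmer_names()]).
#' @examples
#' kmer_spectrum("ACGU", 2)[c("AC", "CG", "GU")]
#' @export
kmer_spectrum <- function(window, k) {
  seq <- .as_seq(window)
  L <- nchar(seq)
  if (k >= L) stop("k must be smaller than the window length")
  starts <- seq_len(L - k + 1L)
  subs <- substring(seq, starts, starts + k - 1L)
  lev <- kmer_names(k)
  counts <- tabulate(factor(subs, levels = lev), nbins = length(lev))
  stats::setNames(counts / (L - k + 1L), lev)
}

#' Positional one-hot (binary) encoding of a window
#'
#' Each position contributes a 4-bit block; the codes are
#' `A = 0001`, `U = 0010`, `C = 0100`, `G = 1000` (most significant bit
#' first), so a block reads `(isG, isC, isU, isA)`.  Features are named
#' `b1 ... b(4L)`, with position p occupying `b(4p-3) ... b(4p)`.
#'
#' @inheritParams kmer_spectrum
#' @return Named numeric 0/1 vector of length `4 * L`.
#' @export
binary_encoding <- function(window) {
  seq <- .as_seq(window)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  code <- rbind(G = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                U = c(0, 0, 1, 0), A = c(0, 0, 0, 1))
  out <- as.vector(t(code[chars, , drop = FALSE]))
  stats::setNames(out, paste0("b", seq_len(4L * L)))
}

#' Feature names for a descriptor set
#'
#' Pure function of window length and descriptor selection; never depends on
#' data.  Descriptor order is fixed: binary, then 2-mer, then 3-mer.
#'
#' @param L Window length.
#' @param descriptors Subset of `c("binary", "kmer2", "kmer3")`.
#' @return Character vector of column names.
#' @export
feature_names <- function(L = 41L, descriptors = c("binary", "kmer2", "kmer3")) {
  descriptors <- .check_descriptors(descriptors)
  out <- character(0)
  if ("binary" %in% descriptors) out <- c(out, paste0("b", seq_len(4L * L)))
  if ("kmer2" %in% descriptors) out <- c(out, kmer_names(2))
  if ("kmer3" %in% descriptors) out <- c(out, kmer_names(3))
  out
}

.check_descriptors <- function(descriptors) {
  valid <- c("binary", "kmer2", "kmer3")
  if (length(descriptors) == 0) stop("at least one descriptor must be selected")
  bad <- setdiff(descriptors, valid)
  if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  valid[valid %in% descriptors]  # canonical order
}

#' Encode one window as the full feature vector
#'
#' Concatenates the positional binary code (4L entries), the 2-mer spectrum
#' (16) and the 3-mer spectrum (64).  For the standard 41-nt window this is
#' the 244-dimensional encoding (41 x 4 + 4^2 + 4^3).
#'
#' @inheritParams kmer_spectrum
#' @param L Expected window length (default 41).
#' @return Named numeric vector of length `4L + 80`.
#' @export
encode_window <- function(window, L = 41L) {
  seq <- .as_seq(window)
  if (nchar(seq) != L) {
    stop("window has length ", nchar(seq), ", expected ", L)
  }
  c(binary_encoding(seq), kmer_spectrum(seq, 2L), kmer_spectrum(seq, 3L))
}

#' Encode a dataset as a feature matrix
#'
#' @param dataset A `labeled_dataset`, or a character vector of window
#'   sequences (optionally named with sample ids).
#' @param descriptors Subset of `c("binary", "kmer2", "kmer3")`; columns
#'   always appear in that fixed order regardless of the order given.
#' @return Numeric matrix, samples x features, with sample ids as rownames
#'   and stable column names from [feature_names()].
#' @export
encode_dataset <- function(dataset, descriptors = c("binary", "kmer2", "kmer3")) {
  descriptors <- .check_descriptors(descriptors)
  if (inherits(dataset, "labeled_dataset")) {
    seqs <- dataset$seqs; ids <- dataset$ids
  } else {
    seqs <- as.character(dataset)
    ids <- if (!is.null(names(dataset))) names(dataset) else
      paste0("s", seq_along(seqs))
  }
  if (length(seqs) == 0L) stop("empty dataset")
  L <- nchar(seqs[[1]])
  blocks <- list()
  if ("binary" %in% descriptors) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
    bin <- matrix(0, nrow = length(seqs), ncol = 4L * L)
    for (b in 1:4) {  # block layout (isG, isC, isU, isA)
      nt <- c("G", "C", "U", "A")[b]
      bin[, seq(b, 4L * L, by = 4L)] <- (chars == nt) + 0
    }
    blocks$binary <- bin
  }
  if ("kmer2" %in% descriptors) {
    blocks$kmer2 <- t(vapply(seqs, kmer_spectrum, numeric(16), k = 2L,
                             USE.NAMES = FALSE))
  }
  if ("kmer3" %in% descriptors) {
    blocks$kmer3 <- t(vapply(seqs, kmer_spectrum, numeric(64), k = 3L,
                             USE.NAMES = FALSE))
  }
  X <- do.call(cbind, blocks)
  dimnames(X) <- list(ids, feature_names(L, descriptors))
  X
}

#' Write a feature matrix to TSV
#'
#' Header row carries the feature names; the first column (`sample`) carries
#' row ids.
#'
#' @param X Feature matrix from [encode_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(sample = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
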