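#' Read a FASTA file of RNA windows
#'
#' Parses a (possibly multi-line) FASTA file.  Record ids are the header up
#' to the first whitespace; sequence lines are concatenated and upper-cased.
#' Records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGUA", ">s2", "GGGCC"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(nonblank[[1]], ">")) {
    stop("malformed FASTA: sequence data before any '>' header in ", path)
  }
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  data.frame(id = ids, seq = toupper(as.character(recs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write windows to a FASTA file
#'
#' Round-trip property: `read_fasta(write_fasta(x, p))` reproduces ids (up to
#' the first whitespace) and sequences exactly.
#'
#' @param x A `labeled_dataset`, a data.frame with `id`/`seq` columns, or a
#'   named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "labeled_dataset")) {
    ids <- x$ids; seqs <- x$seqs
  } else if (is.data.frame(x)) {
    ids <- x$id; seqs <- x$seq
  } else {
    ids <- names(x); seqs <- unname(x)
  }
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

.RNA_ALPHABET <- c("A", "C", "G", "U")

# Normalisation + validation kernel shared by site_window() and the loaders.
# Returns list(ok, seq, reason) with reason in {bad_length, bad_alphabet,
# bad_center} -- machine-readable, as downstream reject reports rely on it.
.check_window <- function(raw, L = 41L, require_center_c = TRUE) {
  seq <- chartr("t", "u", toupper(raw))
  seq <- chartr("T", "U", seq)
  if (nchar(seq) != L) return(list(ok = FALSE, seq = seq, reason = "bad_length"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% .RNA_ALPHABET)) {
    return(list(ok = FALSE, seq = seq, reason = "bad_alphabet"))
  }
  center <- (L + 1L) %/% 2L
  if (require_center_c && chars[center] != "C") {
    return(list(ok = FALSE, seq = seq, reason = "bad_center"))
  }
  list(ok = TRUE, seq = seq, reason = NA_character_)
}

#' Construct a validated site window
#'
#' Normalises a raw sequence (upper-case, DNA-style `T` mapped to `U`) and
#' validates it as a fixed-length RNA window with the candidate cytosine at
#' the central position (1-based position `(L+1)/2`, i.e. 21 for the default
#' 41-nt window).  Ambiguity codes such as `N` are rejected: the downstream
#' encoding has no defined column for them.
#'
#' @param id Record identifier.
#' @param seq Raw sequence string.
#' @param L Window length (odd; default 41).
#' @param require_center_c Require `C` at the central position (default TRUE).
#' @return An object of class `site_window`: a list with `id`, `seq`,
#'   `center_index`.
#' @section Errors: rejection raises a condition of class
#'   `rnahmc_validation_error` whose `reason` field is one of `bad_length`,
#'   `bad_alphabet`, `bad_center`.
#' @export
site_window <- function(id, seq, L = 41L, require_center_c = TRUE) {
  if (L %% 2L == 0L) stop("window length L must be odd")
  if (!nzchar(seq)) stop("empty sequence for record ", id)
  v <- .check_window(seq, L = L, require_center_c = require_center_c)
  if (!v$ok) {
    cond <- structure(
      class = c("rnahmc_validation_error", "error", "condition"),
      list(message = sprintf("window '%s' rejected: %s", id, v$reason),
           call = sys.call(-1), reason = v$reason, id = id))
    stop(cond)
  }
  structure(list(id = id, seq = v$seq, center_index = (L + 1L) %/% 2L),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s (%d nt, center %d = %s)\n", x$id,
              nchar(x$seq), x$center_index,
              substr(x$seq, x$center_index, x$center_index)))
  invisible(x)
}

#' Construct a labeled dataset of site windows
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of validated window sequences (parallel).
#' @param labels Vector coercible to a factor with levels
#'   `c("negative", "positive")`; accepts 0/1, logical, or those strings.
#' @param provenance Free-text source description.
#' @param L Window length.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(ids, seqs, labels, provenance = "", L = 41L) {
  stopifnot(length(ids) == length(seqs), length(ids) == length(labels))
  if (anyDuplicated(ids)) stop("duplicate ids in dataset")
  labels <- as_label_factor(labels)
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 labels = labels, provenance = provenance, L = L),
            class = "labeled_dataset")
}

#' Coerce labels to the canonical negative/positive factor
#' @param x Labels as 0/1, logical, or "positive"/"negative" strings.
#' @return Factor with levels `c("negative", "positive")`.
#' @export
as_label_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "positive", "negative")
  if (is.numeric(x)) {
    stopifnot(all(x %in% c(0, 1)))
    x <- ifelse(x == 1, "positive", "negative")
  }
  if (!all(x %in% c("negative", "positive"))) {
    stop("labels must be 0/1, logical, or 'positive'/'negative'")
  }
  factor(x, levels = c("negative", "positive"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d windows of %d nt (%d positive, %d negative)\n",
              length(x$ids), x$L, sum(x$labels == "positive"),
              sum(x$labels == "negative")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$ids)

#' Subset a labeled dataset by sample index
#' @param x A `labeled_dataset`.
#' @param i Integer or logical index.
#' @param ... Ignored.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  labeled_dataset(x$ids[i], x$seqs[i], x$labels[i],
                  provenance = x$provenance, L = x$L)
}

# Validate a data.frame of raw records; returns list(kept = data.frame,
# rejects = data.frame(id, reason)).
.validate_records <- function(recs, L, require_center_c) {
  if (nrow(recs) == 0L) {
    return(list(kept = recs,
                rejects = data.frame(id = character(0), reason = character(0))))
  }
  checks <- lapply(recs$seq, .check_window, L = L,
                   require_center_c = require_center_c)
  ok <- vapply(checks, `[[`, logical(1), "ok")
  kept <- data.frame(id = recs$id[ok],
                     seq = vapply(checks[ok], `[[`, character(1), "seq"),
                     stringsAsFactors = FALSE)
  rejects <- data.frame(id = recs$id[!ok],
                        reason = vapply(checks[!ok], `[[`, character(1), "reason"),
                        stringsAsFactors = FALSE)
  list(kept = kept, rejects = rejects)
}

#' Load a labeled dataset from a positive and a negative FASTA file
#'
#' Records failing validation are dropped with a message (or abort the run
#' under `strict = TRUE`).  Ids duplicated across the two files are an error
#' under `strict = TRUE` and are suffix-deduplicated (`id.1`, `id.2`, ...)
#' otherwise.
#'
#' @param pos_path FASTA file of positive (5hmC) windows.
#' @param neg_path FASTA file of negative windows.
#' @param L Window length (default 41).
#' @param require_center_c Require the central base to be `C` (default TRUE).
#' @param strict Abort on any invalid record or duplicate id (default FALSE).
#' @return A `labeled_dataset`.
#' @export
load_labeled_dataset <- function(pos_path, neg_path, L = 41L,
                                 require_center_c = TRUE, strict = FALSE) {
  pos <- .validate_records(read_fasta(pos_path), L, require_center_c)
  neg <- .validate_records(read_fasta(neg_path), L, require_center_c)
  n_bad <- nrow(pos$rejects) + nrow(neg$rejects)
  if (n_bad > 0) {
    if (strict) {
      stop(n_bad, " invalid record(s); first: ",
           c(pos$rejects$id, neg$rejects$id)[1], " (",
           c(pos$rejects$reason, neg$rejects$reason)[1], ")")
    }
    message("dropped ", n_bad, " invalid record(s) (",
            nrow(pos$rejects), " positive, ", nrow(neg$rejects), " negative)")
  }
  if (nrow(pos$kept) == 0L) stop("no valid positive records in ", pos_path)
  if (nrow(neg$kept) == 0L) stop("no valid negative records in ", neg_path)
  ids <- c(pos$kept$id, neg$kept$id)
  if (anyDuplicated(ids)) {
    if (strict) stop("duplicate ids across positive/negative files")
    ids <- make.unique(ids, sep = ".")
  }
  labeled_dataset(
    ids, c(pos$kept$seq, neg$kept$seq),
    rep(c("positive", "negative"), c(nrow(pos$kept), nrow(neg$kept))),
    provenance = sprintf("pos=%s; neg=%s", pos_path, neg_path), L = L)
}

#' Load a labeled dataset from one FASTA plus a two-column label table
#'
#' @param fasta_path FASTA file of windows.
#' @param labels_path TSV with columns `id` and `label` (1 = positive,
#'   0 = negative); a header line is optional.
#' @inheritParams load_labeled_dataset
#' @return A `labeled_dataset`.
#' @export
load_labeled_tsv <- function(fasta_path, labels_path, L = 41L,
                             require_center_c = TRUE, strict = FALSE) {
  tab <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "label"))
  if (identical(tolower(tab$id[1]), "id")) tab <- tab[-1, , drop = FALSE]
  tab$label <- as.integer(tab$label)
  v <- .validate_records(read_fasta(fasta_path), L, require_center_c)
  if (nrow(v$rejects) > 0) {
    if (strict) stop(nrow(v$rejects), " invalid record(s)")
    message("dropped ", nrow(v$rejects), " invalid record(s)")
  }
  idx <- match(v$kept$id, tab$id)
  if (anyNA(idx)) stop("ids missing from label table: ",
                       paste(head(v$kept$id[is.na(idx)], 3), collapse = ", "))
  labeled_dataset(v$kept$id, v$kept$seq, tab$label[idx],
                  provenance = sprintf("fasta=%s; labels=%s", fasta_path,
                                       labels_path), L = L)
}
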