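# Reading, writing and tokenizing clinical records, knowledge documents and
# label vocabularies.
#
# Records are stored as line-delimited JSON with keys `id`, `text`,
# `labels` (array) and optional `numeric` (object of feature -> raw string).
# Knowledge documents are one UTF-8 .txt file per medical concept, the file
# name (without extension) being the concept id.  A label vocabulary is a
# plain text file with one label per line; line order defines the columns
# of every score matrix.

#' Whitespace tokenizer
#'
#' Splits a sentence into tokens on runs of whitespace.  This is the default
#' pluggable tokenizer; corpora in other languages (e.g. unsegmented Chinese
#' clinical text) can supply their own function of the same shape.
#'
#' @param x Character scalar, one sentence.
#' @return Character vector of non-empty tokens.
#' @export
whitespace_tokenizer <- function(x) {
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Split a document into sentences of tokens
#'
#' Truncates the raw text to `max_chars` characters (documents are capped by
#' total character count, mirroring the 1600-character cap used for clinical
#' records), splits it into sentences on sentence-final punctuation
#' (`。！？.!?`), tokenizes each sentence with the pluggable
#' tokenizer and drops empty sentences.
#'
#' @param text Character scalar (may be empty).
#' @param tokenizer Function mapping a sentence string to a token vector.
#' @param max_chars Positive integer, maximum number of characters retained.
#' @return List of character vectors, one per non-empty sentence.
#' @export
tokenize_hierarchical <- function(text, tokenizer = whitespace_tokenizer,
                                  max_chars = 1600L) {
  stopifnot(max_chars > 0)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(list())
  text <- substr(text, 1L, max_chars)
  sents <- strsplit(text, "[。！？.!?]+")[[1]]
  out <- lapply(sents, tokenizer)
  out[lengths(out) > 0L]
}

#' Read a label vocabulary
#'
#' @param path Path to a text file with one label per line (order matters:
#'   it fixes the column layout of score matrices).
#' @return Character vector of labels.
#' @export
read_label_vocab <- function(path) {
  labs <- readLines(path, encoding = "UTF-8", warn = FALSE)
  labs <- trimws(labs)
  labs <- labs[nzchar(labs)]
  if (anyDuplicated(labs)) {
    stop("duplicate labels in vocabulary: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  labs
}

#' @rdname read_label_vocab
#' @param labels Character vector of labels to write.
#' @export
write_label_vocab <- function(labels, path) {
  writeLines(labels, path, useBytes = TRUE)
  invisible(path)
}

#' Read clinical records from a JSONL file
#'
#' Each line holds one record object with keys `id`, `text`, `labels` and
#' optionally `numeric`.  Labels are validated against the label vocabulary;
#' a record citing an unknown label is an error naming the record and label.
#'
#' @param path Path to the JSONL file.
#' @param label_vocab Character vector of admissible labels.
#' @return List of records; each record is a list with elements `record_id`,
#'   `text`, `labels` (character) and `numeric_raw` (named character).
#' @export
read_records <- function(path, label_vocab) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) stop("malformed record on line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    labs <- as.character(unlist(rec$labels))
    bad <- setdiff(labs, label_vocab)
    if (length(bad)) {
      stop("record '", rec$id, "' (line ", i, ") has unknown label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    num <- rec$numeric
    num <- if (is.null(num)) character(0) else
      vapply(num, function(x) as.character(x)[1], "")
    out[[i]] <- list(record_id = as.character(rec$id),
                     text = if (is.null(rec$text)) "" else as.character(rec$text),
                     labels = labs,
                     numeric_raw = num,
                     line = i)
  }
  out
}

#' Write clinical records to a JSONL file
#'
#' Inverse of [read_records()]: the written file reads back to records with
#' the same ids, text, label sets and numeric fields.
#'
#' @param records List of records as returned by [read_records()] or
#'   [generate_corpus()].
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    obj <- list(id = r$record_id, text = r$text, labels = I(r$labels))
    if (length(r$numeric_raw)) obj$numeric <- as.list(r$numeric_raw)
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read knowledge documents from a directory
#'
#' @param dir Directory of UTF-8 `.txt` files, one per medical concept;
#'   the file name without extension is the concept id.
#' @return List of knowledge documents (`concept_id`, `text`).
#' @export
read_knowledge_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt knowledge documents under ", dir)
  lapply(files, function(f) {
    list(concept_id = tools::file_path_sans_ext(basename(f)),
         text = paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                      collapse = " "))
  })
}

#' @rdname read_knowledge_dir
#' @param knowledge List of knowledge documents.
#' @export
write_knowledge_dir <- function(knowledge, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in knowledge) {
    writeLines(k$text, file.path(dir, paste0(k$concept_id, ".txt")),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Build a token vocabulary
#'
#' Indices are contiguous from 0: padding takes index 0, unknown tokens
#' index 1, and corpus tokens with count at least `min_count` follow,
#' ordered by descending count with lexicographic tie-break (so the map is
#' deterministic and independent of record order).
#'
#' @param records List of records (tokenized via [tokenize_hierarchical()]).
#' @param knowledge List of knowledge documents included in the vocabulary.
#' @param min_count Minimum corpus count for a token to receive its own
#'   index; rarer tokens map to the unknown index.
#' @param tokenizer,max_chars Passed to [tokenize_hierarchical()].
#' @return A `token_vocab` object: list with `index` (named integer map),
#'   `pad` (0), `unk` (1) and `size`.
#' @export
build_vocab <- function(records, knowledge = list(), min_count = 1L,
                        tokenizer = whitespace_tokenizer, max_chars = 1600L) {
  texts <- c(vapply(records, function(r) r$text, ""),
             vapply(knowledge, function(k) k$text, ""))
  toks <- unlist(lapply(texts, function(tx)
    unlist(tokenize_hierarchical(tx, tokenizer, max_chars))))
  if (!length(toks)) stop("empty corpus: no tokens to build a vocabulary from")
  cnt <- table(toks)
  keep <- cnt[cnt >= max(min_count, 1L)]
  ord <- order(-as.integer(keep), names(keep))
  terms <- names(keep)[ord]
  idx <- seq_along(terms) + 1L          # 0 = pad, 1 = unk
  names(idx) <- terms
  structure(list(index = idx, pad = 0L, unk = 1L, size = length(terms) + 2L),
            class = "token_vocab")
}

#' Map tokens to vocabulary indices
#'
#' @param tokens Character vector.
#' @param vocab A `token_vocab`.
#' @return Integer vector; out-of-vocabulary tokens get the unknown index.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- vocab$unk
  as.integer(ids)
}

#' Pad a batch of tokenized documents to a fixed tensor
#'
#' Documents are truncated/padded to `max_sents` sentences of `max_words`
#' tokens (truncation keeps the leading sentences and words, since clinical
#' chief complaints lead the document).  The mask is 1 exactly on surviving
#' real tokens.
#'
#' @param docs List of tokenized documents (each a list of token vectors).
#' @param vocab A `token_vocab`.
#' @param max_sents,max_words Positive integer limits.
#' @return List with `ids` and `mask`, both arrays of dim
#'   `(length(docs), max_sents, max_words)`.
#' @export
pad_batch <- function(docs, vocab, max_sents = 30L, max_words = 50L) {
  stopifnot(max_sents > 0, max_words > 0)
  n <- length(docs)
  ids <- array(vocab$pad, dim = c(n, max_sents, max_words))
  mask <- array(0, dim = c(n, max_sents, max_words))
  for (d in seq_len(n)) {
    sents <- docs[[d]]
    for (i in seq_len(min(length(sents), max_sents))) {
      w <- tokens_to_ids(sents[[i]], vocab)
      t <- min(length(w), max_words)
      if (t > 0L) {
        ids[d, i, seq_len(t)] <- w[seq_len(t)]
        mask[d, i, seq_len(t)] <- 1
      }
    }
  }
  list(ids = ids, mask = mask)
}

#' @export
print.token_vocab <- function(x, ...) {
  cat("Token vocabulary:", x$size, "indices (pad=0, unk=1,",
      x$size - 2L, "tokens)\n")
  invisible(x)
}
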