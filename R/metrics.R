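# Example-based multilabel ranking metrics.
#
# All five metrics follow the standard example-based definitions: a score
# matrix S (n records x c labels) is compared to a binary relevance matrix
# Y of the same shape; per-record values are averaged over records.  Ranks
# are 1-based by decreasing score with ties broken by label index (stable),
# except in ranking loss where a tied (relevant, irrelevant) pair counts
# one half.  Records violating a metric's precondition (no relevant label;
# for ranking loss additionally no irrelevant label) are skipped and
# counted, not errors: synthetic corpora can produce them.

check_sy <- function(scores, gold) {
  scores <- as.matrix(scores); gold <- as.matrix(gold)
  if (!all(dim(scores) == dim(gold))) stop("scores and gold differ in shape")
  if (anyNA(scores) || anyNA(gold)) stop("NA in scores or gold")
  list(s = scores, y = gold != 0)
}

rank_row <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s)); r[ord] <- seq_along(s)
  r
}

#' Example-based average precision
#'
#' For each record with at least one relevant label: the mean, over its
#' relevant labels, of the precision at that label's rank (the fraction of
#' labels ranked at or above it that are relevant); averaged over records.
#'
#' @param scores n x c score matrix.
#' @param gold n x c binary relevance matrix.
#' @return Average precision in `[0, 1]`; attribute `"skipped"` counts
#'   records excluded for having no relevant label.
#' @export
average_precision <- function(scores, gold) {
  z <- check_sy(scores, gold)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(z$s))) {
    rel <- which(z$y[i, ])
    if (!length(rel)) { skipped <- skipped + 1L; next }
    r <- rank_row(z$s[i, ])
    vals <- c(vals, mean(vapply(rel, function(l)
      sum(r[rel] <= r[l]) / r[l], 0)))
  }
  structure(if (length(vals)) mean(vals) else NaN, skipped = skipped)
}

#' One-error
#'
#' Fraction of records whose single top-ranked label is not relevant.
#'
#' @inheritParams average_precision
#' @return Value in `[0, 1]` with a `"skipped"` attribute.
#' @export
one_error <- function(scores, gold) {
  z <- check_sy(scores, gold)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(z$s))) {
    if (!any(z$y[i, ])) { skipped <- skipped + 1L; next }
    top <- order(-z$s[i, ], seq_len(ncol(z$s)))[1]
    vals <- c(vals, as.numeric(!z$y[i, top]))
  }
  structure(if (length(vals)) mean(vals) else NaN, skipped = skipped)
}

#' Hamming loss
#'
#' Fraction of (record, label) cells where the thresholded prediction
#' (score strictly greater than `tau`) disagrees with the gold label.
#'
#' @inheritParams average_precision
#' @param tau Decision threshold (default 0.5).
#' @return Value in `[0, 1]`.
#' @export
hamming_loss <- function(scores, gold, tau = 0.5) {
  z <- check_sy(scores, gold)
  mean((z$s > tau) != z$y)
}

#' Ranking loss
#'
#' Per record, the fraction of (relevant, irrelevant) label pairs where the
#' relevant label does not outscore the irrelevant one; tied pairs count
#' one half.  Records lacking either a relevant or an irrelevant label are
#' skipped.
#'
#' @inheritParams average_precision
#' @return Value in `[0, 1]` with a `"skipped"` attribute.
#' @export
ranking_loss <- function(scores, gold) {
  z <- check_sy(scores, gold)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(z$s))) {
    rel <- z$s[i, z$y[i, ]]
    irr <- z$s[i, !z$y[i, ]]
    if (!length(rel) || !length(irr)) { skipped <- skipped + 1L; next }
    d <- outer(rel, irr, "-")
    vals <- c(vals, (sum(d < 0) + 0.5 * sum(d == 0)) / length(d))
  }
  structure(if (length(vals)) mean(vals) else NaN, skipped = skipped)
}

#' Coverage
#'
#' Per record, how far down the score-ranked label list one must go to
#' capture every relevant label, minus one (so a single relevant label
#' ranked first gives 0); averaged over records with at least one relevant
#' label.
#'
#' @inheritParams average_precision
#' @return Value in `[0, c - 1]` with a `"skipped"` attribute.
#' @export
coverage <- function(scores, gold) {
  z <- check_sy(scores, gold)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(z$s))) {
    rel <- which(z$y[i, ])
    if (!length(rel)) { skipped <- skipped + 1L; next }
    r <- rank_row(z$s[i, ])
    vals <- c(vals, max(r[rel]) - 1)
  }
  structure(if (length(vals)) mean(vals) else NaN, skipped = skipped)
}

#' All five multilabel metrics at once
#'
#' @inheritParams hamming_loss
#' @return A data frame with one row and columns `average_precision`,
#'   `one_error`, `hamming_loss`, `ranking_loss`, `coverage`, plus a
#'   `"skipped"` attribute with the per-metric skip counts.
#' @export
multilabel_metrics <- function(scores, gold, tau = 0.5) {
  ap <- average_precision(scores, gold)
  oe <- one_error(scores, gold)
  hl <- hamming_loss(scores, gold, tau)
  rl <- ranking_loss(scores, gold)
  cv <- coverage(scores, gold)
  out <- data.frame(average_precision = as.numeric(ap),
                    one_error = as.numeric(oe),
                    hamming_loss = as.numeric(hl),
                    ranking_loss = as.numeric(rl),
                    coverage = as.numeric(cv))
  attr(out, "skipped") <- c(average_precision = attr(ap, "skipped"),
                            one_error = attr(oe, "skipped"),
                            ranking_loss = attr(rl, "skipped"),
                            coverage = attr(cv, "skipped"))
  out
}

#' Write / read a score matrix as TSV
#'
#' Rows are records (first column `record_id`), remaining columns one per
#' label in vocabulary order.
#'
#' @param scores Numeric matrix with rownames = record ids and colnames =
#'   labels.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(record_id = rownames(scores), scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
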