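# Knowledge attention module.
#
# Stage 1 (knowledge filter): records and knowledge documents are embedded
# in a TF-IDF vector space; knowledge documents whose cosine similarity to
# the record falls below a threshold (default 0.5) are considered
# irrelevant and pruned.  TF(x) = N(x)/N is the relative frequency of word
# x in the document; the inverse document frequency is smoothed,
# IDF(x) = log((1 + D) / (1 + D(x))) + 1, so that domain words appearing
# in every document still keep a usable weight.
#
# Stage 2 (knowledge aggregator): surviving knowledge documents, encoded
# by the shared document encoder, are scored against the record embedding
# e' by a learned attention (bilinear by default), softmax-normalised, and
# the top-k documents are fused into the aggregated knowledge embedding
# k'; fewer than k survivors are padded with zero vectors.

#' Fit a TF-IDF model
#'
#' @param documents List of token vectors (records and knowledge documents
#'   together form the fitting corpus).
#' @return A `tfidf_model` with the document count `D`, per-word document
#'   frequencies and smoothed IDF values.
#' @export
tfidf_fit <- function(documents) {
  if (!length(documents)) stop("tfidf_fit: no documents")
  if (all(lengths(documents) == 0L)) stop("tfidf_fit: all documents are empty")
  D <- length(documents)
  df <- table(unlist(lapply(documents, unique)))
  idf <- log((1 + D) / (1 + as.numeric(df))) + 1
  names(idf) <- names(df)
  structure(list(D = D, df = as.integer(df), idf = idf,
                 terms = names(df)), class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("TF-IDF model: ", x$D, " documents, ", length(x$terms), " terms\n",
      sep = "")
  invisible(x)
}

#' TF-IDF vector of a document
#'
#' Component for word x is `TF(x) * IDF(x)` with TF the within-document
#' relative frequency; out-of-vocabulary words are ignored.
#'
#' @param document Token vector.
#' @param model A `tfidf_model`.
#' @return Named numeric vector over the document's in-vocabulary words
#'   (empty documents give a zero-length vector).
#' @export
tfidf_vector <- function(document, model) {
  if (!length(document)) return(stats::setNames(numeric(0), character(0)))
  tf <- table(document) / length(document)
  keep <- intersect(names(tf), model$terms)
  if (!length(keep)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(tf[keep]) * model$idf[keep], keep)
}

#' Cosine similarity
#'
#' For named (sparse-style) vectors, components are aligned by name; for
#' unnamed vectors the two must have equal length.  If either vector has
#' zero norm the similarity is defined as 0.
#'
#' @param u,v Numeric vectors, named or unnamed.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (!is.null(names(u)) || !is.null(names(v))) {
    common <- intersect(names(u), names(v))
    num <- if (length(common)) sum(u[common] * v[common]) else 0
  } else {
    stopifnot(length(u) == length(v))
    num <- sum(u * v)
  }
  den <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  if (den == 0) return(0)
  num / den
}

#' Filter knowledge documents by TF-IDF cosine similarity
#'
#' Knowledge documents with cosine similarity to the record below the
#' threshold are considered irrelevant and dropped; the rule keeps
#' documents with similarity greater than or equal to the threshold.
#'
#' @param record_tokens Token vector of the (truncated) record text.
#' @param knowledge_tokens Named list of token vectors, one per concept.
#' @param model A fitted `tfidf_model`.
#' @param threshold Similarity cutoff (default 0.5).
#' @return Data frame with `concept_id`, `cosine` and `kept`.
#' @export
filter_knowledge <- function(record_tokens, knowledge_tokens, model,
                             threshold = 0.5) {
  rv <- tfidf_vector(record_tokens, model)
  cos <- vapply(knowledge_tokens, function(kt)
    cosine_similarity(rv, tfidf_vector(kt, model)), 0)
  data.frame(concept_id = names(knowledge_tokens),
             cosine = unname(cos),
             kept = unname(cos >= threshold),
             stringsAsFactors = FALSE)
}

#' Aggregate knowledge embeddings by attention against a record embedding
#'
#' Attention weights over the surviving knowledge documents are computed
#' from each knowledge vector and the record embedding (`bilinear` score
#' `k_t' W e'` by default; `dot` and `additive` variants available),
#' softmax-normalised, sorted, and the top `k_budget` documents retained;
#' when fewer than `k_budget` documents survive the filter, the missing
#' slots are zero vectors.  The aggregated embedding is the weighted sum of
#' the retained knowledge vectors under the renormalised weights.
#'
#' @param e_prime Record embedding vector.
#' @param K Matrix of knowledge embeddings (one row per surviving document,
#'   rownames = concept ids); may have zero rows.
#' @param k_budget Maximum number of documents fused (>= 1).
#' @param attn_params List with `W` (and `U`, `v` for the additive score).
#' @param score_fn One of "bilinear", "dot", "additive".
#' @return List with `k_prime` (aggregated vector), `alpha` (softmax
#'   weights over surviving documents, sums to 1), `selected` (<= k_budget
#'   concept ids, by decreasing weight) and `alpha_selected` (renormalised
#'   weights over the selected documents, summing to 1).
#' @export
aggregate_knowledge <- function(e_prime, K, k_budget, attn_params,
                                score_fn = c("bilinear", "dot", "additive")) {
  score_fn <- match.arg(score_fn)
  stopifnot(k_budget >= 1)
  dK <- if (!is.null(K) && nrow(K) > 0) ncol(K) else ncol(attn_params$W)
  if (is.null(K) || nrow(K) == 0L) {
    return(list(k_prime = rep(0, dK), alpha = numeric(0),
                selected = character(0), alpha_selected = numeric(0)))
  }
  ep <- matrix(e_prime, ncol = 1L)
  scores <- switch(score_fn,
    bilinear = drop(K %*% attn_params$W %*% ep),
    dot = drop(K %*% ep[seq_len(ncol(K)), , drop = FALSE]),
    additive = drop(tanh(matrix(drop(crossprod(ep, attn_params$W)),
                                nrow(K), ncol(attn_params$W), byrow = TRUE) +
                         K %*% attn_params$U) %*% attn_params$v))
  e <- exp(scores - max(scores))
  alpha <- e / sum(e)
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  names(alpha) <- ids
  # stable selection: decreasing weight, concept id breaks ties
  ord <- order(-alpha, ids)
  sel <- ord[seq_len(min(k_budget, length(ord)))]
  w <- alpha[sel] / sum(alpha[sel])
  k_prime <- drop(crossprod(K[sel, , drop = FALSE], w))
  list(k_prime = k_prime, alpha = alpha, selected = ids[sel],
       alpha_selected = w)
}

#' Knowledge budget from the label cardinality of the corpus
#'
#' The number of knowledge documents fused per record is the average
#' number of labels per training record, rounded up (an average of 2.688
#' labels gives a budget of 3).
#'
#' @param records List of records with non-empty `labels`.
#' @return Positive integer budget.
#' @export
choose_k_budget <- function(records) {
  counts <- vapply(records, function(r) length(r$labels), 0L)
  if (!length(counts) || all(counts == 0L)) {
    stop("choose_k_budget: no labels in the corpus")
  }
  as.integer(ceiling(mean(counts)))
}
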