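# Hierarchical Bi-GRU attention encoder.
#
# Two routes implement the same mathematics:
#   * plain numeric operations (gru_step, bigru_encode, attention_pool)
#     exposed as the building-block API and usable as a compositional
#     oracle, and
#   * a batched forward on the autodiff tape (kd_encode_batch) used for
#     training and prediction.
# Tests assert the two routes agree.
#
# GRU recurrence (sigma is the logistic function, o elementwise product):
#   r_t = sigma(x_t W_r + h_{t-1} U_r + b_r)
#   z_t = sigma(x_t W_z + h_{t-1} U_z + b_z)
#   hc_t = tanh(x_t W_h + (r_t o h_{t-1}) U_h + b_h)
#   h_t = (1 - z_t) o h_{t-1} + z_t o hc_t
# Attention pooling over annotations h_t:
#   u_t = tanh(h_t W + b);  alpha = softmax(u_t' u_ctx);  pooled = sum alpha_t h_t

#' One GRU step
#'
#' @param x Input vector (length E).
#' @param h_prev Previous hidden state (length H).
#' @param params List with matrices `Wr`, `Wz`, `Wh` (E x H), `Ur`, `Uz`,
#'   `Uh` (H x H) and bias vectors `br`, `bz`, `bh` (length H).
#' @return Hidden state vector of length H.
#' @export
gru_step <- function(x, h_prev, params) {
  x <- matrix(x, 1L)
  h <- matrix(h_prev, 1L)
  if (ncol(x) != nrow(params$Wr) || ncol(h) != nrow(params$Ur)) {
    stop("gru_step: input/hidden dimensions do not match parameter shapes")
  }
  sig <- function(a) 1 / (1 + exp(-a))
  r <- sig(x %*% params$Wr + h %*% params$Ur + rep(params$br, each = 1L))
  z <- sig(x %*% params$Wz + h %*% params$Uz + rep(params$bz, each = 1L))
  hc <- tanh(x %*% params$Wh + (r * h) %*% params$Uh + rep(params$bh, each = 1L))
  drop((1 - z) * h + z * hc)
}

#' Bidirectional GRU encoding of a sequence
#'
#' Runs a forward GRU left-to-right and a backward GRU right-to-left from
#' zero initial states and concatenates the two hidden states per position
#' into a 2H annotation.  Padded positions (mask 0) leave the recurrent
#' state untouched, so padding never influences real positions; their
#' annotation rows are returned as zeros.
#'
#' @param x Matrix (T x E) of input vectors, one row per position.
#' @param mask Logical/0-1 vector of length T, 1 on real positions.
#' @param fwd,bwd GRU parameter lists as in [gru_step()].
#' @return Matrix (T x 2H) of annotations.
#' @export
bigru_encode <- function(x, mask, fwd, bwd) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  T_ <- nrow(x)
  if (length(mask) != T_) stop("bigru_encode: mask length != sequence length")
  H <- ncol(fwd$Ur)
  if (T_ == 0L) return(matrix(0, 0L, 2L * H))
  hf <- matrix(0, T_, H)
  h <- rep(0, H)
  for (t in seq_len(T_)) {
    if (mask[t] > 0) h <- gru_step(x[t, ], h, fwd)
    hf[t, ] <- if (mask[t] > 0) h else 0
  }
  hb <- matrix(0, T_, H)
  h <- rep(0, H)
  for (t in rev(seq_len(T_))) {
    if (mask[t] > 0) h <- gru_step(x[t, ], h, bwd)
    hb[t, ] <- if (mask[t] > 0) h else 0
  }
  cbind(hf, hb)
}

#' Attention pooling of annotations
#'
#' Projects each annotation through `tanh(h W + b)`, scores it against the
#' learned context vector `u`, softmax-normalises the scores over unmasked
#' positions (padding receives exactly zero weight) and returns the
#' weighted sum of annotations.
#'
#' @param ann Matrix (T x D) of annotations.
#' @param mask 0-1 vector of length T; at least one position must be real.
#' @param params List with `W` (D x A), `b` (length A), `u` (length A).
#' @return List with `pooled` (length D) and `alpha` (length T, sums to 1
#'   over unmasked positions, 0 on padding).
#' @export
attention_pool <- function(ann, mask, params) {
  if (all(mask == 0)) stop("attention_pool: all positions are masked")
  proj <- tanh(ann %*% params$W + rep(matrix(params$b, 1L), each = nrow(ann)))
  score <- drop(proj %*% matrix(params$u, ncol = 1L))
  score[mask == 0] <- -Inf
  e <- exp(score - max(score))
  alpha <- e / sum(e)
  list(pooled = drop(crossprod(ann, alpha)), alpha = alpha)
}

## ---- parameter initialisation ----

kd_glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

kd_gru_init <- function(din, H) {
  list(Wr = kd_glorot(din, H), Wz = kd_glorot(din, H), Wh = kd_glorot(din, H),
       Ur = kd_glorot(H, H), Uz = kd_glorot(H, H), Uh = kd_glorot(H, H),
       br = rep(0, H), bz = rep(0, H), bh = rep(0, H))
}

kd_attn_init <- function(D) {
  list(W = kd_glorot(D, D), b = rep(0, D), u = drop(kd_glorot(D, 1L)))
}

# Flat named list of all trainable matrices.  Prefixes: w* word level,
# s* sentence level (f/b direction, a attention), agg_* knowledge
# aggregator, fc* classification head, emb embedding table.
kd_init_params <- function(vocab_size, n_labels, n_numeric, n_knowledge,
                           config) {
  E <- config$embed_dim
  H <- config$hidden
  D <- 2L * H
  de <- D + n_numeric
  if (isTRUE(config$project_eprime)) de <- D
  p <- list(emb = matrix(stats::rnorm(vocab_size * E, sd = 0.1), vocab_size, E))
  add_gru <- function(p, prefix, din) {
    g <- kd_gru_init(din, H)
    for (nm in names(g)) {
      m <- g[[nm]]
      if (is.null(dim(m))) m <- matrix(m, 1L)
      p[[paste0(prefix, "_", nm)]] <- m
    }
    p
  }
  add_attn <- function(p, prefix) {
    a <- kd_attn_init(D)
    p[[paste0(prefix, "_W")]] <- a$W
    p[[paste0(prefix, "_b")]] <- matrix(a$b, 1L)
    p[[paste0(prefix, "_u")]] <- matrix(a$u, ncol = 1L)
    p
  }
  p <- add_gru(p, "wf", E); p <- add_gru(p, "wb", E); p <- add_attn(p, "wa")
  p <- add_gru(p, "sf", D); p <- add_gru(p, "sb", D); p <- add_attn(p, "sa")
  if (isTRUE(config$project_eprime)) {
    p$proj_W <- kd_glorot(D + n_numeric, D)
    p$proj_b <- matrix(0, 1L, D)
  }
  if (config$ablation == "full") {
    if (config$score_fn == "bilinear") {
      p$agg_W <- kd_glorot(D, de)
    } else if (config$score_fn == "additive") {
      p$agg_W <- kd_glorot(de, D)
      p$agg_U <- kd_glorot(D, D)
      p$agg_v <- kd_glorot(D, 1L)
    }
  }
  din <- switch(config$ablation,
                full = de + D,
                no_knowledge = de,
                no_attention = de + n_knowledge * D)
  p$fc1_W <- kd_glorot(din, config$fc_hidden)
  p$fc1_b <- matrix(0, 1L, config$fc_hidden)
  p$fc2_W <- kd_glorot(config$fc_hidden, n_labels)
  p$fc2_b <- matrix(0, 1L, n_labels)
  p
}

# Reassemble the plain-list view of one GRU / attention block from the flat
# parameter list (used by the plain-numeric route and by encode_document).
kd_gru_view <- function(params, prefix) {
  list(Wr = params[[paste0(prefix, "_Wr")]], Wz = params[[paste0(prefix, "_Wz")]],
       Wh = params[[paste0(prefix, "_Wh")]], Ur = params[[paste0(prefix, "_Ur")]],
       Uz = params[[paste0(prefix, "_Uz")]], Uh = params[[paste0(prefix, "_Uh")]],
       br = drop(params[[paste0(prefix, "_br")]]),
       bz = drop(params[[paste0(prefix, "_bz")]]),
       bh = drop(params[[paste0(prefix, "_bh")]]))
}

kd_attn_view <- function(params, prefix) {
  list(W = params[[paste0(prefix, "_W")]],
       b = drop(params[[paste0(prefix, "_b")]]),
       u = drop(params[[paste0(prefix, "_u")]]))
}

## ---- batched tape forward ----

# One GRU direction over a batch.  xs: list of T nodes (n x E); mask: n x T
# constant matrix.  Returns list of T annotation nodes (n x H), zeros at
# padded positions.
tp_gru_dir <- function(tape, xs, mask, pn, prefix, reverse = FALSE) {
  T_ <- length(xs)
  n <- nrow(mask)
  H <- ncol(pn[[paste0(prefix, "_Ur")]]$v)
  P <- function(nm) pn[[paste0(prefix, "_", nm)]]
  h <- tp_const(tape, matrix(0, n, H))
  out <- vector("list", T_)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (t in steps) {
    x <- xs[[t]]
    m <- mask[, t]
    r <- tp_sigmoid(tape, tp_addvec(tape, tp_add(tape,
           tp_mm(tape, x, P("Wr")), tp_mm(tape, h, P("Ur"))), P("br")))
    z <- tp_sigmoid(tape, tp_addvec(tape, tp_add(tape,
           tp_mm(tape, x, P("Wz")), tp_mm(tape, h, P("Uz"))), P("bz")))
    hc <- tp_tanh(tape, tp_addvec(tape, tp_add(tape,
            tp_mm(tape, x, P("Wh")), tp_mm(tape, tp_mul(tape, r, h), P("Uh"))),
            P("bh")))
    hnew <- tp_add(tape, tp_mul(tape, tp_onem(tape, z), h),
                   tp_mul(tape, z, hc))
    # padded steps keep the previous state and emit a zero annotation
    h <- tp_add(tape, tp_colmulc(tape, hnew, m),
                tp_colmulc(tape, h, 1 - m))
    out[[t]] <- tp_colmulc(tape, h, m)
  }
  out
}

# Attention pooling over T annotation nodes; returns list(pooled node,
# alpha value matrix n x T).
tp_attn_pool <- function(tape, anns, mask, pn, prefix) {
  P <- function(nm) pn[[paste0(prefix, "_", nm)]]
  cols <- lapply(anns, function(a) {
    tp_mm(tape, tp_tanh(tape, tp_addvec(tape, tp_mm(tape, a, P("W")), P("b"))),
          P("u"))
  })
  scores <- if (length(cols) == 1L) cols[[1]] else do.call(tp_cbind, c(list(tape), cols))
  alpha <- tp_masked_softmax(tape, scores, mask)
  pooled <- NULL
  for (t in seq_along(anns)) {
    term <- tp_colmul(tape, anns[[t]], tp_col(tape, alpha, t))
    pooled <- if (is.null(pooled)) term else tp_add(tape, pooled, term)
  }
  list(pooled = pooled, alpha = alpha$v)
}

# Batched hierarchical encoding of ndoc documents.
# ids/mask: arrays (ndoc, L, T).  Returns list(e = node (ndoc x 2H),
# alpha_w = (ndoc*L x T), alpha_s = (ndoc x L), sent = node (ndoc*L x 2H)).
kd_encode_batch <- function(tape, pn, ids, mask) {
  ndoc <- dim(ids)[1]; L <- dim(ids)[2]; T_ <- dim(ids)[3]
  # flatten doc-major: row (d-1)*L + i  <-> document d, sentence i
  flat_ids <- matrix(aperm(ids, c(2, 1, 3)), ndoc * L, T_)
  flat_mask <- matrix(aperm(mask, c(2, 1, 3)), ndoc * L, T_)
  xs <- lapply(seq_len(T_), function(t)
    tp_rows(tape, pn$emb, flat_ids[, t] + 1L))
  hf <- tp_gru_dir(tape, xs, flat_mask, pn, "wf", reverse = FALSE)
  hb <- tp_gru_dir(tape, xs, flat_mask, pn, "wb", reverse = TRUE)
  anns <- lapply(seq_len(T_), function(t) tp_cbind(tape, hf[[t]], hb[[t]]))
  wp <- tp_attn_pool(tape, anns, flat_mask, pn, "wa")
  sent <- wp$pooled                                    # (ndoc*L) x 2H
  smask <- matrix(0, ndoc, L)
  smask[] <- apply(mask, c(1, 2), max)
  svec <- lapply(seq_len(L), function(i)
    tp_rows(tape, sent, (seq_len(ndoc) - 1L) * L + i))
  sf <- tp_gru_dir(tape, svec, smask, pn, "sf", reverse = FALSE)
  sb <- tp_gru_dir(tape, svec, smask, pn, "sb", reverse = TRUE)
  sanns <- lapply(seq_len(L), function(i) tp_cbind(tape, sf[[i]], sb[[i]]))
  sp <- tp_attn_pool(tape, sanns, smask, pn, "sa")
  list(e = sp$pooled, alpha_w = wp$alpha, alpha_s = sp$alpha, sent = sent,
       smask = smask)
}

#' Encode one document with the hierarchical attention encoder
#'
#' Runs the word-level Bi-GRU + attention to form sentence vectors, then
#' the sentence-level Bi-GRU + attention to form the document vector,
#' retaining every attention distribution for interpretability.
#'
#' @param doc A tokenized document (list of token vectors), or a raw string
#'   which is tokenized with the model's tokenizer settings.
#' @param params Flat parameter list (e.g. `model$params`).
#' @param vocab A `token_vocab`.
#' @param max_sents,max_words Padding limits.
#' @return An `encoded_doc`: list with `e` (document vector, length 2H),
#'   `sentence_vectors` (L x 2H), `sentence_attention` (length L, sums to
#'   1), `word_attention` (list per sentence, each summing to 1) and
#'   `n_sentences`.
#' @export
encode_document <- function(doc, params, vocab, max_sents = 30L,
                            max_words = 50L) {
  if (is.character(doc)) doc <- tokenize_hierarchical(doc)
  if (!length(doc)) stop("encode_document: empty document")
  pb <- pad_batch(list(doc), vocab, max_sents = min(max_sents, length(doc)),
                  max_words = max_words)
  tape <- tape_new()
  pn <- lapply(params, function(m) tp_const(tape, m))
  enc <- kd_encode_batch(tape, pn, pb$ids, pb$mask)
  L <- dim(pb$ids)[2]
  word_attention <- lapply(seq_len(L), function(i) {
    a <- enc$alpha_w[i, ]
    a[pb$mask[1, i, ] > 0]
  })
  keep <- enc$smask[1, ] > 0
  structure(list(e = drop(enc$e$v),
                 sentence_vectors = enc$sent$v,
                 sentence_attention = enc$alpha_s[1, ],
                 word_attention = word_attention,
                 n_sentences = sum(keep)),
            class = "encoded_doc")
}

#' @export
print.encoded_doc <- function(x, ...) {
  cat("Encoded document: ", x$n_sentences, " sentences, embedding dim ",
      length(x$e), "\n", sep = "")
  invisible(x)
}
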