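# End-to-end knowledge-aware hierarchical diagnosis model.
#
# knowdiag() assembles the hierarchical encoder, the numeric feature
# vector, and the knowledge filter/aggregator into a multilabel sigmoid
# classifier, trained with Adam on summed per-label binary cross-entropy.
# The classification head is FC1 (input -> fc_hidden, tanh) followed by
# FC2 (fc_hidden -> c), reconciling the "two fully connected layers"
# architecture with the stated 200 x c output layer.

#' Model configuration
#'
#' Defaults follow the reference training setup for clinical records:
#' GRU hidden size 100 per direction (200-dimensional document vectors),
#' sigmoid decision threshold tau = 0.5 (a label is predicted when its
#' probability strictly exceeds tau), Adam with learning rate 0.001 and
#' batch size 32, and a 1600-character document cap.
#'
#' @param embed_dim Word embedding dimension.
#' @param hidden GRU hidden size per direction (document dim = 2 * hidden).
#' @param fc_hidden Width of the first fully connected layer.
#' @param tau Prediction threshold in (0, 1).
#' @param k_budget Number of knowledge documents fused per record; `NULL`
#'   applies the ceiling-of-mean-label-count rule ([choose_k_budget()]).
#' @param lr,batch_size,epochs Adam learning rate, minibatch size, epochs.
#' @param seed RNG seed controlling initialisation and shuffling.
#' @param ablation One of `"full"`, `"no_knowledge"` (text + numerics only),
#'   `"no_attention"` (all padded knowledge embeddings concatenated
#'   directly, no aggregator).
#' @param score_fn Aggregator score between a knowledge vector and the
#'   record embedding: `"dot"` (default; both live in the shared encoder
#'   space, so similarity is meaningful from initialisation), `"bilinear"`
#'   (`k_t' W e'`, a learned interaction), or `"additive"`.
#' @param filter_threshold TF-IDF cosine cutoff of the knowledge filter.
#' @param max_chars Character cap per document before tokenization.
#' @param max_sents,max_words Upper bounds on sentences per document and
#'   words per sentence (the corpus may use less).
#' @param min_count Minimum token count for a vocabulary entry.
#' @param project_eprime If `TRUE`, project the concatenation of the
#'   document vector and numeric features back to 2 * hidden dimensions.
#' @param tokenizer Pluggable sentence tokenizer.
#' @param verbose Print per-epoch loss.
#' @return A `knowdiag_config` list.
#' @export
knowdiag_config <- function(embed_dim = 100L, hidden = 100L, fc_hidden = 200L,
                            tau = 0.5, k_budget = NULL, lr = 0.001,
                            batch_size = 32L, epochs = 30L, seed = 1L,
                            ablation = c("full", "no_knowledge", "no_attention"),
                            score_fn = c("dot", "bilinear", "additive"),
                            filter_threshold = 0.5, max_chars = 1600L,
                            max_sents = 30L, max_words = 50L, min_count = 1L,
                            project_eprime = FALSE,
                            tokenizer = whitespace_tokenizer,
                            verbose = FALSE) {
  ablation <- match.arg(ablation)
  score_fn <- match.arg(score_fn)
  stopifnot(tau > 0, tau < 1, embed_dim > 0, hidden > 0, fc_hidden > 0,
            lr > 0, batch_size >= 1, epochs >= 0)
  structure(as.list(environment()), class = "knowdiag_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tokenize + pad a record list against fixed dims; also numeric matrix and
# per-record knowledge survival mask.
kd_prepare <- function(records, model_env) {
  me <- model_env
  docs <- lapply(records, function(r)
    tokenize_hierarchical(r$text, me$config$tokenizer, me$config$max_chars))
  pb <- pad_batch(docs, me$vocab, me$dims$L, me$dims$T)
  nmat <- if (is.null(me$schema)) {
    matrix(0, length(records), 0L)
  } else {
    extract_matrix(records, me$schema, me$numeric_stats)$values
  }
  j <- length(me$concept_ids)
  kmask <- matrix(0, length(records), j)
  if (j > 0L && me$config$ablation != "no_knowledge") {
    for (i in seq_along(records)) {
      fk <- filter_knowledge(unlist(docs[[i]]), me$knowledge_tokens,
                             me$tfidf, me$config$filter_threshold)
      kmask[i, ] <- as.numeric(fk$kept)
    }
  }
  list(ids = pb$ids, mask = pb$mask, nmat = nmat, kmask = kmask)
}

# Forward pass over one batch on a fresh tape.  gold (B x c) adds a loss
# node.  Returns tape, parameter nodes, loss, probabilities and the
# knowledge attention actually used.
kd_forward_batch <- function(params, batch, kn, config, k_budget,
                             gold = NULL) {
  tape <- tape_new()
  pn <- lapply(params, function(m) tp_const(tape, m))
  B <- dim(batch$ids)[1]
  j <- if (config$ablation == "no_knowledge") 0L else dim(kn$ids)[1]
  if (j > 0L) {
    ids <- array(0L, dim = c(B + j, dim(batch$ids)[2], dim(batch$ids)[3]))
    msk <- array(0, dim = dim(ids))
    ids[seq_len(B), , ] <- batch$ids; ids[B + seq_len(j), , ] <- kn$ids
    msk[seq_len(B), , ] <- batch$mask; msk[B + seq_len(j), , ] <- kn$mask
  } else {
    ids <- batch$ids; msk <- batch$mask
  }
  enc <- kd_encode_batch(tape, pn, ids, msk)
  E <- if (j > 0L) tp_rows(tape, enc$e, seq_len(B)) else enc$e
  K <- if (j > 0L) tp_rows(tape, enc$e, B + seq_len(j)) else NULL
  eprime <- if (ncol(batch$nmat) > 0L) {
    tp_cbind(tape, E, tp_const(tape, batch$nmat))
  } else E
  if (isTRUE(config$project_eprime)) {
    eprime <- tp_addvec(tape, tp_mm(tape, eprime, pn$proj_W), pn$proj_b)
  }
  alpha_v <- NULL; sel <- NULL
  if (config$ablation == "full") {
    Sc <- switch(config$score_fn,
      bilinear = tp_mm(tape, eprime, tp_t(tape, tp_mm(tape, K, pn$agg_W))),
      dot = tp_mm(tape, E, tp_t(tape, K)),
      additive = {
        A <- tp_mm(tape, eprime, pn$agg_W)
        cols <- lapply(seq_len(j), function(t) {
          bt <- tp_mm(tape, tp_rows(tape, K, t), pn$agg_U)
          tp_mm(tape, tp_tanh(tape, tp_addvec(tape, A, bt)), pn$agg_v)
        })
        if (j == 1L) cols[[1]] else do.call(tp_cbind, c(list(tape), cols))
      })
    alpha <- tp_masked_softmax(tape, Sc, batch$kmask)
    alpha_v <- alpha$v
    sel <- matrix(0, B, j)
    for (i in seq_len(B)) {
      surv <- which(batch$kmask[i, ] > 0)
      if (!length(surv)) next
      ord <- surv[order(-alpha_v[i, surv], surv)]
      sel[i, ord[seq_len(min(k_budget, length(ord)))]] <- 1
    }
    alpha2 <- tp_renorm_rows(tape, tp_mulc(tape, alpha, sel))
    kprime <- tp_mm(tape, alpha2, K)
    z <- tp_cbind(tape, eprime, kprime)
  } else if (config$ablation == "no_attention") {
    blocks <- lapply(seq_len(j), function(t)
      tp_mm(tape, tp_const(tape, batch$kmask[, t, drop = FALSE]),
            tp_rows(tape, K, t)))
    z <- do.call(tp_cbind, c(list(tape, eprime), blocks))
  } else {
    z <- eprime
  }
  h1 <- tp_tanh(tape, tp_addvec(tape, tp_mm(tape, z, pn$fc1_W), pn$fc1_b))
  logits <- tp_addvec(tape, tp_mm(tape, h1, pn$fc2_W), pn$fc2_b)
  loss <- if (!is.null(gold)) tp_bce_logits(tape, logits, gold) else NULL
  list(tape = tape, pn = pn, loss = loss,
       probs = 1 / (1 + exp(-logits$v)), alpha = alpha_v, selected = sel)
}

#' Summed per-label binary cross-entropy
#'
#' Cross-entropy summed over labels and averaged over records, with
#' probabilities clamped to `[eps, 1 - eps]` for stability.
#'
#' @param probs Probability matrix or vector.
#' @param gold Binary matrix/vector of the same shape.
#' @param eps Clamping constant.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(probs, gold, eps = 1e-7) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)   # one record
  if (is.null(dim(gold))) gold <- matrix(gold, 1L)
  p <- pmin(pmax(as.matrix(probs), eps), 1 - eps)
  y <- as.matrix(gold)
  stopifnot(all(dim(p) == dim(y)))
  -sum(y * log(p) + (1 - y) * log(1 - p)) / nrow(p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

#' Fit the knowledge-aware hierarchical diagnosis model
#'
#' Builds the token vocabulary over records and knowledge documents, fits
#' numeric feature statistics and the TF-IDF filter model, chooses the
#' knowledge budget from the training label cardinality, and trains the
#' hierarchical encoder + knowledge aggregator + sigmoid head end to end
#' with Adam on summed binary cross-entropy.  Training is deterministic
#' given `config$seed`.
#'
#' @param records Training records (see [read_records()]).
#' @param knowledge List of knowledge documents (one per medical concept;
#'   see [read_knowledge_dir()]); may be empty for the `no_knowledge`
#'   ablation.
#' @param label_vocab Character vector of labels; fixes score columns.
#' @param schema Optional [feature_schema()] for numeric features.
#' @param config A [knowdiag_config()].
#' @return A fitted `knowdiag` object with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
knowdiag <- function(records, knowledge = list(), label_vocab,
                     schema = NULL, config = knowdiag_config()) {
  stopifnot(length(records) > 0, length(label_vocab) > 0)
  cl <- match.call()
  set.seed(config$seed)
  # the no-knowledge ablation must be invariant to the knowledge input
  if (config$ablation == "no_knowledge") knowledge <- list()
  # knowledge in stable concept-id order: defines aggregator columns
  if (length(knowledge)) {
    knowledge <- knowledge[order(vapply(knowledge, function(k) k$concept_id, ""))]
  }
  me <- new.env(parent = emptyenv())
  me$config <- config
  me$label_vocab <- label_vocab
  me$schema <- schema
  me$vocab <- build_vocab(records, knowledge, config$min_count,
                          config$tokenizer, config$max_chars)
  me$numeric_stats <- if (!is.null(schema))
    fit_numeric_stats(records, schema) else NULL
  rec_docs <- lapply(records, function(r)
    tokenize_hierarchical(r$text, config$tokenizer, config$max_chars))
  kn_docs <- lapply(knowledge, function(k)
    tokenize_hierarchical(k$text, config$tokenizer, config$max_chars))
  me$knowledge_tokens <- lapply(kn_docs, unlist)
  names(me$knowledge_tokens) <- vapply(knowledge, function(k) k$concept_id, "")
  me$concept_ids <- names(me$knowledge_tokens)
  me$tfidf <- tfidf_fit(c(lapply(rec_docs, unlist), me$knowledge_tokens))
  me$dims <- list(
    L = max(1L, min(config$max_sents, max(lengths(c(rec_docs, kn_docs))))),
    T = max(1L, min(config$max_words,
                    max(unlist(lapply(c(rec_docs, kn_docs), lengths)), 0L))))
  k_budget <- config$k_budget %||% choose_k_budget(records)
  prep <- kd_prepare(records, me)
  kn <- if (length(knowledge)) {
    kpb <- pad_batch(kn_docs, me$vocab, me$dims$L, me$dims$T)
    list(ids = kpb$ids, mask = kpb$mask)
  } else NULL
  gold <- matrix(0, length(records), length(label_vocab))
  for (i in seq_along(records)) {
    gold[i, match(records[[i]]$labels, label_vocab)] <- 1
  }
  n_num <- if (is.null(schema)) 0L else length(schema$features)
  params <- kd_init_params(me$vocab$size, length(label_vocab), n_num,
                           length(knowledge), config)
  opt <- adam_init(params)
  n <- length(records)
  loss_history <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      batch <- list(ids = prep$ids[bidx, , , drop = FALSE],
                    mask = prep$mask[bidx, , , drop = FALSE],
                    nmat = prep$nmat[bidx, , drop = FALSE],
                    kmask = prep$kmask[bidx, , drop = FALSE])
      fw <- kd_forward_batch(params, batch, kn, config, k_budget,
                             gold = gold[bidx, , drop = FALSE])
      lv <- fw$loss$v[1L]
      if (!is.finite(lv)) {
        stop("knowdiag: training diverged (non-finite loss) at epoch ", ep)
      }
      losses <- c(losses, lv)
      tape_backward(fw$tape, fw$loss)
      grads <- lapply(fw$pn, function(nd) nd$g)
      upd <- adam_step(params, grads, opt, config$lr)
      params <- upd$params
      opt <- upd$state
    }
    loss_history <- c(loss_history, mean(losses))
    if (isTRUE(config$verbose)) {
      cat(sprintf("epoch %3d  loss %.4f\n", ep, mean(losses)))
    }
  }
  structure(list(params = params, config = config, vocab = me$vocab,
                 label_vocab = label_vocab, schema = schema,
                 numeric_stats = me$numeric_stats, tfidf = me$tfidf,
                 knowledge_tokens = me$knowledge_tokens,
                 concept_ids = me$concept_ids, knowledge_padded = kn,
                 dims = me$dims, k_budget = k_budget,
                 loss_history = loss_history, call = cl),
            class = "knowdiag")
}

# environment view of a fitted model for kd_prepare()
kd_model_env <- function(object) {
  me <- new.env(parent = emptyenv())
  for (nm in c("config", "vocab", "schema", "numeric_stats", "tfidf",
               "knowledge_tokens", "concept_ids", "dims")) {
    assign(nm, object[[nm]], envir = me)
  }
  me
}

#' Predict diagnosis probabilities and label sets
#'
#' @param object A fitted `knowdiag` model.
#' @param records List of records to score.
#' @param type `"scores"` for the probability matrix, `"labels"` for the
#'   thresholded label sets (probability strictly greater than tau),
#'   `"both"` for both plus the knowledge attention report.
#' @param ... Unused.
#' @return See `type`.  The score matrix has record ids as rownames and
#'   the label vocabulary as colnames.
#' @export
predict.knowdiag <- function(object, records, type = c("scores", "labels",
                                                       "both"), ...) {
  type <- match.arg(type)
  me <- kd_model_env(object)
  prep <- kd_prepare(records, me)
  n <- length(records)
  cfg <- object$config
  scores <- matrix(NA_real_, n, length(object$label_vocab),
                   dimnames = list(vapply(records, function(r) r$record_id, ""),
                                   object$label_vocab))
  alpha <- NULL; selected <- NULL
  if (cfg$ablation == "full" && length(object$concept_ids)) {
    alpha <- matrix(0, n, length(object$concept_ids),
                    dimnames = list(rownames(scores), object$concept_ids))
    selected <- alpha
  }
  for (b0 in seq(1L, n, by = cfg$batch_size)) {
    bidx <- b0:min(b0 + cfg$batch_size - 1L, n)
    batch <- list(ids = prep$ids[bidx, , , drop = FALSE],
                  mask = prep$mask[bidx, , , drop = FALSE],
                  nmat = prep$nmat[bidx, , drop = FALSE],
                  kmask = prep$kmask[bidx, , drop = FALSE])
    fw <- kd_forward_batch(object$params, batch, object$knowledge_padded,
                           cfg, object$k_budget)
    scores[bidx, ] <- fw$probs
    if (!is.null(alpha) && !is.null(fw$alpha)) {
      alpha[bidx, ] <- fw$alpha
      selected[bidx, ] <- fw$selected
    }
  }
  if (type == "scores") return(scores)
  sets <- apply(scores, 1L, function(p)
    object$label_vocab[p > cfg$tau], simplify = FALSE)
  if (type == "labels") return(sets)
  list(scores = scores, labels = sets, alpha = alpha, selected = selected)
}

#' Evaluate a fitted model on labelled records
#'
#' @param object A fitted `knowdiag` model.
#' @param records Labelled records.
#' @return One-row data frame of the five multilabel metrics.
#' @export
evaluate <- function(object, records) {
  scores <- predict(object, records)
  gold <- matrix(0, length(records), length(object$label_vocab))
  for (i in seq_along(records)) {
    gold[i, match(records[[i]]$labels, object$label_vocab)] <- 1
  }
  multilabel_metrics(scores, gold, object$config$tau)
}

#' @export
print.knowdiag <- function(x, ...) {
  cat("Knowledge-aware hierarchical diagnosis model\n")
  cat("  labels:", length(x$label_vocab),
      " vocabulary:", x$vocab$size, "tokens\n")
  cat("  hidden:", x$config$hidden, " embed:", x$config$embed_dim,
      " ablation:", x$config$ablation, "\n")
  cat("  knowledge documents:", length(x$concept_ids),
      " k budget:", x$k_budget, "\n")
  if (length(x$loss_history)) {
    cat("  training loss:", sprintf("%.4f", x$loss_history[1]), "->",
        sprintf("%.4f", utils::tail(x$loss_history, 1)),
        "over", length(x$loss_history), "epochs\n")
  }
  invisible(x)
}

#' @export
summary.knowdiag <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 0L))
  cat("Knowledge-aware hierarchical diagnosis model\n\n")
  print(object$call)
  cat("\nParameters:", npar, "in", length(object$params), "tensors\n")
  cat("Decision threshold tau:", object$config$tau,
      " knowledge budget k:", object$k_budget, "\n")
  cat("Numeric features:",
      if (is.null(object$schema)) 0L else length(object$schema$features), "\n")
  if (length(object$loss_history)) {
    cat("\nTraining loss by epoch:\n")
    print(round(object$loss_history, 4))
  }
  invisible(object)
}

#' @export
coef.knowdiag <- function(object, ...) object$params

#' @export
plot.knowdiag <- function(x, ...) {
  if (!length(x$loss_history)) stop("model has no training history")
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "training loss",
       main = "knowdiag training loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' @param object A fitted `knowdiag` model.
#' @param path File path for the single-file checkpoint.
#' @export
knowdiag_save <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname knowdiag_save
#' @export
knowdiag_load <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "knowdiag"))
  obj
}
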