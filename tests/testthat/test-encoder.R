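test_that("a zero-parameter GRU step halves the hidden state", {
  zero <- list(Wr = matrix(0, 2, 3), Wz = matrix(0, 2, 3), Wh = matrix(0, 2, 3),
               Ur = matrix(0, 3, 3), Uz = matrix(0, 3, 3), Uh = matrix(0, 3, 3),
               br = rep(0, 3), bz = rep(0, 3), bh = rep(0, 3))
  v <- c(2, -4, 6)
  expect_equal(gru_step(c(1, 1), v, zero), 0.5 * v)
  expect_equal(gru_step(c(1, 1), rep(0, 3), zero), rep(0, 3))
  expect_error(gru_step(c(1, 1, 1), v, zero), "dimensions")
})

test_that("gru_step matches an independent scalar oracle on random draws", {
  set.seed(11)
  for (i in 1:100) {
    din <- sample(1:4, 1); H <- sample(1:4, 1)
    p <- rand_gru(din, H)
    x <- rnorm(din); h <- rnorm(H)
    expect_equal(gru_step(x, h, p), oracle_gru_step(x, h, p),
                 tolerance = 1e-6)
  }
})

test_that("bidirectional encoding respects masks and symmetry", {
  set.seed(21)
  fwd <- rand_gru(2, 3)
  # a length-1 sequence takes one step from the zero state in each direction
  x <- matrix(rnorm(2), 1, 2)
  ann <- bigru_encode(x, 1, fwd, fwd)
  step <- gru_step(x[1, ], rep(0, 3), fwd)
  expect_equal(ann[1, ], c(step, step))

  # palindromic input with tied parameters: forward half mirrors backward
  xp <- rbind(c(1, -1), c(0.5, 2), c(1, -1))
  annp <- bigru_encode(xp, c(1, 1, 1), fwd, fwd)
  for (t in 1:3) {
    expect_equal(annp[t, 1:3], annp[4 - t, 4:6], tolerance = 1e-12)
  }

  # appending padding leaves real-position annotations unchanged
  bwd <- rand_gru(2, 3)
  x3 <- matrix(rnorm(6), 3, 2)
  a3 <- bigru_encode(x3, c(1, 1, 1), fwd, bwd)
  a5 <- bigru_encode(rbind(x3, matrix(9, 2, 2)), c(1, 1, 1, 0, 0), fwd, bwd)
  expect_equal(a5[1:3, ], a3)
  expect_true(all(a5[4:5, ] == 0))

  expect_equal(nrow(bigru_encode(matrix(0, 0, 2), logical(0), fwd, bwd)), 0L)
})

test_that("attention pooling normalises over real positions only", {
  set.seed(31)
  p <- rand_attn(4)
  # identical annotations share the weight equally
  ann <- matrix(rep(c(1, 2, -1, 0.5), 3), 3, 4, byrow = TRUE)
  ap <- attention_pool(ann, c(1, 1, 1), p)
  expect_equal(ap$alpha, rep(1 / 3, 3))
  expect_equal(ap$pooled, ann[1, ])
  # one unmasked position takes all the weight
  ann2 <- matrix(rnorm(12), 3, 4)
  ap2 <- attention_pool(ann2, c(0, 1, 0), p)
  expect_equal(ap2$alpha, c(0, 1, 0))
  expect_equal(ap2$pooled, ann2[2, ])
  expect_error(attention_pool(ann2, c(0, 0, 0), p), "masked")
  # brute-force agreement on random annotations
  for (i in 1:20) {
    ann3 <- matrix(rnorm(12), 3, 4)
    m <- c(1, 1, sample(0:1, 1))
    got <- attention_pool(ann3, m, p)
    want <- oracle_attention_pool(ann3, m, p)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
    expect_equal(got$pooled, want$pooled, tolerance = 1e-12)
  }
})

# a tiny fitted model supplies real parameter tensors for the document tests
tiny_model <- local({
  spec <- synthetic_spec(n_records = 30L, n_labels = 3L, seed = 17)
  corp <- generate_corpus(spec)
  cfg <- knowdiag_config(embed_dim = 5L, hidden = 4L, fc_hidden = 8L,
                         epochs = 1L, seed = 2L)
  knowdiag(corp$records, corp$knowledge, corp$label_vocab, corp$schema, cfg)
})

test_that("document encoding composes word- and sentence-level operations", {
  m <- tiny_model
  doc <- list(c("a", "b"), c("c"))
  enc <- encode_document(doc, m$params, m$vocab)
  # compositional oracle: chain the exported plain operations by hand
  emb <- m$params$emb
  wf <- knowdiag:::kd_gru_view(m$params, "wf")
  wb <- knowdiag:::kd_gru_view(m$params, "wb")
  wa <- knowdiag:::kd_attn_view(m$params, "wa")
  sf <- knowdiag:::kd_gru_view(m$params, "sf")
  sb <- knowdiag:::kd_gru_view(m$params, "sb")
  sa <- knowdiag:::kd_attn_view(m$params, "sa")
  svecs <- t(vapply(doc, function(s) {
    x <- emb[tokens_to_ids(s, m$vocab) + 1L, , drop = FALSE]
    ann <- bigru_encode(x, rep(1, nrow(x)), wf, wb)
    attention_pool(ann, rep(1, nrow(x)), wa)$pooled
  }, numeric(2L * 4L)))
  sann <- bigru_encode(svecs, c(1, 1), sf, sb)
  want <- attention_pool(sann, c(1, 1), sa)
  expect_equal(enc$e, want$pooled, tolerance = 1e-10)
  expect_equal(enc$sentence_attention, want$alpha, tolerance = 1e-10)

  # attention distributions are proper and retained at both levels
  expect_equal(sum(enc$sentence_attention), 1, tolerance = 1e-6)
  for (a in enc$word_attention) expect_equal(sum(a), 1, tolerance = 1e-6)
  expect_length(enc$e, 8L)
  expect_error(encode_document(list(), m$params, m$vocab), "empty")
})

test_that("document encoding is deterministic and padding-invariant", {
  m <- tiny_model
  doc <- list(c("a", "b", "c"), c("b", "b"))
  e1 <- encode_document(doc, m$params, m$vocab)
  e2 <- encode_document(doc, m$params, m$vocab)
  expect_identical(e1$e, e2$e)
  # widening the padding frame must not change the embedding
  e3 <- encode_document(doc, m$params, m$vocab, max_sents = 7L,
                        max_words = 11L)
  expect_equal(e1$e, e3$e, tolerance = 1e-12)
  # duplicated sentences yield identical sentence vectors (word-level
  # pooling is per sentence); their attention weights may differ slightly
  # because sentence-level Bi-GRU annotations carry positional context
  e4 <- encode_document(list(c("a", "b"), c("a", "b")), m$params, m$vocab)
  expect_equal(e4$sentence_vectors[1, ], e4$sentence_vectors[2, ],
               tolerance = 1e-12)
  expect_equal(e4$word_attention[[1]], e4$word_attention[[2]],
               tolerance = 1e-12)
})

test_that("autodiff gradients match finite differences on a tiny instance", {
  spec <- synthetic_spec(n_records = 8L, n_labels = 3L,
                         sentences_range = c(2L, 3L), words_range = c(3L, 5L),
                         seed = 7)
  corp <- generate_corpus(spec)
  cfg <- knowdiag_config(embed_dim = 4L, hidden = 3L, fc_hidden = 6L,
                         epochs = 0L, seed = 5L, k_budget = 3L)
  m <- knowdiag(corp$records, corp$knowledge, corp$label_vocab,
                corp$schema, cfg)
  me <- knowdiag:::kd_model_env(m)
  prep <- knowdiag:::kd_prepare(corp$records, me)
  gold <- matrix(0, 8, 3)
  for (i in 1:8) gold[i, match(corp$records[[i]]$labels, corp$label_vocab)] <- 1
  batch <- list(ids = prep$ids, mask = prep$mask, nmat = prep$nmat,
                kmask = prep$kmask)
  lossfn <- function(params) {
    knowdiag:::kd_forward_batch(params, batch, m$knowledge_padded, cfg,
                                m$k_budget, gold = gold)$loss$v[1]
  }
  fw <- knowdiag:::kd_forward_batch(m$params, batch, m$knowledge_padded, cfg,
                                    m$k_budget, gold = gold)
  knowdiag:::tape_backward(fw$tape, fw$loss)
  grads <- lapply(fw$pn, function(nd) nd$g)
  set.seed(42)
  h <- 1e-5
  for (nm in names(m$params)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    for (rep in 1:3) {
      i <- sample(length(m$params[[nm]]), 1)
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + h
      fp <- lossfn(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      fm <- lossfn(p2)
      fd <- (fp - fm) / (2 * h)
      denom <- max(1e-6, abs(fd) + abs(grads[[nm]][i]))
      expect_lt(abs(fd - grads[[nm]][i]) / denom, 1e-4)
    }
  }
})
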