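test_that("TF-IDF follows the smoothed formulation", {
  corpus <- list(c("a", "b"), c("a"), c("c"))
  m <- tfidf_fit(corpus)
  # "a" appears in 2 of 3 docs; smoothed IDF = log(4/3) + 1
  expect_equal(unname(m$idf["a"]), log(4 / 3) + 1)
  # a word present in every document keeps IDF exactly 1
  m2 <- tfidf_fit(list(c("x", "y"), c("x"), c("x", "z")))
  expect_equal(unname(m2$idf["x"]), 1)

  v1 <- tfidf_vector(corpus[[1]], m)
  expect_equal(unname(v1["a"]), 0.5 * (log(4 / 3) + 1))
  expect_equal(unname(v1["b"]), 0.5 * (log(4 / 2) + 1))
  expect_equal(sort(names(v1)), c("a", "b"))      # support is the word set
  expect_length(tfidf_vector(character(0), m), 0L)
  expect_length(tfidf_vector("zzz", m), 0L)       # OOV ignored
  expect_error(tfidf_fit(list(character(0))), "empty")
})

test_that("TF-IDF agrees with a naive two-pass counting oracle", {
  set.seed(13)
  vocabulary <- letters[1:9]
  for (trial in 1:25) {
    corpus <- lapply(1:sample(2:6, 1), function(i)
      sample(vocabulary, sample(1:12, 1), replace = TRUE))
    m <- tfidf_fit(corpus)
    for (d in corpus) {
      got <- tfidf_vector(d, m)
      want <- oracle_tfidf(d, corpus)
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-9)
    }
  }
})

test_that("cosine similarity handles named vectors and zero norms", {
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)
  v <- c(a = 1, b = 2)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(a = 1), c(b = 1)), 0)
  expect_equal(cosine_similarity(c(a = 0), c(a = 3)), 0)
  set.seed(3)
  for (i in 1:10) {
    u <- setNames(rnorm(4), letters[1:4])
    w <- setNames(rnorm(3), letters[3:5])
    expect_equal(cosine_similarity(u, w), oracle_cosine(u, w),
                 tolerance = 1e-12)
  }
})

test_that("the knowledge filter keeps documents at or above the cutoff", {
  kn <- list(rel = c("x", "x", "y"), unrel = c("p", "q"))
  m <- tfidf_fit(c(list(c("x", "y", "x")), kn))
  fk <- filter_knowledge(c("x", "y", "x"), kn, m)
  expect_true(fk$kept[fk$concept_id == "rel"])       # near-identical text
  expect_false(fk$kept[fk$concept_id == "unrel"])    # zero vocabulary overlap
  expect_equal(fk$cosine[fk$concept_id == "unrel"], 0)

  # a constructed pair straddling the 0.5 rule
  rec <- c(rep("s", 9), "t")
  below <- c(rep("s", 1), rep("u", 3))
  above <- c(rep("s", 3), rep("u", 1))
  m2 <- tfidf_fit(list(rec, below, above))
  fk2 <- filter_knowledge(rec, list(lo = below, hi = above), m2)
  expect_lt(fk2$cosine[fk2$concept_id == "lo"], 0.5)
  expect_gte(fk2$cosine[fk2$concept_id == "hi"], 0.5)
  expect_equal(fk2$kept, fk2$concept_id == "hi")
})

test_that("raising the filter threshold never adds a document", {
  set.seed(29)
  vocabulary <- letters[1:8]
  for (trial in 1:10) {
    rec <- sample(vocabulary, 10, replace = TRUE)
    kn <- lapply(1:4, function(i) sample(vocabulary, 6, replace = TRUE))
    names(kn) <- paste0("k", 1:4)
    m <- tfidf_fit(c(list(rec), kn))
    kept_prev <- NULL
    for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      kept <- filter_knowledge(rec, kn, m, threshold = th)$kept
      if (!is.null(kept_prev)) expect_true(all(kept_prev | !kept))
      kept_prev <- kept
    }
  }
})

test_that("the aggregator selects top-k and zero-pads short survivor lists", {
  set.seed(41)
  W <- diag(4)
  e <- c(1, 0.5, -0.2, 0.1)
  # one surviving document with budget 3: full weight, k' = that vector
  K1 <- matrix(rnorm(4), 1, 4, dimnames = list("c1", NULL))
  ag1 <- aggregate_knowledge(e, K1, 3, list(W = W), "bilinear")
  expect_equal(ag1$alpha_selected, c(c1 = 1))
  expect_equal(ag1$k_prime, unname(K1[1, ]))
  expect_equal(ag1$selected, "c1")
  # identical embeddings share attention equally
  K2 <- matrix(rep(c(1, 2, 0, -1), each = 5), 5, 4,
               dimnames = list(paste0("c", 1:5), NULL))
  ag2 <- aggregate_knowledge(e, K2, 2, list(W = W), "bilinear")
  expect_equal(unname(ag2$alpha), rep(0.2, 5))
  expect_equal(ag2$selected, c("c1", "c2"))          # tie-break by concept id
  # no survivors at all: legal degenerate case with a zero vector
  ag0 <- aggregate_knowledge(e, matrix(0, 0, 4), 2, list(W = W))
  expect_equal(ag0$k_prime, rep(0, 4))
  expect_length(ag0$selected, 0L)
})

test_that("aggregation matches exhaustive enumeration on small instances", {
  set.seed(43)
  for (score in c("bilinear", "dot", "additive")) {
    for (trial in 1:10) {
      j <- sample(2:6, 1)
      d <- 3L
      K <- matrix(rnorm(j * d), j, d, dimnames = list(paste0("c", 1:j), NULL))
      e <- rnorm(d)
      p <- list(W = matrix(rnorm(d * d), d), U = matrix(rnorm(d * d), d),
                v = rnorm(d))
      kb <- sample(1:j, 1)
      got <- aggregate_knowledge(e, K, kb, p, score)
      # independent evaluation: score, softmax, sort, renormalised sum
      s <- sapply(seq_len(j), function(t) {
        switch(score,
               bilinear = sum(K[t, ] * (p$W %*% e)),
               dot = sum(K[t, ] * e),
               additive = sum(tanh(as.numeric(e %*% p$W) + K[t, ] %*% p$U) * p$v))
      })
      a <- exp(s - max(s)); a <- a / sum(a)
      ord <- order(-a, seq_len(j))
      sel <- ord[seq_len(kb)]
      w <- a[sel] / sum(a[sel])
      kp <- rep(0, d)
      for (q in seq_along(sel)) kp <- kp + w[q] * K[sel[q], ]
      expect_equal(unname(got$alpha), a, tolerance = 1e-9)
      expect_equal(got$selected, paste0("c", sel))
      expect_equal(got$k_prime, kp, tolerance = 1e-9)
      expect_equal(sum(got$alpha), 1, tolerance = 1e-12)
      expect_equal(sum(got$alpha_selected), 1, tolerance = 1e-12)
    }
  }
})

test_that("the knowledge budget is the ceiling of the mean label count", {
  # label counts whose mean is exactly 2.688
  counts <- c(rep(2, 312), rep(3, 688))
  recs <- lapply(seq_along(counts), function(i)
    mk_record(paste0("r", i), "x.", paste0("D", seq_len(counts[i]))))
  expect_equal(choose_k_budget(recs), 3L)            # 2.688 -> 3
  ones <- lapply(1:5, function(i) mk_record("r", "x.", "D1"))
  expect_equal(choose_k_budget(ones), 1L)
  mix <- lapply(1:3, function(k) mk_record("r", "x.", paste0("D", 1:k)))
  expect_equal(choose_k_budget(mix), 2L)             # mean 2 -> 2
  expect_error(choose_k_budget(list(mk_record("r", "x.", character(0)))),
               "labels")
})

test_that("an unreachable filter threshold zeroes the aggregated knowledge", {
  spec <- synthetic_spec(n_records = 20L, n_labels = 3L, seed = 9)
  corp <- generate_corpus(spec)
  cfg <- knowdiag_config(embed_dim = 4L, hidden = 3L, fc_hidden = 6L,
                         epochs = 0L, seed = 1L, filter_threshold = 1 + 1e-9)
  m <- knowdiag(corp$records, corp$knowledge, corp$label_vocab,
                corp$schema, cfg)
  me <- knowdiag:::kd_model_env(m)
  prep <- knowdiag:::kd_prepare(corp$records, me)
  expect_true(all(prep$kmask == 0))
  pr <- predict(m, corp$records[1:4], type = "both")
  expect_true(all(pr$alpha == 0))
})
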