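# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (double loops, literal formula transcriptions) and
# share no code with the package implementations they check.

# scalar transcription of the four GRU equations, one hidden unit at a time
oracle_gru_step <- function(x, h_prev, p) {
  H <- length(h_prev)
  sig <- function(a) 1 / (1 + exp(-a))
  h_new <- numeric(H)
  r <- numeric(H); z <- numeric(H)
  for (k in seq_len(H)) {
    r[k] <- sig(sum(x * p$Wr[, k]) + sum(h_prev * p$Ur[, k]) + p$br[k])
    z[k] <- sig(sum(x * p$Wz[, k]) + sum(h_prev * p$Uz[, k]) + p$bz[k])
  }
  for (k in seq_len(H)) {
    hc <- tanh(sum(x * p$Wh[, k]) + sum((r * h_prev) * p$Uh[, k]) + p$bh[k])
    h_new[k] <- (1 - z[k]) * h_prev[k] + z[k] * hc
  }
  h_new
}

oracle_attention_pool <- function(ann, mask, p) {
  T_ <- nrow(ann)
  score <- numeric(T_)
  for (t in seq_len(T_)) {
    u <- tanh(as.numeric(ann[t, ] %*% p$W) + p$b)
    score[t] <- sum(u * p$u)
  }
  w <- exp(score)
  w[mask == 0] <- 0
  alpha <- w / sum(w)
  pooled <- rep(0, ncol(ann))
  for (t in seq_len(T_)) pooled <- pooled + alpha[t] * ann[t, ]
  list(pooled = pooled, alpha = alpha)
}

# two-pass counting TF-IDF: component = (count/len) * (log((1+D)/(1+df)) + 1)
oracle_tfidf <- function(doc, corpus) {
  D <- length(corpus)
  terms <- sort(unique(unlist(corpus)))
  df <- sapply(terms, function(w) sum(sapply(corpus, function(d) w %in% d)))
  out <- numeric(0)
  for (w in unique(doc)) {
    if (!(w %in% terms)) next
    tf <- sum(doc == w) / length(doc)
    out[w] <- tf * (log((1 + D) / (1 + df[[w]])) + 1)
  }
  out
}

oracle_cosine <- function(u, v) {
  keys <- union(names(u), names(v))
  a <- sapply(keys, function(k) if (k %in% names(u)) u[[k]] else 0)
  b <- sapply(keys, function(k) if (k %in% names(v)) v[[k]] else 0)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# ranks 1-based by decreasing score, ties broken by label index
oracle_ranks <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s)); r[ord] <- seq_along(s)
  r
}

oracle_average_precision <- function(scores, gold) {
  vals <- c()
  for (i in seq_len(nrow(scores))) {
    rel <- which(gold[i, ] == 1)
    if (!length(rel)) next
    r <- oracle_ranks(scores[i, ])
    s <- 0
    for (l in rel) {
      cnt <- 0
      for (l2 in rel) if (r[l2] <= r[l]) cnt <- cnt + 1
      s <- s + cnt / r[l]
    }
    vals <- c(vals, s / length(rel))
  }
  mean(vals)
}

oracle_one_error <- function(scores, gold) {
  vals <- c()
  for (i in seq_len(nrow(scores))) {
    if (!any(gold[i, ] == 1)) next
    r <- oracle_ranks(scores[i, ])
    vals <- c(vals, as.numeric(gold[i, which(r == 1)] != 1))
  }
  mean(vals)
}

oracle_hamming <- function(scores, gold, tau = 0.5) {
  bad <- 0
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores))) {
    pred <- scores[i, j] > tau
    if (pred != (gold[i, j] == 1)) bad <- bad + 1
  }
  bad / (nrow(scores) * ncol(scores))
}

oracle_ranking_loss <- function(scores, gold) {
  vals <- c()
  for (i in seq_len(nrow(scores))) {
    rel <- which(gold[i, ] == 1); irr <- which(gold[i, ] == 0)
    if (!length(rel) || !length(irr)) next
    bad <- 0
    for (a in rel) for (b in irr) {
      if (scores[i, a] < scores[i, b]) bad <- bad + 1
      else if (scores[i, a] == scores[i, b]) bad <- bad + 0.5
    }
    vals <- c(vals, bad / (length(rel) * length(irr)))
  }
  mean(vals)
}

oracle_coverage <- function(scores, gold) {
  vals <- c()
  for (i in seq_len(nrow(scores))) {
    rel <- which(gold[i, ] == 1)
    if (!length(rel)) next
    r <- oracle_ranks(scores[i, ])
    vals <- c(vals, max(r[rel]) - 1)
  }
  mean(vals)
}

# random GRU/attention parameter factories
rand_gru <- function(din, H) {
  m <- function(a, b) matrix(stats::rnorm(a * b, sd = 0.5), a, b)
  list(Wr = m(din, H), Wz = m(din, H), Wh = m(din, H),
       Ur = m(H, H), Uz = m(H, H), Uh = m(H, H),
       br = stats::rnorm(H, sd = 0.3), bz = stats::rnorm(H, sd = 0.3),
       bh = stats::rnorm(H, sd = 0.3))
}

rand_attn <- function(D) {
  list(W = matrix(stats::rnorm(D * D, sd = 0.5), D, D),
       b = stats::rnorm(D, sd = 0.3), u = stats::rnorm(D, sd = 0.5))
}

# tiny labelled record helper
mk_record <- function(id, text, labels, numeric_raw = character(0)) {
  list(record_id = id, text = text, labels = labels,
       numeric_raw = numeric_raw)
}
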