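# Synthetic multilabel clinical corpora.
#
# The generator emulates the statistical structure the diagnosis model
# assumes in real obstetric records, at desk scale: multi-sentence
# documents; label sets of ~2.7 labels per record (zero-truncated Poisson);
# per-label signature vocabularies planted in the text of records carrying
# the label, with the first-drawn (primary) label contributing the most
# tokens, as a main diagnosis dominates a clinical narrative; exactly one
# knowledge document per label written predominantly in that label's
# signature vocabulary (so TF-IDF retrieval has real signal); bounded
# numeric features with label-conditional shifts and a configurable
# fraction of corrupted (out-of-range) values to exercise validation.
# Tokens are synthetic ASCII symbols; everything is reproducible from the
# seed.

#' Specification of a synthetic corpus
#'
#' @param n_records Number of records.
#' @param n_labels Number of labels (= number of knowledge documents).
#' @param mu_labels Target mean label-set size (zero-truncated Poisson).
#' @param sig_tokens_per_label Signature vocabulary size per label.
#' @param noise_tokens Size of the shared background vocabulary.
#' @param p_signature Probability that a record token is drawn from its
#'   labels' signature vocabularies rather than the background.
#' @param primary_weight Share of signature tokens drawn from the primary
#'   (first-drawn) label; the remainder is split over the other labels.
#' @param distractor_rate Fraction of signature draws taken from a random
#'   label the record does NOT carry, emulating mentions of ruled-out or
#'   misleading symptoms in clinical narratives.  Distractor tokens are
#'   scattered, so they confuse token-level evidence without reaching the
#'   TF-IDF cosine a knowledge document needs to pass the filter.
#' @param rare_tokens_per_label Size of each label's rare-symptom pool:
#'   tokens described prominently in the label's knowledge document but
#'   seldom written in records, so their meaning is learnable mainly from
#'   the knowledge text.
#' @param atypical_rate Fraction of records with an atypical presentation,
#'   whose primary-label tokens are drawn mostly from the rare pool.
#' @param atypical_rare_share Share of primary signature draws taken from
#'   the rare pool in an atypical record.
#' @param common_rare_share The same share for typical records (small).
#' @param knowledge_rare_share Share of rare-pool tokens in a knowledge
#'   document.
#' @param sentences_range,words_range Integer ranges (min, max) for
#'   sentences per record and words per sentence.
#' @param knowledge_sentences,knowledge_words Size of each knowledge
#'   document.
#' @param knowledge_noise Fraction of background tokens in knowledge
#'   documents.
#' @param numeric_corruption Probability that a numeric field is corrupted
#'   to an implausible (out-of-range) value.
#' @param seed Mandatory RNG seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 600L, n_labels = 8L, mu_labels = 2.7,
                           sig_tokens_per_label = 12L, noise_tokens = 30L,
                           p_signature = 0.8, primary_weight = 0.6,
                           distractor_rate = 0.12,
                           rare_tokens_per_label = 24L, atypical_rate = 0.15,
                           atypical_rare_share = 0.7, common_rare_share = 0.05,
                           knowledge_rare_share = 0.15,
                           sentences_range = c(3L, 6L),
                           words_range = c(6L, 10L),
                           knowledge_sentences = 8L, knowledge_words = 12L,
                           knowledge_noise = 0.1,
                           numeric_corruption = 0.03, seed) {
  if (missing(seed)) stop("synthetic_spec: a seed is mandatory")
  stopifnot(mu_labels >= 1, mu_labels <= n_labels,
            p_signature >= 0, p_signature <= 1,
            numeric_corruption >= 0, numeric_corruption <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# lambda of a zero-truncated Poisson with the requested mean
ztp_lambda <- function(mu) {
  if (mu <= 1) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mu,
                 c(1e-8, 4 * mu))$root
}

#' Generate a synthetic corpus
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records`, `knowledge`, `label_vocab` and `schema`
#'   (the [example_feature_schema()], whose thresholds the corrupted values
#'   violate).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  c_ <- spec$n_labels
  labels <- sprintf("D%02d", seq_len(c_))
  sig <- lapply(seq_len(c_), function(l)
    sprintf("L%d_sig_%02d", l, seq_len(spec$sig_tokens_per_label)))
  names(sig) <- labels
  rare <- lapply(seq_len(c_), function(l)
    sprintf("L%d_rare_%02d", l, seq_len(spec$rare_tokens_per_label)))
  names(rare) <- labels
  noise <- sprintf("noise_%03d", seq_len(spec$noise_tokens))
  lambda <- ztp_lambda(spec$mu_labels)
  schema <- example_feature_schema()
  feat_names <- vapply(schema$features, function(f) f$name, "")
  base_mean <- c(age = 28, menopause = 5, uterine_height = 30)
  base_sd <- c(age = 5, menopause = 2, uterine_height = 4)
  # label-conditional shifts on named features (cyclic over features)
  effect <- lapply(seq_len(c_), function(l) {
    f <- feat_names[(l - 1L) %% length(feat_names) + 1L]
    stats::setNames(1.5 * base_sd[[f]] * (1 - 0.5 * ((l - 1L) %/% length(feat_names))), f)
  })
  names(effect) <- labels

  knowledge <- lapply(labels, function(lab) {
    sents <- replicate(spec$knowledge_sentences, {
      n_w <- spec$knowledge_words
      u <- stats::runif(n_w)
      w <- character(n_w)
      is_noise <- u < spec$knowledge_noise
      is_rare <- !is_noise & u < spec$knowledge_noise + spec$knowledge_rare_share
      is_sig <- !is_noise & !is_rare
      w[is_sig] <- sample(sig[[lab]], sum(is_sig), replace = TRUE)
      w[is_rare] <- sample(rare[[lab]], sum(is_rare), replace = TRUE)
      w[is_noise] <- sample(noise, sum(is_noise), replace = TRUE)
      paste(w, collapse = " ")
    })
    list(concept_id = lab, text = paste0(sents, ".", collapse = " "))
  })

  records <- vector("list", spec$n_records)
  for (i in seq_len(spec$n_records)) {
    k <- if (spec$mu_labels <= 1) 1L else {
      kk <- 0L
      while (kk < 1L) kk <- stats::rpois(1L, lambda)
      kk
    }
    k <- min(k, c_)
    labs <- sample(labels, k)                 # first drawn label is primary
    lw <- if (k == 1L) 1 else
      c(spec$primary_weight, rep((1 - spec$primary_weight) / (k - 1L), k - 1L))
    atypical <- stats::runif(1) < spec$atypical_rate
    rare_share <- if (atypical) spec$atypical_rare_share else
      spec$common_rare_share
    n_sents <- sample(spec$sentences_range[1]:spec$sentences_range[2], 1L)
    sents <- vapply(seq_len(n_sents), function(s) {
      n_w <- sample(spec$words_range[1]:spec$words_range[2], 1L)
      w <- vapply(seq_len(n_w), function(j) {
        if (stats::runif(1) < spec$p_signature) {
          other <- setdiff(labels, labs)
          if (length(other) && stats::runif(1) < spec$distractor_rate) {
            sample(sig[[sample(other, 1L)]], 1L)
          } else {
            pick <- sample.int(k, 1L, prob = lw)
            lab <- labs[pick]
            # atypical presentations voice the primary label in rare symptoms
            pool <- if (pick == 1L && stats::runif(1) < rare_share)
              rare[[lab]] else sig[[lab]]
            sample(pool, 1L)
          }
        } else sample(noise, 1L)
      }, "")
      paste(w, collapse = " ")
    }, "")
    text <- paste0(sents, ".", collapse = " ")

    num <- character(0)
    for (j in seq_along(schema$features)) {
      f <- schema$features[[j]]
      mu <- base_mean[[f$name]] +
        sum(vapply(labs, function(l) {
          e <- effect[[l]]
          if (f$name %in% names(e)) e[[f$name]] else 0
        }, 0))
      val <- stats::rnorm(1L, mu, base_sd[[f$name]])
      val <- min(max(val, f$min + 0.1), f$max - 0.1)
      raw <- sprintf("%.1f", val)
      if (f$name == "menopause" && stats::runif(1) < 0.25) {
        raw <- sprintf("%.1f weeks", val * 4)   # alternative unit in the wild
      }
      if (stats::runif(1) < spec$numeric_corruption) {
        raw <- sprintf("%.1f", f$max + 5 + abs(stats::rnorm(1L, 0, 10 * (f$max - f$min))))
      }
      num[[f$name]] <- raw
    }
    records[[i]] <- list(record_id = sprintf("R%05d", i), text = text,
                         labels = labs, numeric_raw = num)
  }
  list(records = records, knowledge = knowledge, label_vocab = labels,
       schema = schema)
}

#' Score-matrix fixtures for metric tests
#'
#' `perfect` ranks every relevant label above every irrelevant one (scores
#' in (0.6, 1) vs (0, 0.4)); `inverted` is the reverse; `random` draws all
#' scores i.i.d. uniform.  Gold rows always have between 1 and c-1
#' relevant labels.
#'
#' @param n,c Matrix dimensions.
#' @param structure One of "perfect", "inverted", "random".
#' @param seed RNG seed.
#' @return List with `scores` and `gold` (n x c matrices).
#' @export
generate_score_fixture <- function(n, c, structure = c("perfect", "inverted",
                                                       "random"), seed) {
  structure <- match.arg(structure)
  set.seed(seed)
  gold <- matrix(0L, n, c)
  for (i in seq_len(n)) {
    k <- sample.int(c - 1L, 1L)
    gold[i, sample.int(c, k)] <- 1L
  }
  scores <- matrix(stats::runif(n * c), n, c)
  if (structure == "perfect") {
    scores <- ifelse(gold == 1L, 0.6 + 0.4 * scores, 0.4 * scores)
  } else if (structure == "inverted") {
    scores <- ifelse(gold == 1L, 0.4 * scores, 0.6 + 0.4 * scores)
  }
  list(scores = scores, gold = gold)
}
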