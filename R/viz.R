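# Attention interpretability exports.
#
# Static HTML (no scripts): one line per sentence with a red background
# shade for the sentence weight and a blue shade per token for the word
# weight, each level min-max normalised across the document; and a row
# diagram of knowledge attention with weights below a display cutoff
# (default 1e-3) omitted.  Normalised weights are carried in data-*
# attributes so rendered documents can be parsed back and checked.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

minmax <- function(w) {
  if (!length(w)) return(numeric(0))
  rng <- range(w)
  if (diff(rng) < 1e-12) return(rep(1, length(w)))
  (w - rng[1]) / diff(rng)
}

#' Render word/sentence attention of a document as an HTML heatmap
#'
#' @param encoded An `encoded_doc` from [encode_document()].
#' @param tokens Tokenized document (list of token vectors) matching the
#'   encoding.
#' @param path Output HTML path.
#' @param mode `"plain"` normalises word weights within the document;
#'   `"scaled"` multiplies each word weight by its sentence weight first,
#'   so only important words of important sentences stand out.
#' @return The output path, invisibly.
#' @export
render_document_attention <- function(encoded, tokens, path,
                                      mode = c("plain", "scaled")) {
  mode <- match.arg(mode)
  if (!length(tokens)) stop("render_document_attention: empty document")
  L <- encoded$n_sentences
  sw <- minmax(encoded$sentence_attention[seq_len(L)])
  rows <- character(L)
  for (i in seq_len(L)) {
    wa <- encoded$word_attention[[i]]
    if (mode == "scaled") wa <- wa * encoded$sentence_attention[i]
    ww <- minmax(wa)
    toks <- tokens[[i]][seq_along(ww)]
    spans <- sprintf(
      '<span class="w" data-weight="%.6f" style="background: rgba(0,0,255,%.3f)">%s</span>',
      ww, 0.75 * ww, html_escape(toks))
    rows[i] <- sprintf(
      '<div class="s" data-weight="%.6f" style="background: rgba(255,0,0,%.3f)">%s</div>',
      sw[i], 0.35 * sw[i], paste(spans, collapse = " "))
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            "<style>.s{margin:2px;padding:2px}.w{padding:1px}</style>",
            "<title>Document attention</title></head><body>",
            rows, "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' Render knowledge attention as an HTML diagram
#'
#' One row per knowledge concept whose attention weight reaches the
#' display cutoff; row intensity is proportional to the weight.  All
#' weights below the cutoff (default 1e-3) are removed from the
#' visualization.
#'
#' @param alpha Named numeric vector of attention weights over concepts
#'   (e.g. `alpha` from [aggregate_knowledge()] or a row of
#'   `predict(..., type = "both")$alpha`).
#' @param path Output HTML path.
#' @param cutoff Minimum weight displayed.
#' @return The output path, invisibly.
#' @export
render_knowledge_attention <- function(alpha, path, cutoff = 1e-3) {
  keep <- which(alpha >= cutoff)
  keep <- keep[order(-alpha[keep])]
  rows <- if (length(keep)) {
    shade <- alpha[keep] / max(alpha[keep])
    sprintf(paste0('<div class="k" data-alpha="%.6f" ',
                   'style="background: rgba(0,128,0,%.3f)">%s (%.4f)</div>'),
            alpha[keep], 0.75 * shade, html_escape(names(alpha)[keep]),
            alpha[keep])
  } else {
    "<p>No knowledge attention above the display cutoff.</p>"
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            "<style>.k{margin:2px;padding:3px}</style>",
            "<title>Knowledge attention</title></head><body>",
            rows, "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
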