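#' Per-word self-information (surprisal) in bits
#'
#' The self-information of a word is the negative base-2 logarithm of its
#' probability under a trained statistical model. For the word unigram
#' model this is `-log2 P(word)`; for morph-based unigram models it is the
#' sum of `-log2 P(morph)` over the word's analysis; context-dependent
#' models (morph bigram, category HMM) additionally include word-start and
#' word-end terms. Unscorable words are returned as `NA` and carry through
#' downstream analyses as missing.
#'
#' @param model a trained model (`word_unigram`, `morph_ngram`,
#'   `mdl_model`, or `category_model`).
#' @param words character vector of query words.
#' @param ... method-specific arguments; supervised morph models accept
#'   `segmentations`, a named list overriding the training-time lookup.
#' @return named numeric vector of bits (>= 0 up to rounding), with
#'   attribute `model_name`.
#' @export
self_information <- function(model, words, ...) UseMethod("self_information")

surprisal_vector <- function(values, words, model_name) {
  structure(stats::setNames(as.numeric(values), words),
            model_name = model_name)
}

#' @export
self_information.word_unigram <- function(model, words, ...) {
  p <- model$probs[words]
  bits <- -log2(unname(p))
  miss <- is.na(p)
  if (any(miss)) {
    if (model$smoothing$oov == "strict") {
      bits[miss] <- NA_real_
    } else {
      bits[miss] <- vapply(words[miss], function(w)
        letter_string_bits(w, model$letter_probs) + log2(model$total + 1), 0.0)
    }
  }
  surprisal_vector(bits, words, model$model_name)
}

#' @export
self_information.morph_ngram <- function(model, words, segmentations = NULL, ...) {
  bits <- vapply(words, function(w) {
    s <- resolve_segmentation(model, w, segmentations[[w]])
    if (is.null(s)) return(NA_real_)
    if (model$order == 1L) {
      p <- morph_unigram_prob(model, s)
    } else {
      p <- morph_bigram_prob(model, c("<w>", s), c(s, "</w>"))
    }
    if (anyNA(p) || any(p <= 0)) return(NA_real_)
    -sum(log2(p))
  }, 0.0)
  surprisal_vector(bits, words, model$model_name)
}

#' @export
self_information.mdl_model <- function(model, words, fallback = TRUE, ...) {
  bits <- vapply(words, function(w) {
    s <- viterbi_segment(model, w, fallback = fallback)
    if (is.null(s)) return(NA_real_)
    -attr(s, "log2prob")
  }, 0.0)
  surprisal_vector(bits, words, model$model_name)
}

#' Cross-entropy of a model over a word set
#'
#' The arithmetic mean of per-word self-information, in bits per word;
#' computed through the same code path as [self_information()] so the two
#' agree exactly.
#'
#' @inheritParams self_information
#' @return mean bits per word.
#' @export
cross_entropy <- function(model, words, ...) {
  stopifnot(length(words) > 0)
  bits <- self_information(model, words, ...)
  if (anyNA(bits))
    stop("unscorable words: ", paste(words[is.na(bits)], collapse = ", "))
  mean(bits)
}

#' Score a set of words under several models
#'
#' @param models named list of trained models.
#' @param words character vector of words.
#' @param ... passed to [self_information()] (e.g. `segmentations`).
#' @return data.frame with a `word` column and one bits column per model.
#' @export
surprisal_table <- function(models, words, ...) {
  out <- data.frame(word = words, stringsAsFactors = FALSE)
  for (nm in names(models))
    out[[nm]] <- unname(self_information(models[[nm]], words, ...))
  out
}

#' Write a surprisal table in long TSV form (word, model, bits)
#' @param tab a data.frame from [surprisal_table()].
#' @param path output file.
#' @export
write_surprisal_tsv <- function(tab, path) {
  long <- do.call(rbind, lapply(setdiff(names(tab), "word"), function(m)
    data.frame(word = tab$word, model = m, bits = tab[[m]])))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
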