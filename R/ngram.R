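#' Smoothing descriptor for n-gram models
#'
#' @param method `"ml"` for unsmoothed maximum likelihood, or
#'   `"absolute_discount"` for interpolated absolute discounting against a
#'   letter-model base distribution.
#' @param discount discount mass subtracted from each observed count
#'   (absolute discounting only).
#' @return list of class `smoothing`.
#' @export
smoothing <- function(method = c("absolute_discount", "ml"), discount = 0.5) {
  method <- match.arg(method)
  if (method == "absolute_discount")
    stopifnot(discount > 0, discount < 1)
  structure(list(method = method, discount = discount), class = "smoothing")
}

check_smoothing <- function(x) {
  if (!inherits(x, "smoothing"))
    stop("unknown smoothing descriptor; use smoothing()")
  x
}

#' Train a word unigram model on surface frequencies
#'
#' Word probabilities are maximum-likelihood token frequencies
#' `count / total_tokens`. Out-of-vocabulary queries are scored by the
#' letter-model escape `P0(w) / (total + 1)` under the `"letter"` policy,
#' or marked unscorable (`NA`) under `"strict"`.
#'
#' @param corpus a [token_counts()] object.
#' @param oov out-of-vocabulary policy.
#' @return object of class `word_unigram`.
#' @export
train_word_unigram <- function(corpus, oov = c("letter", "strict")) {
  stopifnot(inherits(corpus, "token_counts"), length(corpus$entries) > 0)
  oov <- match.arg(oov)
  structure(
    list(probs = corpus$entries / corpus$total_tokens,
         total = corpus$total_tokens,
         letter_probs = letter_probs(corpus),
         smoothing = list(method = "ml", oov = oov),
         model_name = "word_unigram"),
    class = c("word_unigram", "surprisal_model"))
}

# token counts over units, weighted by word counts
morph_token_counts <- function(segmentations, counts) {
  reps <- vapply(segmentations, length, 1L)
  morphs <- unlist(segmentations, use.names = FALSE)
  tapply(rep(unname(counts[names(segmentations)]), reps), morphs, sum)
}

#' Train a morph n-gram model on pre-segmented input
#'
#' Supervised counterpart of the unsupervised segmentation models: unit
#' probabilities are estimated from a gold-segmented corpus. The unigram
#' model treats morph tokens independently; the bigram model conditions
#' each morph on the previous one, with a word-start marker as initial
#' context and word-end as a terminal event. Absolute discounting
#' interpolates towards a letter-model base distribution, so every
#' observed-alphabet morph has positive probability.
#'
#' @param segmentations named list word -> character vector of morphs.
#' @param counts named numeric word counts.
#' @param order 1 (unigram) or 2 (bigram).
#' @param smooth a [smoothing()] descriptor.
#' @return object of class `morph_ngram`.
#' @export
train_morph_ngram <- function(segmentations, counts, order = 1L,
                              smooth = smoothing()) {
  stopifnot(order %in% c(1L, 2L))
  smooth <- check_smoothing(smooth)
  bad <- vapply(seq_along(segmentations), function(i)
    paste(segmentations[[i]], collapse = "") != names(segmentations)[i], TRUE)
  if (any(bad)) stop("invalid segmentation for word ",
                     names(segmentations)[which(bad)[1L]])
  uni <- morph_token_counts(segmentations, counts)
  lp <- letter_probs(token_counts(
    stats::setNames(unname(counts[names(segmentations)]), names(segmentations))))
  model <- list(order = order, unigram_counts = uni, letter_probs = lp,
                smoothing = smooth, lookup = segmentations,
                model_name = if (order == 1L) "morph_unigram" else "morph_bigram")
  if (order == 2L) {
    # bigram counts over (context, event); events include the end marker
    ctx <- character(0); ev <- character(0); wt <- numeric(0)
    for (i in seq_along(segmentations)) {
      s <- segmentations[[i]]
      c_i <- unname(counts[names(segmentations)[i]])
      ctx <- c(ctx, "<w>", s)
      ev <- c(ev, s, "</w>")
      wt <- c(wt, rep(c_i, length(s) + 1L))
    }
    key <- paste(ctx, ev, sep = "\r")
    big <- tapply(wt, key, sum)
    ctx_tot <- tapply(wt, ctx, sum)
    ctx_types <- tapply(ev, ctx, function(e) length(unique(e)))
    # base distribution for interpolation: unigram over morphs plus the
    # end event (one per word token), itself discounted against letters
    n_word_tokens <- sum(unname(counts[names(segmentations)]))
    base_counts <- c(uni, "</w>" = n_word_tokens)
    model$bigram_counts <- big
    model$context_totals <- ctx_tot
    model$context_types <- ctx_types
    model$base_counts <- base_counts
  }
  structure(model, class = c("morph_ngram", "surprisal_model"))
}

# P0: letter-model probability of a unit (end marker uses the marker prob,
# normalised so the base sums to 1 over strings plus the end event)
ngram_base_prob <- function(model, units) {
  lp <- model$letter_probs
  peom <- lp[["<EOM>"]]
  vapply(units, function(u) {
    raw <- if (u == "</w>") peom else 2^(-letter_string_bits(u, lp))
    raw / (1 + peom)
  }, 0.0)
}

# unigram probability of morphs under the model's smoothing
morph_unigram_prob <- function(model, morphs, include_end = FALSE) {
  cnts <- if (include_end) model$base_counts else model$unigram_counts
  n <- sum(cnts)
  obs <- cnts[morphs]
  obs[is.na(obs)] <- 0
  if (model$smoothing$method == "ml") {
    p <- obs / n
    p[obs == 0] <- NA_real_
    return(p)
  }
  d <- model$smoothing$discount
  t <- length(cnts)
  base <- ngram_base_prob(model, morphs)
  if (!include_end) base <- base / 1 # morph strings only; mass documented
  pmax(obs - d, 0) / n + (d * t / n) * base
}

# bigram probability of events given contexts
morph_bigram_prob <- function(model, contexts, events) {
  key <- paste(contexts, events, sep = "\r")
  obs <- model$bigram_counts[key]
  obs[is.na(obs)] <- 0
  tot <- model$context_totals[contexts]
  if (model$smoothing$method == "ml") {
    p <- as.numeric(obs) / as.numeric(tot)
    p[is.na(tot) | obs == 0] <- NA_real_
    return(p)
  }
  d <- model$smoothing$discount
  types <- model$context_types[contexts]
  lower <- morph_unigram_prob(model, events, include_end = TRUE)
  unseen_ctx <- is.na(tot)
  tot[unseen_ctx] <- 1; types[unseen_ctx] <- 0; obs[unseen_ctx] <- 0
  p <- pmax(as.numeric(obs) - d, 0) / as.numeric(tot) +
    (d * as.numeric(types) / as.numeric(tot)) * lower
  p[unseen_ctx] <- lower[unseen_ctx]
  p
}

# resolve the segmentation used to score a word with a supervised model
resolve_segmentation <- function(model, word, segmentation = NULL) {
  if (!is.null(segmentation)) return(segmentation)
  model$lookup[[word]]
}
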