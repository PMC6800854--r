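CATS <- c("prefix", "stem", "suffix", "non-morpheme")

# allowed transition structure over categories plus start/end pseudo-states;
# word-start -> suffix and prefix -> word-end are forbidden by morphotactics
allowed_transitions <- function() {
  states <- c("<s>", CATS, "</s>")
  ok <- matrix(TRUE, length(states), length(states),
               dimnames = list(states, states))
  ok[, "<s>"] <- FALSE
  ok["</s>", ] <- FALSE
  ok["<s>", "</s>"] <- FALSE
  ok["<s>", "suffix"] <- FALSE
  ok["prefix", "</s>"] <- FALSE
  ok
}

#' Train a flat category HMM over MDL segmentations
#'
#' A structured variant of the segmentation model: words are assumed to be
#' built from prefixes, stems and suffixes (plus a non-morpheme residual
#' class), and morph categories depend on the previous category. Category
#' assignments are initialised heuristically (the longest morph in a word
#' leans stem; preceding longer morphs lean prefix, following ones suffix;
#' very short strings lean non-morpheme) and refined by Viterbi-EM over
#' transition and emission tables estimated from the base model's
#' segmentations. Transitions forbidden by morphotactics stay at
#' probability zero.
#'
#' @param corpus the [token_counts()] the base model was trained on.
#' @param base a trained `mdl_model`.
#' @param n_em_iters number of Viterbi-EM iterations (>= 1).
#' @param seed recorded in the model metadata.
#' @return object of class `category_model`.
#' @export
train_category_hmm <- function(corpus, base, n_em_iters = 10L, seed = 1L) {
  if (n_em_iters < 1) stop("n_em_iters must be >= 1")
  stopifnot(inherits(base, "mdl_model"))
  segs <- base$segmentations
  counts <- corpus$entries[names(segs)]
  vocab <- names(base$lexicon)

  # heuristic initial category path per word
  init_path <- function(morphs) {
    k <- length(morphs)
    if (k == 1L) return("stem")
    stem_i <- which.max(nchar(morphs))
    cats <- character(k)
    for (p in seq_len(k)) {
      if (p == stem_i) cats[p] <- "stem"
      else if (p < stem_i) cats[p] <- if (nchar(morphs[p]) >= 2L) "prefix" else "non-morpheme"
      else cats[p] <- if (nchar(morphs[p]) >= 2L) "suffix" else "non-morpheme"
    }
    cats
  }
  paths <- lapply(segs, init_path)

  ok <- allowed_transitions()
  estimate <- function(paths) {
    tr <- matrix(0, nrow(ok), ncol(ok), dimnames = dimnames(ok))
    em <- matrix(0, length(CATS), length(vocab),
                 dimnames = list(CATS, vocab))
    for (i in seq_along(segs)) {
      p <- c("<s>", paths[[i]], "</s>")
      w <- unname(counts[i])
      for (j in seq_len(length(p) - 1L))
        tr[p[j], p[j + 1L]] <- tr[p[j], p[j + 1L]] + w
      for (j in seq_along(segs[[i]]))
        em[paths[[i]][j], segs[[i]][j]] <- em[paths[[i]][j], segs[[i]][j]] + w
    }
    tr <- tr + 0.5 * ok          # add-0.5 over allowed transitions only
    tr[!ok] <- 0
    rs <- rowSums(tr)
    tr[rs > 0, ] <- tr[rs > 0, ] / rs[rs > 0]
    em <- em + 0.1
    em <- em / rowSums(em)
    list(transitions = tr, emissions = em)
  }

  tables <- estimate(paths)
  for (it in seq_len(n_em_iters)) {
    new_paths <- lapply(segs, function(m)
      viterbi_categories(tables$transitions, tables$emissions, m)$path)
    if (identical(new_paths, paths)) { paths <- new_paths; break }
    paths <- new_paths
    tables <- estimate(paths)
  }

  structure(
    list(transitions = tables$transitions, emissions = tables$emissions,
         base = base, letter_probs = base$letter_probs,
         n_em_iters = as.integer(n_em_iters), seed = as.integer(seed),
         model_name = "category_hmm"),
    class = c("category_model", "surprisal_model"))
}

#' Most probable category path for a morph sequence
#'
#' Viterbi decoding over the category HMM, including the start and end
#' pseudo-states. Morphs absent from the emission table are scored by the
#' letter-model base distribution times the emission floor of the category.
#'
#' @param transitions,emissions tables as in a `category_model` (a
#'   `category_model` object may be passed as `transitions` instead).
#' @param morphs character vector of morphs.
#' @param letter_prob optional letter probabilities for unseen morphs.
#' @return list with `path` (categories) and `log2prob`.
#' @export
viterbi_categories <- function(transitions, emissions = NULL, morphs,
                               letter_prob = NULL) {
  if (inherits(transitions, "category_model")) {
    model <- transitions
    emissions <- model$emissions
    transitions <- model$transitions
    letter_prob <- model$letter_probs
  }
  k <- length(morphs)
  emis_lp <- function(cat, m) {
    if (m %in% colnames(emissions)) return(log2(emissions[cat, m]))
    if (is.null(letter_prob)) return(-Inf)
    floor_p <- min(emissions[cat, ])
    log2(floor_p) - letter_string_bits(m, letter_prob)
  }
  # delta[c]: best log2 prob of a path ending in category c at position p
  delta <- log2(transitions["<s>", CATS]) +
    vapply(CATS, emis_lp, 0.0, m = morphs[1L])
  back <- matrix(NA_integer_, nrow = k, ncol = length(CATS))
  if (k > 1L) for (p in 2:k) {
    new_delta <- rep(-Inf, length(CATS))
    for (ci in seq_along(CATS)) {
      step <- delta + log2(transitions[CATS, CATS[ci]])
      b <- which.max(step)
      new_delta[ci] <- step[b] + emis_lp(CATS[ci], morphs[p])
      back[p, ci] <- b
    }
    delta <- new_delta
  }
  final <- delta + log2(transitions[CATS, "</s>"])
  ci <- which.max(final)
  path <- integer(k)
  path[k] <- ci
  if (k > 1L) for (p in k:2) path[p - 1L] <- back[p, path[p]]
  list(path = CATS[path], log2prob = unname(final[ci]))
}

#' @export
self_information.category_model <- function(model, words, ...) {
  bits <- vapply(words, function(w) {
    s <- viterbi_segment(model$base, w)
    if (is.null(s)) return(NA_real_)
    vp <- viterbi_categories(model, morphs = as.character(s))
    if (is.infinite(vp$log2prob)) return(NA_real_)
    -vp$log2prob
  }, 0.0)
  surprisal_vector(bits, words, model$model_name)
}
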