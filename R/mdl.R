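#' Parameters for the MDL segmentation model
#'
#' @param alpha positive corpus-weight hyperparameter: the total cost is
#'   `lexicon cost + alpha * corpus cost`. Small values buy a compact
#'   lexicon of short, morph-like units; large values (e.g. 10) keep words
#'   whole.
#' @param seed integer seed driving the per-epoch word shuffles and the
#'   random restarts.
#' @param max_epochs maximum number of training epochs per restart.
#' @param convergence_tol minimum relative total-cost decrease per epoch;
#'   below it training stops and the model is flagged converged.
#' @param use_type_counts if TRUE each word type counts once regardless of
#'   its token frequency.
#' @param n_restarts number of search restarts (whole-word init, fully-split
#'   init, then random-split inits); the lowest-cost solution is kept.
#' @return list of class `mdl_params`.
#' @export
mdl_params <- function(alpha, seed = 1L, max_epochs = 15L,
                       convergence_tol = 1e-4, use_type_counts = FALSE,
                       n_restarts = 3L) {
  stopifnot(alpha > 0, max_epochs >= 1, convergence_tol > 0, n_restarts >= 1)
  structure(list(alpha = alpha, seed = as.integer(seed),
                 max_epochs = as.integer(max_epochs),
                 convergence_tol = convergence_tol,
                 use_type_counts = isTRUE(use_type_counts),
                 n_restarts = as.integer(n_restarts)),
            class = "mdl_params")
}

# Map every distinct character to one printable ASCII byte so that the C++
# trainer can segment at byte positions; returns the two chartr alphabets.
byte_encoding <- function(chars) {
  if (length(chars) > 94L)
    stop("alphabet has more than 94 distinct characters; not supported")
  list(from = paste(chars, collapse = ""),
       to = rawToChar(as.raw(32L + seq_along(chars))))
}

#' Train the MDL segmentation model
#'
#' Unsupervised segmentation by minimising a two-part code length: the cost
#' of storing the morph lexicon (each morph string encoded with fixed
#' letter probabilities plus an end-of-morph marker) plus `alpha` times the
#' cost of encoding the corpus as morph tokens under the maximum-likelihood
#' unigram over current lexicon counts. Training runs epochs of exhaustive
#' per-word re-analysis in seeded random order, from several restarts, and
#' the accepted total cost never increases within a restart.
#'
#' @param corpus a [token_counts()] object.
#' @param params an [mdl_params()] object.
#' @return object of class `mdl_model` with fields `lexicon` (named morph
#'   token counts), `segmentations` (named list word -> morphs),
#'   `letter_probs`, `params`, `final_cost` (bits) and `converged`.
#' @export
train_mdl_segmenter <- function(corpus, params) {
  stopifnot(inherits(corpus, "token_counts"), inherits(params, "mdl_params"))
  words <- names(corpus$entries)
  counts <- if (params$use_type_counts) rep(1, length(words)) else
    unname(corpus$entries)
  lp <- letter_probs(corpus)
  enc <- byte_encoding(setdiff(names(lp), "<EOM>"))
  ewords <- chartr(enc$from, enc$to, words)
  byte_cost <- rep(Inf, 256)
  idx <- utf8ToInt(enc$to)
  byte_cost[idx + 1L] <- -log2(lp[setdiff(names(lp), "<EOM>")])
  fit <- mdl_train_cpp(ewords, counts, params$alpha, byte_cost,
                       -log2(lp[["<EOM>"]]), params$max_epochs,
                       params$convergence_tol, params$seed,
                       params$n_restarts, 10L)
  segs <- lapply(fit$segmentations, function(s) chartr(enc$to, enc$from, s))
  names(segs) <- words
  lex <- fit$lexicon
  names(lex) <- chartr(enc$to, enc$from, names(lex))
  if (!fit$converged)
    warning("MDL training did not meet the convergence tolerance within max_epochs")
  structure(
    list(lexicon = lex, segmentations = segs, letter_probs = lp,
         params = params, final_cost = fit$final_cost,
         converged = fit$converged, n_morph_tokens = fit$n_morph_tokens,
         model_name = sprintf("mdl_alpha_%g", params$alpha)),
    class = c("mdl_model", "surprisal_model"))
}

#' @export
print.mdl_model <- function(x, ...) {
  cat(sprintf("MDL segmentation model (alpha = %g): %d morph types, cost %.1f bits%s\n",
              x$params$alpha, length(x$lexicon), x$final_cost,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Total two-part cost of a set of segmentations
#'
#' Evaluates `lexicon cost + alpha * corpus cost` for an arbitrary
#' assignment of segmentations to corpus words, under the given letter
#' probabilities. This is the objective minimised by
#' [train_mdl_segmenter()].
#'
#' @param segmentations named list word -> character vector of morphs.
#' @param counts named numeric word counts (aligned by name).
#' @param lp letter probabilities from [letter_probs()].
#' @param alpha corpus weight.
#' @return total cost in bits.
#' @export
mdl_cost <- function(segmentations, counts, lp, alpha) {
  morphs <- unlist(segmentations, use.names = FALSE)
  reps <- vapply(segmentations, length, 1L)
  mc <- tapply(rep(counts[names(segmentations)], reps), morphs, sum)
  n <- sum(mc)
  corpus_cost <- n * log2(n) - sum(mc * log2(mc))
  lex_cost <- sum(vapply(names(mc), letter_string_bits, 0.0, lp = lp))
  lex_cost + alpha * corpus_cost
}

#' Segment a word with a trained MDL model
#'
#' Dynamic programming over split points, maximising the product of
#' morph-unigram probabilities under the model lexicon. With
#' `fallback = TRUE` a morph absent from the lexicon receives escape mass
#' `P0(m) / (N + 1)` where `P0` is the letter-model string probability;
#' with `fallback = FALSE` words not coverable by lexicon morphs are
#' unscorable and `NULL` is returned. Ties are broken by preferring fewer
#' morphs, then longer leftmost morphs.
#'
#' @param model an `mdl_model`.
#' @param word non-empty string.
#' @param fallback score out-of-lexicon morphs by the letter model?
#' @return character vector of morphs with attribute `log2prob`, or `NULL`
#'   if the word is unscorable.
#' @export
viterbi_segment <- function(model, word, fallback = TRUE) {
  stopifnot(nzchar(word))
  n <- nchar(word)
  N <- model$n_morph_tokens
  lp <- model$letter_probs
  chars <- strsplit(word, "")[[1L]]
  known_chars <- chars %in% names(lp)
  # log2 prob of substring [i, j]
  sub <- substring(word, rep(1:n, each = n), rep(1:n, times = n))
  dim(sub) <- c(n, n) # sub[j, i] = substring starting i ending j
  best <- rep(-Inf, n + 1L); best[1L] <- 0
  nmorph <- rep(0L, n + 1L)
  back <- rep(NA_integer_, n + 1L)
  for (j in 1:n) {
    for (i in 1:j) {
      m <- sub[j, i]
      cnt <- model$lexicon[m]
      if (!is.na(cnt)) {
        lpm <- log2(cnt) - log2(N)
      } else if (fallback && all(known_chars[i:j])) {
        lpm <- -letter_string_bits(m, lp) - log2(N + 1)
      } else next
      cand <- best[i] + lpm
      better <- cand > best[j + 1L] + 1e-12 ||
        (cand >= best[j + 1L] - 1e-12 && !is.na(back[j + 1L]) &&
           (nmorph[i] + 1L < nmorph[j + 1L] ||
              (nmorph[i] + 1L == nmorph[j + 1L] && i > back[j + 1L])))
      if (is.infinite(best[j + 1L]) && is.finite(cand)) better <- TRUE
      if (better) {
        best[j + 1L] <- cand
        nmorph[j + 1L] <- nmorph[i] + 1L
        back[j + 1L] <- i
      }
    }
  }
  if (is.infinite(best[n + 1L])) return(NULL)
  morphs <- character(0)
  pos <- n + 1L
  while (pos > 1L) {
    i <- back[pos]
    morphs <- c(sub[pos - 1L, i], morphs)
    pos <- i
  }
  structure(morphs, log2prob = unname(best[n + 1L]))
}

#' Boundary precision, recall and F1 of predicted segmentations
#'
#' Boundaries are internal split positions; scores are micro-averaged over
#' words. Supports evaluating unsupervised segmentations against a gold
#' (linguistic) lexicon.
#'
#' @param predicted,gold named lists word -> character vector of morphs;
#'   both must cover the same words.
#' @return list with `precision`, `recall`, `f1` (all in \[0, 1\]).
#' @export
boundary_prf <- function(predicted, gold) {
  if (!setequal(names(predicted), names(gold)))
    stop("predicted and gold segmentations cover different word lists")
  gold <- gold[names(predicted)]
  bounds <- function(morphs) {
    if (length(morphs) < 2L) integer(0) else cumsum(nchar(morphs))[-length(morphs)]
  }
  tp <- fp <- fn <- 0L
  for (w in names(predicted)) {
    pb <- bounds(predicted[[w]]); gb <- bounds(gold[[w]])
    tp <- tp + length(intersect(pb, gb))
    fp <- fp + length(setdiff(pb, gb))
    fn <- fn + length(setdiff(gb, pb))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 1
  r <- if (tp + fn > 0) tp / (tp + fn) else 1
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f)
}

#' Serialize an MDL model to JSON
#' @param model an `mdl_model`.
#' @param path output file.
#' @export
save_mdl_model <- function(model, path) {
  obj <- list(lexicon = as.list(model$lexicon),
              segmentations = model$segmentations,
              letter_probs = as.list(model$letter_probs),
              params = unclass(model$params),
              final_cost = model$final_cost,
              converged = model$converged,
              n_morph_tokens = model$n_morph_tokens,
              model_name = model$model_name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an MDL model from JSON
#' @param path file written by [save_mdl_model()].
#' @return an `mdl_model`.
#' @export
load_mdl_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(lexicon = unlist(obj$lexicon),
         segmentations = lapply(obj$segmentations, as.character),
         letter_probs = unlist(obj$letter_probs),
         params = do.call(mdl_params, obj$params[c("alpha", "seed",
           "max_epochs", "convergence_tol", "use_type_counts", "n_restarts")]),
         final_cost = obj$final_cost, converged = obj$converged,
         n_morph_tokens = obj$n_morph_tokens, model_name = obj$model_name),
    class = c("mdl_model", "surprisal_model"))
}
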