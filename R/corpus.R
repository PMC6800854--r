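#' Token-count table
#'
#' Constructs the basic corpus container: a word-to-count table together
#' with the total token count and the observed character alphabet.
#'
#' @param counts named non-negative integer vector; names are word strings,
#'   values token frequencies (entries with count >= 1 are kept).
#' @return An object of class `token_counts` with fields `entries`
#'   (named numeric), `total_tokens`, and `alphabet` (character vector).
#' @export
token_counts <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector with non-empty word names")
  counts <- counts[counts >= 1]
  if (length(counts) == 0L) stop("empty corpus: no entries with count >= 1")
  if (anyDuplicated(names(counts)))
    counts <- tapply(counts, names(counts), sum)[unique(names(counts))]
  structure(
    list(entries = stats::setNames(as.numeric(counts), names(counts)),
         total_tokens = sum(counts),
         alphabet = sort(unique(unlist(strsplit(names(counts), ""))))),
    class = "token_counts")
}

#' @export
print.token_counts <- function(x, ...) {
  cat(sprintf("token_counts: %d types, %g tokens, %d characters\n",
              length(x$entries), x$total_tokens, length(x$alphabet)))
  invisible(x)
}

#' Load a word-frequency corpus
#'
#' Reads a UTF-8 plain-text corpus with one `word<TAB>count` pair per line.
#'
#' @param path file path.
#' @param min_count entries with a count below this are dropped
#'   (`total_tokens` is recomputed after filtering).
#' @return A [token_counts()] object.
#' @export
load_corpus <- function(path, min_count = 1L) {
  stopifnot(min_count >= 1)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) == 0L) {
    cnt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    bad <- which(is.na(cnt) | cnt < 1 | cnt != floor(cnt))
  }
  if (length(bad) > 0L)
    stop(sprintf("malformed line %d", bad[1L]))
  words <- vapply(parts, `[`, "", 1L)
  cnt <- as.numeric(vapply(parts, `[`, "", 2L))
  keep <- cnt >= min_count
  if (!any(keep)) stop("empty corpus after filtering")
  token_counts(stats::setNames(cnt[keep], words[keep]))
}

#' Write a corpus to the word<TAB>count format
#' @param corpus a [token_counts()] object.
#' @param path output file.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(sprintf("%s\t%d", names(corpus$entries),
                     as.integer(corpus$entries)), path, useBytes = TRUE)
  invisible(path)
}

#' Letter probabilities of a corpus
#'
#' Maximum-likelihood character probabilities over the corpus word types
#' (each type counted once), extended with an end-of-morph marker whose
#' pseudo-count equals the number of types. Used for the lexicon
#' string-encoding cost of the MDL model and as the base distribution of
#' out-of-vocabulary fallbacks.
#'
#' @param corpus a [token_counts()] object.
#' @return named numeric vector of probabilities summing to 1; the marker
#'   entry is named `"<EOM>"`.
#' @export
letter_probs <- function(corpus) {
  chars <- unlist(strsplit(names(corpus$entries), ""))
  tab <- table(chars)
  n_types <- length(corpus$entries)
  tot <- sum(tab) + n_types
  p <- c(as.numeric(tab) / tot, n_types / tot)
  names(p) <- c(names(tab), "<EOM>")
  p
}

# -log2 probability of a string under the letter model (includes the
# end-of-morph marker factor).
letter_string_bits <- function(str, lp) {
  chars <- strsplit(str, "")[[1L]]
  costs <- lp[chars]
  if (anyNA(costs)) return(Inf)
  -sum(log2(costs)) - log2(lp[["<EOM>"]])
}

#' Read a segmentation lexicon file
#'
#' Format: `word<TAB>morph1 morph2 ...` with space-separated morphs; a
#' `'+'`-joined morph field is accepted on read.
#'
#' @param path file path.
#' @return named list mapping word to character vector of morphs.
#' @export
read_segmentation_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) stop(sprintf("malformed line %d", bad[1L]))
  words <- vapply(parts, `[`, "", 1L)
  morphs <- lapply(parts, function(p) {
    m <- strsplit(gsub("+", " ", p[2L], fixed = TRUE), " ", fixed = TRUE)[[1L]]
    m[nzchar(m)]
  })
  ok <- vapply(seq_along(words), function(i)
    paste(morphs[[i]], collapse = "") == words[i], TRUE)
  if (!all(ok))
    stop(sprintf("morphs do not concatenate to word on line %d", which(!ok)[1L]))
  stats::setNames(morphs, words)
}

#' Write a segmentation lexicon file
#' @param segmentations named list word -> character vector of morphs.
#' @param path output file.
#' @export
write_segmentation_file <- function(segmentations, path) {
  writeLines(sprintf("%s\t%s", names(segmentations),
                     vapply(segmentations, paste, "", collapse = " ")),
             path, useBytes = TRUE)
  invisible(path)
}
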