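# Independent brute-force oracle for the two-part MDL objective: enumerates
# every joint assignment of segmentations to corpus words and returns the
# global cost minimizer under the same tie-break as the trainer (fewer
# morphs in total, then leftmost-longest per word in corpus order). Written
# from the cost definition alone; shares no code with the trained path.

all_segmentations_of <- function(word) {
  n <- nchar(word)
  if (n == 1L) return(list(word))
  masks <- 0:(2^(n - 1L) - 1L)
  lapply(masks, function(mask) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    substring(word, starts, ends)
  })
}

oracle_cost <- function(seg_list, counts, lp, alpha) {
  tokens <- character(0)
  wt <- numeric(0)
  for (i in seq_along(seg_list)) {
    tokens <- c(tokens, seg_list[[i]])
    wt <- c(wt, rep(counts[i], length(seg_list[[i]])))
  }
  cnt <- tapply(wt, tokens, sum)
  n <- sum(cnt)
  corpus_bits <- sum(cnt * (log2(n) - log2(cnt)))
  lex_bits <- 0
  for (m in names(cnt)) {
    chars <- strsplit(m, "")[[1L]]
    lex_bits <- lex_bits - sum(log2(lp[chars])) - log2(lp[["<EOM>"]])
  }
  lex_bits + alpha * corpus_bits
}

# tie-break: fewer morphs total, then per word (in order) fewer morphs,
# then longer leftmost morph
oracle_prefer <- function(a, b) {
  na <- sum(lengths(a)); nb <- sum(lengths(b))
  if (na != nb) return(na < nb)
  for (i in seq_along(a)) {
    sa <- a[[i]]; sb <- b[[i]]
    if (length(sa) != length(sb)) return(length(sa) < length(sb))
    for (j in seq_along(sa)) {
      if (nchar(sa[j]) != nchar(sb[j])) return(nchar(sa[j]) > nchar(sb[j]))
    }
  }
  FALSE
}

brute_force_mdl <- function(words, counts, lp, alpha) {
  cand <- lapply(words, all_segmentations_of)
  idx <- rep(1L, length(words))
  sizes <- vapply(cand, length, 1L)
  best <- NULL; best_cost <- Inf
  repeat {
    seg <- lapply(seq_along(words), function(i) cand[[i]][[idx[i]]])
    cost <- oracle_cost(seg, counts, lp, alpha)
    if (cost < best_cost - 1e-6 ||
        (cost <= best_cost + 1e-6 && !is.null(best) && oracle_prefer(seg, best))) {
      best <- seg; best_cost <- cost
    }
    # advance the mixed-radix counter
    k <- 1L
    while (k <= length(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
    }
    if (k > length(idx)) break
  }
  names(best) <- words
  list(segmentations = best, cost = best_cost)
}

# random toy corpus built from a small shared morph inventory, with the
# joint enumeration capped so the oracle stays tractable
random_toy_corpus <- function(seed, max_joint = 2e5) {
  set.seed(seed)
  repeat {
    alphabet <- sample(letters[1:6], 4)
    n_morphs <- sample(2:4, 1)
    morphs <- unique(vapply(seq_len(n_morphs), function(i)
      paste(sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = ""), ""))
    n_words <- sample(2:4, 1)
    words <- unique(vapply(seq_len(n_words), function(i)
      paste(sample(morphs, sample(1:2, 1), replace = TRUE), collapse = ""), ""))
    words <- words[nchar(words) <= 8]
    if (length(words) < 2) next
    joint <- prod(2^(nchar(words) - 1))
    if (joint > max_joint) next
    counts <- sample(1:5, length(words), replace = TRUE)
    return(token_counts(stats::setNames(counts, words)))
  }
}
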