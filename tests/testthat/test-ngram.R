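toy_segs <- list(ab = c("a", "b"), ac = c("a", "c"))
toy_counts <- c(ab = 2, ac = 1)

test_that("word unigram probabilities are maximum likelihood", {
  wu <- train_word_unigram(token_counts(c(a = 1, b = 1, c = 2)))
  expect_equal(unname(wu$probs["c"]), 0.5)
  expect_equal(unname(wu$probs["a"]), 0.25)
  expect_equal(as.vector(self_information(wu, "c")), 1)

  single <- train_word_unigram(token_counts(c(x = 5)))
  expect_equal(as.vector(self_information(single, "x")), 0)
})

test_that("word unigram OOV policy scores or flags unknown words", {
  wu <- train_word_unigram(token_counts(c(ab = 3, ba = 1)), oov = "letter")
  bits <- self_information(wu, "bb")
  expect_true(is.finite(bits) && bits > 0)
  strict <- train_word_unigram(token_counts(c(ab = 3)), oov = "strict")
  expect_true(is.na(self_information(strict, "bb")))
})

test_that("unsmoothed morph n-gram probabilities match hand counts", {
  bg <- train_morph_ngram(toy_segs, toy_counts, order = 2,
                          smooth = smoothing("ml"))
  # P(a|start) = 1, P(b|a) = 2/3, P(end|b) = 1
  expect_equal(as.vector(self_information(bg, "ab")), -log2(2 / 3))
  ug <- train_morph_ngram(toy_segs, toy_counts, order = 1,
                          smooth = smoothing("ml"))
  # token counts a:3 b:2 c:1 over 6
  expect_equal(as.vector(self_information(ug, "ab")),
               -log2(3 / 6) - log2(2 / 6))

  one <- train_morph_ngram(list(x = "x"), c(x = 4), order = 2,
                           smooth = smoothing("ml"))
  expect_equal(as.vector(self_information(one, "x")), 0)
})

test_that("unknown smoothing descriptors are rejected", {
  expect_error(smoothing("kneser-ney"))
  expect_error(train_morph_ngram(toy_segs, toy_counts, order = 1,
                                 smooth = list(method = "ml")),
               "smoothing")
})

test_that("invalid segmentations are rejected", {
  expect_error(train_morph_ngram(list(ab = c("a", "x")), c(ab = 1)),
               "invalid segmentation")
})

test_that("discounted bigram rows sum to one over the full event space", {
  bg <- train_morph_ngram(toy_segs, toy_counts, order = 2,
                          smooth = smoothing("absolute_discount", 0.5))
  events <- c(names(bg$unigram_counts), "</w>")
  for (h in c("<w>", "a", "b")) {
    mass_obs <- sum(morph_bigram_prob(bg, rep(h, length(events)), events))
    # the residual (1 - mass_obs) is exactly the interpolation mass that
    # flows to unseen strings through the letter-model base distribution
    d <- bg$smoothing$discount
    lambda <- d * bg$context_types[[h]] / bg$context_totals[[h]]
    lambda_uni <- d * length(bg$base_counts) / sum(bg$base_counts)
    base_obs <- sum(ngram_base_prob(bg, events))
    leak <- lambda * lambda_uni * (1 - base_obs)
    expect_equal(mass_obs + leak, 1, tolerance = 1e-9)
  }
})

test_that("all smoothed probabilities are strictly positive for the vocabulary", {
  ug <- train_morph_ngram(toy_segs, toy_counts, order = 1)
  p <- morph_unigram_prob(ug, c("a", "b", "c"))
  expect_true(all(p > 0))
  bg <- train_morph_ngram(toy_segs, toy_counts, order = 2)
  p2 <- morph_bigram_prob(bg, c("a", "b", "c"), c("b", "c", "a"))
  expect_true(all(p2 > 0))
})

test_that("cross-entropy is exactly the mean self-information", {
  ug <- train_morph_ngram(toy_segs, toy_counts, order = 1,
                          smooth = smoothing("ml"))
  bits <- self_information(ug, c("ab", "ac"))
  expect_identical(cross_entropy(ug, c("ab", "ac")), mean(bits))

  wu <- train_word_unigram(token_counts(stats::setNames(rep(1, 8),
    c("aa", "bb", "cc", "dd", "ee", "ff", "gg", "hh"))))
  expect_equal(cross_entropy(wu, c("aa", "ff", "cc")), 3)
  expect_equal(cross_entropy(wu, "aa"), 3)
})

test_that("cross-entropy errors on unscorable words, naming offenders", {
  strict <- train_word_unigram(token_counts(c(ab = 3)), oov = "strict")
  expect_error(cross_entropy(strict, c("ab", "zz")), "zz")
})

test_that("bigram training-set cross-entropy never exceeds the unigram's", {
  for (s in 1:5) {
    set.seed(300 + s)
    morphs <- c("ta", "lo", "ssa", "kin", "pa")
    segs <- list()
    for (i in 1:6) {
      m <- sample(morphs, sample(1:3, 1), replace = TRUE)
      w <- paste(m, collapse = "")
      segs[[w]] <- m
    }
    counts <- stats::setNames(sample(1:5, length(segs), replace = TRUE),
                              names(segs))
    ug <- train_morph_ngram(segs, counts, order = 1, smooth = smoothing("ml"))
    bg <- train_morph_ngram(segs, counts, order = 2, smooth = smoothing("ml"))
    words <- names(segs)
    # the bigram also pays for the end-of-word event; compare on the
    # shared morph terms by subtracting that term is not possible in
    # closed form, so compare the full quantities: conditioning can only
    # sharpen the per-morph distribution on the training set
    uni_bits <- self_information(ug, words)
    big_bits <- self_information(bg, words)
    # per-morph terms: drop the bigram's end term, which the unigram lacks
    end_bits <- vapply(words, function(w) {
      s <- segs[[w]]
      -log2(morph_bigram_prob(bg, s[length(s)], "</w>"))
    }, 0.0)
    expect_lte(mean(big_bits - end_bits), mean(uni_bits) + 1e-9)
  }
})

test_that("word-unigram surprisal strictly decreases with frequency", {
  counts <- stats::setNames(c(1, 3, 9, 27, 81), c("va", "wa", "xa", "ya", "za"))
  wu <- train_word_unigram(token_counts(counts))
  bits <- self_information(wu, names(counts))
  expect_true(all(diff(as.vector(bits)) < 0))
})
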