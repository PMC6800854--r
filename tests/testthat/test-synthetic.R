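# a small corpus reused across tests (sampling is cheap; training is not)
small_world <- function(seed = 1, n_tokens = 60000) {
  g <- morphology_grammar(seed = seed)
  suppressMessages(sample_corpus(g, n_tokens, seed = seed + 1))
}

test_that("grammar and corpus generation are deterministic under a seed", {
  g1 <- morphology_grammar(seed = 4)
  g2 <- morphology_grammar(seed = 4)
  expect_identical(g1, g2)
  sc1 <- suppressMessages(sample_corpus(g1, 30000, seed = 9))
  sc2 <- suppressMessages(sample_corpus(g2, 30000, seed = 9))
  expect_identical(sc1, sc2)
})

test_that("gold segmentations concatenate to their words and span 1-5 morphs", {
  sc <- small_world()
  words <- names(sc$gold)
  expect_identical(vapply(words, function(w)
    paste(sc$gold[[w]], collapse = ""), "", USE.NAMES = FALSE), words)
  k <- lengths(sc$gold)
  expect_gte(min(k), 1L)
  expect_lte(max(k), 5L)
  expect_gt(length(unique(k)), 2L)
})

test_that("attachment probabilities control morph counts at the extremes", {
  g0 <- morphology_grammar(p_attach = c(derivational = 0, inflectional = 0,
                                        possessive = 0, clitic = 0),
                           n_stems = 50, seed = 2)
  sc0 <- suppressMessages(sample_corpus(g0, 1000, seed = 3))
  expect_true(all(lengths(sc0$gold) == 1L))

  g1 <- morphology_grammar(p_attach = c(derivational = 1, inflectional = 1,
                                        possessive = 1, clitic = 1),
                           n_stems = 50, seed = 2)
  sc1 <- suppressMessages(sample_corpus(g1, 1000, seed = 3))
  expect_true(all(lengths(sc1$gold) == 5L))
})

test_that("stem frequencies follow the configured Zipf exponent", {
  sc <- small_world(seed = 7, n_tokens = 200000)
  stem_counts <- tapply(sc$corpus$entries[names(sc$stems)], sc$stems, sum)
  sorted <- sort(stem_counts, decreasing = TRUE)
  top <- sorted[1:100]
  fit <- stats::lm(log(as.numeric(top)) ~ log(seq_along(top)))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1.0), 0.15)
})

test_that("stimulus selection yields 360 stem-distinct targets", {
  sc <- small_world()
  stim <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  expect_equal(nrow(stim), 360L)
  expect_equal(sum(stim$stratum == "highfreq"), 60L)
  expect_false(anyDuplicated(stim$stem) > 0)
  expect_false(anyDuplicated(stim$word) > 0)
  # the high-frequency stratum draws from the top count quartile
  q3 <- stats::quantile(sc$corpus$entries, 0.75)
  expect_true(all(stim$count[stim$stratum == "highfreq"] >= q3))
  stim2 <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  expect_identical(stim, stim2)
})

test_that("pseudowords avoid the vocabulary and match target lengths exactly", {
  sc <- small_world()
  stim <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  pw <- generate_pseudowords(names(sc$corpus$entries), stim$length, seed = 6)
  expect_length(pw, 360L)
  expect_false(any(pw %in% names(sc$corpus$entries)))
  expect_identical(sort(nchar(pw)), sort(stim$length))
  expect_false(anyDuplicated(pw) > 0)
  pw2 <- generate_pseudowords(names(sc$corpus$entries), stim$length, seed = 6)
  expect_identical(pw, pw2)
})

test_that("pseudoword generation errors when rejection is impossible", {
  expect_error(
    generate_pseudowords(c("aa", "aaa"), lengths = 2, order = 1, seed = 1,
                         reject = c("aa"), max_tries = 20),
    "length 2")
})

test_that("the deterministic limit of the simulator is exact", {
  stim <- data.frame(word = c("talo", "kalassa"), length = c(4, 7))
  pred <- list(early = c(talo = 2, kalassa = 2),
               late = c(talo = 3, kalassa = 3))
  cfg <- sim_config("exp1", n_subjects = 2, beta_early = 1, beta_late = 1,
                    sd_subj_ffd = 0, sd_item_ffd = 0, sd_resid_ffd = 0,
                    sd_subj_gmf = 0, sd_item_gmf = 0, sd_resid_gmf = 0,
                    single_fixation_prob = 0, order_slope = 0,
                    error_shape1 = 1e-6, error_shape2 = 1)
  sim <- simulate_exp1(stim, pred, cfg)
  expect_true(all(sim$measures$FFD == cfg$intercept_ffd + 2))
  expect_true(all(sim$measures$GmF == cfg$intercept_gmf + 3))
  expect_true(all(sim$measures$GD == sim$measures$FFD + sim$measures$GmF))
})

test_that("simulated fixations round-trip through the measure computation", {
  sc <- small_world()
  stim <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  set.seed(8)
  pred <- list(early = stats::setNames(rnorm(360, 15, 4), stim$word),
               late = stats::setNames(rnorm(360, 15, 4), stim$word))
  sim <- simulate_exp1(stim, pred, sim_config("exp1", n_subjects = 6, seed = 2))
  got <- compute_measures_exp1(sim$fixations)
  keys <- function(d) order(d$subject, d$trial)
  got <- got[keys(got), ]
  want <- sim$measures[keys(sim$measures), ]
  expect_identical(got$FFD, want$FFD)
  expect_identical(got$GD, want$GD)
  expect_identical(got$GmF, want$GmF)
  expect_identical(got$item, want$item)
  # GmF is missing exactly when the defining run has one fixation
  n_fix <- table(paste(sim$fixations$subject, sim$fixations$trial))
  expect_equal(mean(is.na(got$GmF)),
               mean(n_fix == 1))
})

test_that("reaction times track gaze durations as designed", {
  sc <- small_world()
  stim <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  set.seed(9)
  pred <- list(early = stats::setNames(rnorm(360, 15, 4), stim$word),
               late = stats::setNames(rnorm(360, 15, 4), stim$word))
  sim <- simulate_exp1(stim, pred, sim_config("exp1", n_subjects = 8, seed = 3))
  expect_gte(stats::cor(sim$measures$rt_ms, sim$measures$GD), 0.98)
  # single-fixation fraction within 2 binomial SE of the configured rate
  p <- 0.02; n <- nrow(sim$measures)
  expect_lt(abs(mean(is.na(sim$measures$GmF)) - p), 2 * sqrt(p * (1 - p) / n))
})

test_that("word-row simulation matches the stimulus design and round-trips", {
  sc <- small_world(n_tokens = 100000)
  stim <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = 5)
  set.seed(10)
  pred <- list(early = stats::setNames(rnorm(360, 15, 4), stim$word),
               late = stats::setNames(rnorm(360, 15, 4), stim$word))
  fillers <- setdiff(names(sc$corpus$entries), stim$word)[1:1980]
  pw <- generate_pseudowords(names(sc$corpus$entries), stim$length, seed = 6)
  sim <- simulate_exp2(stim, fillers, pw, pred,
                       sim_config("exp2", n_subjects = 4, seed = 4))

  rows <- sim$rows
  for (l in unique(rows$list_id)) {
    rl <- rows[rows$list_id == l, ]
    expect_equal(nrow(rl), 360 * 7)
    tgt <- rl[rl$type == "target", ]
    expect_true(all(tgt$position %in% c(3, 5)))
    expect_setequal(tgt$item, stim$word)         # each target used once
    pwr <- rl[rl$type == "pseudoword", ]
    expect_equal(nrow(pwr), 180L)                # one pseudoword per row
    expect_equal(length(unique(pwr$row_id)), 180L)
  }
  # per-trial row structure: seven areas, targets at 3 and 5
  f1 <- sim$fixations[sim$fixations$subject == 1 & sim$fixations$trial == 1, ]
  expect_setequal(unique(f1$interest_area), 1:7)
  expect_setequal(unique(f1$row_position[!is.na(f1$row_position)]), c(3, 5))

  got <- compute_measures_exp2(sim$fixations)
  key <- function(d) order(d$subject, d$trial, d$row_position)
  got <- got[key(got), ]
  want <- sim$measures[key(sim$measures), ]
  expect_identical(got$FFD, want$FFD)
  expect_identical(got$GD, want$GD)
  expect_identical(got$GmF, want$GmF)
  expect_identical(got$launch_site, want$launch_site)
  expect_identical(got$item, want$item)

  p <- 0.37; n <- nrow(want)
  expect_lt(abs(mean(is.na(want$GmF)) - p), 2 * sqrt(p * (1 - p) / n))
})

test_that("filler shortage raises an error", {
  stim <- data.frame(word = sprintf("w%03d", 1:360),
                     length = rep(5, 360))
  pred <- list(early = stats::setNames(rep(1, 360), stim$word),
               late = stats::setNames(rep(1, 360), stim$word))
  expect_error(
    simulate_exp2(stim, fillers = c("f1", "f2"), pseudowords = rep("p", 180),
                  pred, sim_config("exp2", n_subjects = 1)),
    "filler shortage")
})
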