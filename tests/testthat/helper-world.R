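# The default synthetic study conditions, cached per session: grammar and
# corpus defaults as documented, one world per seed. Training the MDL
# models dominates test time, so trained models are cached alongside.

.world_cache <- new.env(parent = emptyenv())

default_world <- function(seed = 1) {
  key <- paste0("world", seed)
  if (is.null(.world_cache[[key]])) {
    g <- morphology_grammar(seed = seed)
    sc <- suppressMessages(sample_corpus(g, seed = seed + 100))
    sc$stimuli <- select_stimuli(sc$corpus, sc$gold, sc$stems, seed = seed)
    .world_cache[[key]] <- sc
  }
  .world_cache[[key]]
}

default_mdl <- function(alpha, seed = 1) {
  key <- sprintf("mdl_%g_%d", alpha, seed)
  if (is.null(.world_cache[[key]])) {
    w <- default_world(seed)
    .world_cache[[key]] <- train_mdl_segmenter(
      w$corpus, mdl_params(alpha, seed = seed))
  }
  .world_cache[[key]]
}

default_models <- function() {
  if (is.null(.world_cache$models)) {
    w <- default_world(1)
    models <- list(word_unigram = train_word_unigram(w$corpus))
    for (a in c(0.01, 0.8, 10)) {
      m <- default_mdl(a, 1)
      models[[m$model_name]] <- m
    }
    models$category_hmm <- train_category_hmm(w$corpus,
                                              models$mdl_alpha_0.8,
                                              n_em_iters = 10, seed = 1)
    counts <- w$corpus$entries[names(w$gold)]
    models$morph_unigram <- train_morph_ngram(w$gold, counts, order = 1)
    models$morph_bigram <- train_morph_ngram(w$gold, counts, order = 2)
    .world_cache$models <- models
  }
  .world_cache$models
}

default_surprisals <- function() {
  if (is.null(.world_cache$surprisals)) {
    w <- default_world(1)
    .world_cache$surprisals <- surprisal_table(default_models(),
                                               w$stimuli$word)
  }
  .world_cache$surprisals
}

mean_stimulus_morphs <- function(model, stimuli) {
  mean(vapply(stimuli$word, function(w)
    length(viterbi_segment(model, w)), 1L))
}
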