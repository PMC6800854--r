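VALID_MODELS <- c("word_unigram", "mdl_alpha_0.01", "mdl_alpha_0.8",
                  "mdl_alpha_10", "category_hmm", "morph_unigram",
                  "morph_bigram")

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @return nested configuration list (the same structure is accepted from
#'   a YAML file by [run_pipeline()]).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    corpus = list(n_stems = 420L, n_tokens = 600000L,
                  zipf_stem = 1.0, zipf_suffix = 0.8),
    models = list(include = VALID_MODELS,
                  alphas = c(0.01, 0.8, 10.0),
                  smoothing_discount = 0.5,
                  catmap_iters = 10L,
                  max_epochs = 15L, n_restarts = 3L),
    stimuli = list(n_random = 300L, n_highfreq = 60L),
    exp1 = list(n_subjects = 24L),
    exp2 = list(n_subjects = 26L),
    analyses = list(length_split = TRUE, joint_word_unigram = TRUE,
                    length_threshold = 8L))
}

#' Train the full model set on a corpus
#'
#' Trains the seven models compared throughout the package: the surface
#' word unigram, three MDL segmentation models (alpha 0.01, 0.8, 10.0),
#' the category HMM on top of the alpha = 0.8 base, and the supervised
#' morph unigram and bigram models on the gold segmentations.
#'
#' @param corpus a [token_counts()].
#' @param gold gold segmentations (for the supervised morph models).
#' @param alphas corpus-weight values for the MDL models.
#' @param discount absolute-discounting parameter of the morph n-grams.
#' @param catmap_iters Viterbi-EM iterations of the category HMM.
#' @param seed training seed.
#' @param max_epochs,n_restarts passed to [mdl_params()].
#' @return named list of trained models.
#' @export
train_model_set <- function(corpus, gold, alphas = c(0.01, 0.8, 10.0),
                            discount = 0.5, catmap_iters = 10L, seed = 1L,
                            max_epochs = 15L, n_restarts = 3L) {
  models <- list(word_unigram = train_word_unigram(corpus))
  for (a in alphas) {
    m <- train_mdl_segmenter(corpus, mdl_params(a, seed = seed,
                                                max_epochs = max_epochs,
                                                n_restarts = n_restarts))
    models[[m$model_name]] <- m
  }
  base_name <- sprintf("mdl_alpha_%g", alphas[which.min(abs(alphas - 0.8))])
  models$category_hmm <- train_category_hmm(corpus, models[[base_name]],
                                            n_em_iters = catmap_iters,
                                            seed = seed)
  counts <- corpus$entries[names(gold)]
  sm <- smoothing("absolute_discount", discount)
  models$morph_unigram <- train_morph_ngram(gold, counts, order = 1L,
                                            smooth = sm)
  models$morph_bigram <- train_morph_ngram(gold, counts, order = 2L,
                                           smooth = sm)
  models
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates corpus generation, model training, stimulus scoring,
#' simulation of both experiments, gaze-measure computation with the
#' trimming and exclusion rules, and the full-set, joint-word-unigram and
#' length-split rankings, writing all tables plus a machine-readable run
#' manifest into `out_dir`.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  for (k in names(base)) {
    if (is.null(config[[k]])) config[[k]] <- base[[k]]
    else if (is.list(base[[k]]))
      for (k2 in setdiff(names(base[[k]]), names(config[[k]])))
        config[[k]][[k2]] <- base[[k]][[k2]]
  }
  bad <- setdiff(config$models$include, VALID_MODELS)
  if (length(bad))
    stop("unknown model name(s) ", paste(bad, collapse = ", "),
         "; valid models: ", paste(VALID_MODELS, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(config = config, package_version =
                     as.character(utils::packageVersion("morphgaze")),
                   stages = list(), files = character(0))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2))
    val
  }
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    manifest$files <<- c(manifest$files, name)
  }

  corp <- stage("corpus", {
    g <- morphology_grammar(n_stems = config$corpus$n_stems,
                            zipf_stem = config$corpus$zipf_stem,
                            zipf_suffix = config$corpus$zipf_suffix,
                            seed = seed)
    sample_corpus(g, n_tokens = config$corpus$n_tokens, seed = seed + 1L)
  })
  write_corpus(corp$corpus, file.path(out_dir, "corpus.tsv"))
  write_segmentation_file(corp$gold, file.path(out_dir, "gold_segmentation.tsv"))
  manifest$files <- c(manifest$files, "corpus.tsv", "gold_segmentation.tsv")

  stimuli <- stage("stimuli",
    select_stimuli(corp$corpus, corp$gold, corp$stems,
                   n_random = config$stimuli$n_random,
                   n_highfreq = config$stimuli$n_highfreq, seed = seed + 2L))
  emit(stimuli, "stimuli.tsv")
  pseudo <- stage("pseudowords",
    generate_pseudowords(names(corp$corpus$entries), stimuli$length,
                         seed = seed + 3L))
  writeLines(pseudo, file.path(out_dir, "pseudowords.txt"))
  manifest$files <- c(manifest$files, "pseudowords.txt")

  models <- stage("models",
    train_model_set(corp$corpus, corp$gold,
                    alphas = config$models$alphas,
                    discount = config$models$smoothing_discount,
                    catmap_iters = config$models$catmap_iters,
                    seed = seed + 4L,
                    max_epochs = config$models$max_epochs,
                    n_restarts = config$models$n_restarts))
  models <- models[intersect(names(models), config$models$include)]

  surp <- stage("surprisal", surprisal_table(models, stimuli$word))
  write_surprisal_tsv(surp, file.path(out_dir, "surprisal.tsv"))
  manifest$files <- c(manifest$files, "surprisal.tsv")
  xent <- stage("cross_entropy", data.frame(
    model = names(models),
    range_min = vapply(names(models), function(m) min(surp[[m]]), 0),
    range_max = vapply(names(models), function(m) max(surp[[m]]), 0),
    mean = vapply(names(models), function(m) mean(surp[[m]]), 0),
    sd = vapply(names(models), function(m) stats::sd(surp[[m]]), 0),
    cross_entropy = vapply(names(models), function(m)
      mean(surp[[m]]), 0)))
  emit(xent, "cross_entropy.tsv")

  early <- stats::setNames(surp$morph_unigram, surp$word)
  late <- stats::setNames(surp$morph_bigram, surp$word)
  predictors <- list(early = early, late = late)

  sim1 <- stage("simulate_exp1",
    simulate_exp1(stimuli, predictors,
                  sim_config("exp1", n_subjects = config$exp1$n_subjects,
                             seed = seed + 5L)))
  meas1 <- stage("measures_exp1", {
    m <- compute_measures_exp1(sim1$fixations)
    m <- exclude_error_and_subjects(m)
    trim_outliers(m, "rt_ms")
  })
  emit(meas1, "exp1_measures.tsv")

  fillers <- stage("fillers", {
    pool <- setdiff(names(corp$corpus$entries), stimuli$word)
    if (length(pool) < 1980L)
      stop("corpus vocabulary too small to supply 1980 distinct fillers")
    set.seed(seed + 6L)
    pool[sample.int(length(pool), 1980L)]
  })
  sim2 <- stage("simulate_exp2",
    simulate_exp2(stimuli, fillers, pseudo, predictors,
                  sim_config("exp2", n_subjects = config$exp2$n_subjects,
                             seed = seed + 7L)))
  meas2 <- stage("measures_exp2", {
    m <- compute_measures_exp2(sim2$fixations)
    trim_outliers(m, "GD")
  })
  emit(meas2, "exp2_measures.tsv")

  rank_and_emit <- function(meas, design, tag) {
    full <- stage(paste0("ranking_", tag),
                  run_model_ranking(meas, surp, design))
    emit(full, sprintf("ranking_%s.tsv", tag))
    if (isTRUE(config$analyses$joint_word_unigram)) {
      j <- stage(paste0("ranking_", tag, "_joint"),
                 joint_with_word_unigram(meas, surp, design))
      emit(j, sprintf("ranking_%s_joint.tsv", tag))
    }
    if (isTRUE(config$analyses$length_split)) {
      sets <- split_by_length(stimuli$word, config$analyses$length_threshold)
      for (grp in c("short", "long")) {
        sub <- meas[meas$item %in% sets[[grp]], , drop = FALSE]
        r <- stage(paste0("ranking_", tag, "_", grp),
                   run_model_ranking(sub, surp, design))
        emit(r, sprintf("ranking_%s_%s.tsv", tag, grp))
      }
    }
    emit(correlations(meas, surp), sprintf("correlations_%s.tsv", tag))
  }
  rank_and_emit(meas1, "exp1", "exp1")
  rank_and_emit(meas2, "exp2", "exp2")

  manifest$seed <- seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
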