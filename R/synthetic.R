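#' Morphology grammar for the synthetic agglutinative lexicon
#'
#' Defines the generator standing in for a morphologically rich natural
#' corpus: a Zipf-distributed stem inventory and four ordered suffix slots
#' (derivational, inflectional, possessive, clitic), each with its own
#' attachment probability and Zipf-distributed within-slot frequencies.
#' Every generated word is a stem plus zero to four suffixes, i.e. one to
#' five morphs.
#'
#' Stems are random consonant-vowel syllable strings; suffix inventories
#' are fixed short strings so that suffixes recur across many stems, which
#' is what makes unsupervised boundary discovery possible.
#'
#' Each stem licenses a bounded paradigm: only `max_forms_per_stem`
#' distinct suffix combinations are attested for a given stem, emulating
#' the usage-based sparsity of real paradigms and giving the corpus a
#' realistic token/type ratio (without the cap the combinatorial space
#' floods the vocabulary with singleton forms).
#'
#' @param n_stems number of stems.
#' @param zipf_stem Zipf exponent of stem frequencies.
#' @param zipf_suffix Zipf exponent of within-slot suffix frequencies.
#' @param p_attach named attachment probabilities per slot.
#' @param max_forms_per_stem number of attested suffix combinations per
#'   stem.
#' @param seed integer seed for stem generation.
#' @return object of class `morphology_grammar`.
#' @export
morphology_grammar <- function(n_stems = 420L, zipf_stem = 1.0,
                               zipf_suffix = 0.8,
                               p_attach = c(derivational = 0.22,
                                            inflectional = 0.55,
                                            possessive = 0.12,
                                            clitic = 0.15),
                               max_forms_per_stem = 8L,
                               seed = 1L) {
  stopifnot(all(p_attach >= 0 & p_attach <= 1), n_stems >= 1)
  slots <- list(
    derivational = c("ja", "sto", "uus", "nen", "nti", "mo"),
    inflectional = c("ssa", "sta", "lla", "lta", "lle", "ksi", "na", "in"),
    possessive   = c("ni", "si", "nsa", "mme"),
    clitic       = c("kin", "han", "pa", "ko"))
  stopifnot(setequal(names(p_attach), names(slots)))
  consonants <- strsplit("dhjklmnprstv", "")[[1L]]
  vowels <- strsplit("aeiou", "")[[1L]]
  withr_seed <- function(expr) { set.seed(seed); expr }
  stems <- withr_seed({
    out <- character(0)
    while (length(out) < n_stems) {
      need <- n_stems - length(out)
      n_syl <- sample(2:3, need, replace = TRUE)
      cand <- vapply(n_syl, function(k)
        paste0(sample(consonants, k, replace = TRUE),
               sample(vowels, k, replace = TRUE), collapse = ""), "")
      out <- unique(c(out, cand))
    }
    out[seq_len(n_stems)]
  })
  zipf <- function(n, s) { p <- (1 / seq_len(n))^s; p / sum(p) }
  structure(
    list(stems = stems, stem_probs = zipf(n_stems, zipf_stem),
         slots = slots,
         slot_probs = lapply(slots, function(m) zipf(length(m), zipf_suffix)),
         p_attach = p_attach[names(slots)],
         max_forms_per_stem = as.integer(max_forms_per_stem),
         alphabet = sort(unique(unlist(strsplit(c(stems, unlist(slots)), "")))),
         zipf_stem = zipf_stem, zipf_suffix = zipf_suffix,
         seed = as.integer(seed)),
    class = "morphology_grammar")
}

#' Sample a corpus with gold segmentations from a grammar
#'
#' First materialises each stem's attested paradigm: suffix combinations
#' are drawn by independently attaching each slot with its attachment
#' probability (morph within slot Zipf-weighted) until
#' `max_forms_per_stem` distinct combinations are collected. Tokens are
#' then drawn with probability proportional to the stem's Zipf weight
#' times the combination's generative probability within the paradigm.
#' Returns surface token counts together with the gold morph segmentation
#' per word type. Distinct morph compositions that collide on the same
#' surface string are permitted (as in real orthography); the most
#' frequent composition becomes the gold analysis and collisions are
#' reported via `message()`.
#'
#' @param grammar a [morphology_grammar()].
#' @param n_tokens number of tokens to draw (>= 10 per stem recommended).
#' @param seed sampling seed.
#' @return list with `corpus` ([token_counts()]), `gold` (named list word
#'   -> morphs), and `stems` (named character: word -> stem).
#' @export
sample_corpus <- function(grammar, n_tokens = 600000L, seed = 1L) {
  stopifnot(inherits(grammar, "morphology_grammar"))
  n_stems <- length(grammar$stems)
  stopifnot(n_tokens >= 10L * n_stems)
  set.seed(seed)
  slots <- grammar$slots
  # candidate suffix combinations per stem, with generative probabilities
  n_draw <- 6L * grammar$max_forms_per_stem
  draw_combos <- function() {
    parts <- list()
    prob <- rep(1, n_draw)
    for (slot in names(slots)) {
      attach <- stats::runif(n_draw) < grammar$p_attach[[slot]]
      mi <- sample.int(length(slots[[slot]]), n_draw, replace = TRUE,
                       prob = grammar$slot_probs[[slot]])
      m <- slots[[slot]][mi]
      m[!attach] <- ""
      prob <- prob * ifelse(attach,
                            grammar$p_attach[[slot]] * grammar$slot_probs[[slot]][mi],
                            1 - grammar$p_attach[[slot]])
      parts[[slot]] <- m
    }
    key <- do.call(paste, c(unname(parts), list(sep = "\r")))
    keep <- !duplicated(key)
    keep[which(keep)[-seq_len(min(sum(keep), grammar$max_forms_per_stem))]] <- FALSE
    list(key = key[keep], prob = prob[keep] / sum(prob[keep]))
  }
  paradigms <- lapply(seq_len(n_stems), function(i) draw_combos())
  form_stem <- rep(seq_len(n_stems),
                   vapply(paradigms, function(p) length(p$key), 1L))
  form_key <- unlist(lapply(paradigms, `[[`, "key"))
  form_prob <- unlist(lapply(seq_len(n_stems), function(i)
    grammar$stem_probs[i] * paradigms[[i]]$prob))
  drawn <- sample.int(length(form_key), n_tokens, replace = TRUE,
                      prob = form_prob)
  comp_key <- paste(grammar$stems[form_stem[drawn]], form_key[drawn],
                    sep = "\r")
  surface <- gsub("\r", "", comp_key, fixed = TRUE)
  comp_count <- table(comp_key)
  comp_surface <- surface[match(names(comp_count), comp_key)]
  # gold analysis per surface string: most frequent composition
  ord <- order(comp_surface, -as.numeric(comp_count))
  comp_count <- comp_count[ord]; comp_surface <- comp_surface[ord]
  first <- !duplicated(comp_surface)
  n_collisions <- sum(!first)
  if (n_collisions > 0)
    message(sprintf("%d surface collisions between distinct morph compositions",
                    n_collisions))
  gold_keys <- names(comp_count)[first]
  gold <- lapply(strsplit(gold_keys, "\r", fixed = TRUE),
                 function(p) p[nzchar(p)])
  names(gold) <- comp_surface[first]
  stems_map <- stats::setNames(
    vapply(strsplit(gold_keys, "\r", fixed = TRUE), `[`, "", 1L),
    comp_surface[first])
  counts <- tapply(as.numeric(comp_count), comp_surface, sum)
  list(corpus = token_counts(counts), gold = gold, stems = stems_map)
}

#' Select the stimulus word set
#'
#' 300 words drawn uniformly from the corpus vocabulary, complemented with
#' 60 draws restricted to the top frequency quartile (the random sample
#' over-represents low-frequency words). No two targets share a stem.
#'
#' @param corpus [token_counts()] with vocabulary >= 2000 types.
#' @param gold gold segmentations from [sample_corpus()].
#' @param stems named word -> stem map from [sample_corpus()].
#' @param n_random,n_highfreq stratum sizes.
#' @param seed sampling seed.
#' @return data.frame: `word`, `count`, `length`, `n_morphs`, `stem`,
#'   `stratum` (`"random"` or `"highfreq"`).
#' @export
select_stimuli <- function(corpus, gold, stems, n_random = 300L,
                           n_highfreq = 60L, seed = 1L) {
  vocab <- names(corpus$entries)
  if (length(vocab) < 2000L)
    stop("corpus vocabulary below 2000 types; enlarge the corpus")
  if (length(unique(stems)) < n_random + n_highfreq)
    stop("insufficient unique stems for a shared-stem-free stimulus set")
  set.seed(seed)
  pick_distinct <- function(pool, n, used_stems) {
    pool <- pool[sample.int(length(pool))]
    out <- character(0)
    for (w in pool) {
      if (stems[[w]] %in% used_stems) next
      out <- c(out, w)
      used_stems <- c(used_stems, stems[[w]])
      if (length(out) == n) break
    }
    if (length(out) < n) stop("insufficient unique stems in sampling pool")
    list(words = out, used = used_stems)
  }
  r <- pick_distinct(vocab, n_random, character(0))
  hi_pool <- vocab[corpus$entries >= stats::quantile(corpus$entries, 0.75)]
  h <- pick_distinct(hi_pool, n_highfreq, r$used)
  words <- c(r$words, h$words)
  data.frame(word = words,
             count = unname(corpus$entries[words]),
             length = nchar(words),
             n_morphs = vapply(gold[words], length, 1L),
             stem = unname(stems[words]),
             stratum = rep(c("random", "highfreq"),
                           c(n_random, n_highfreq)),
             stringsAsFactors = FALSE)
}

#' Generate length-matched pseudowords from a letter n-gram model
#'
#' Trains a letter n-gram (default order 3, additive 0.1 smoothing) on the
#' real word types and samples letter strings of prescribed lengths.
#' Strings that occur in the corpus vocabulary (or were already generated)
#' are rejected, so the pseudoword length multiset exactly matches the
#' target length multiset while no pseudoword is a real word.
#'
#' @param real_words word types the letter model is trained on.
#' @param lengths integer vector: required pseudoword lengths (one
#'   pseudoword is generated per entry).
#' @param order n-gram order.
#' @param seed sampling seed.
#' @param reject additional strings to avoid (defaults to `real_words`).
#' @param max_tries rejection budget per pseudoword.
#' @return character vector of pseudowords, aligned with `lengths`.
#' @export
generate_pseudowords <- function(real_words, lengths, order = 3L, seed = 1L,
                                 reject = real_words, max_tries = 2000L) {
  stopifnot(length(real_words) > 0, order >= 1)
  set.seed(seed)
  pad <- strrep("^", order - 1L)
  padded <- paste0(pad, real_words, "$")
  grams <- unlist(lapply(padded, function(w) {
    n <- nchar(w)
    if (n < order) return(character(0))
    substring(w, 1:(n - order + 1L), order:n)
  }))
  tab <- table(grams)
  contexts <- substr(names(tab), 1L, order - 1L)
  nextch <- substr(names(tab), order, order)
  alphabet <- sort(unique(unlist(strsplit(real_words, ""))))
  cond <- split(data.frame(ch = nextch, n = as.numeric(tab)), contexts)
  sample_char <- function(ctx) {
    e <- cond[[ctx]]
    counts <- stats::setNames(rep(0.1, length(alphabet)), alphabet)
    if (!is.null(e)) {
      e <- e[e$ch != "$", ]
      counts[e$ch] <- counts[e$ch] + e$n
    }
    sample(alphabet, 1L, prob = counts)
  }
  seen <- c(reject, character(0))
  out <- character(length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ctx <- pad
      chars <- character(L)
      for (p in seq_len(L)) {
        chars[p] <- sample_char(ctx)
        ctx <- substring(paste0(pad, paste(chars[1:p], collapse = "")),
                         p + 1L, p + order - 1L)
      }
      w <- paste(chars, collapse = "")
      if (!(w %in% seen)) {
        out[i] <- w
        seen <- c(seen, w)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("pseudoword rejection budget exhausted for length %d", L))
  }
  out
}

#' Simulation configuration
#'
#' Defaults reflect the study design being emulated: descriptive means of
#' the gaze measures, single-fixation probabilities of 0.02 (single-word
#' design, 98% multi-fixation trials) and 0.37 (word-row design, 63%), and
#' a reaction time tied to gaze duration so that their correlation exceeds
#' 0.98. Effect sizes are in ms per bit of surprisal.
#'
#' @param design `"exp1"` (single-word lexical decision) or `"exp2"`
#'   (seven-word rows with targets at positions 3 and 5).
#' @param n_subjects number of participants.
#' @param beta_early effect of the early predictor on FFD (ms/bit).
#' @param beta_late effect of the late predictor on GmF (ms/bit).
#' @param ... overrides of the remaining defaults (see the returned list).
#' @param seed simulation seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(design = c("exp1", "exp2"),
                       n_subjects = NULL, beta_early = 8, beta_late = 25,
                       seed = 1L, ...) {
  design <- match.arg(design)
  cfg <- list(
    design = design,
    n_subjects = n_subjects %||% if (design == "exp1") 24L else 26L,
    beta_early = beta_early, beta_late = beta_late,
    intercept_ffd = if (design == "exp1") 244 else 306,
    intercept_gmf = if (design == "exp1") 537 else 484,
    sd_subj_ffd = 25, sd_item_ffd = 15, sd_resid_ffd = 60,
    sd_subj_gmf = 80, sd_item_gmf = 40, sd_resid_gmf = 200,
    single_fixation_prob = if (design == "exp1") 0.02 else 0.37,
    order_slope = -0.05,
    launch_slope = 6, launch_shape = 2, launch_scale = 1.5,
    pos_slope_sd = 10,
    rt_offset = 150, rt_sd = 40,
    error_shape1 = 2, error_shape2 = 38,
    n_lists = 4L,
    seed = as.integer(seed))
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  stopifnot(cfg$single_fixation_prob >= 0, cfg$single_fixation_prob <= 1,
            cfg$sd_resid_ffd >= 0, cfg$sd_resid_gmf >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate the single-word lexical decision experiment
#'
#' Generates per subject-by-item trials: FFD carries the early predictor's
#' effect, GmF the late predictor's effect (set missing with the
#' single-fixation probability), GD = FFD + GmF (or FFD alone on
#' single-fixation trials), and RT tracks GD closely. Random subject and
#' item intercepts, a presentation-order slope, per-subject error rates
#' drawn from a Beta distribution, and Gaussian residuals complete the
#' generative model, which is linear on the bit scale by design so that it
#' matches the analysis model. Durations are rounded to whole
#' milliseconds, and the emitted fixation lists reconstruct the intended
#' measures exactly (two fixations per multi-fixation trial).
#'
#' @param stimuli stimulus data.frame from [select_stimuli()].
#' @param predictors list with named numeric vectors `early` and `late`
#'   (bits per word, covering all stimulus words).
#' @param config a [sim_config()] with `design = "exp1"`.
#' @return list with `fixations` (fixation report) and `measures` (the
#'   intended measure table).
#' @export
simulate_exp1 <- function(stimuli, predictors, config = sim_config("exp1")) {
  stopifnot(config$design == "exp1")
  words <- stimuli$word
  xe <- predictors$early[words]; xl <- predictors$late[words]
  if (anyNA(xe) || anyNA(xl)) stop("predictors must cover all stimulus words")
  set.seed(config$seed)
  S <- config$n_subjects; n <- length(words)
  u_f <- stats::rnorm(S, 0, config$sd_subj_ffd)
  u_g <- stats::rnorm(S, 0, config$sd_subj_gmf)
  v_f <- stats::rnorm(n, 0, config$sd_item_ffd)
  v_g <- stats::rnorm(n, 0, config$sd_item_gmf)
  err_rate <- stats::rbeta(S, config$error_shape1, config$error_shape2)
  orders <- vapply(seq_len(S), function(s) sample.int(n), integer(n))
  subj <- rep(seq_len(S), each = n)
  item_i <- rep(seq_len(n), times = S)
  ord <- as.vector(orders)
  oc <- ord - (n + 1) / 2
  ffd <- round(config$intercept_ffd + config$beta_early * xe[item_i] +
                 u_f[subj] + v_f[item_i] + config$order_slope * oc +
                 stats::rnorm(S * n, 0, config$sd_resid_ffd))
  ffd <- pmax(ffd, 30)
  single <- stats::runif(S * n) < config$single_fixation_prob
  gmf <- round(config$intercept_gmf + config$beta_late * xl[item_i] +
                 u_g[subj] + v_g[item_i] + config$order_slope * oc +
                 stats::rnorm(S * n, 0, config$sd_resid_gmf))
  gmf <- pmax(gmf, 20)
  gmf[single] <- NA_real_
  gd <- ffd + ifelse(is.na(gmf), 0, gmf)
  rt <- round(gd + config$rt_offset + stats::rnorm(S * n, 0, config$rt_sd))
  correct <- stats::runif(S * n) >= err_rate[subj]
  measures <- measure_row(subj, words[item_i], trial = ord,
                          FFD = ffd, GD = gd, GmF = gmf,
                          presentation_order = ord,
                          response_correct = correct, rt_ms = rt)
  two <- !is.na(gmf)
  fix1 <- data.frame(subject = subj, trial = ord, item = words[item_i],
                     fixation_index = 1L, interest_area = 1L,
                     onset_ms = 0, duration_ms = ffd,
                     x_offset_letters = 0,
                     area_len = nchar(words[item_i]),
                     response_correct = correct, rt_ms = rt,
                     list_id = NA_integer_, row_position = NA_integer_,
                     presentation_order = ord)
  fix2 <- fix1[two, ]
  fix2$fixation_index <- 2L
  fix2$onset_ms <- ffd[two]
  fix2$duration_ms <- gmf[two]
  fixations <- rbind(fix1, fix2)
  fixations <- fixations[order(fixations$subject, fixations$trial,
                               fixations$onset_ms), ]
  rownames(fixations) <- NULL
  list(fixations = fixations, measures = measures)
}

# deterministic assignment of targets and fillers to rows for each list
build_exp2_lists <- function(stimuli, fillers, pseudowords, n_lists, seed) {
  n_rows <- length(stimuli$word) / 2L
  fillers <- fillers[!is.na(fillers)]
  if (length(fillers) < 5L * n_rows + 6L * n_rows)
    stop("filler shortage: need at least ", 11L * n_rows, " filler words")
  set.seed(seed)
  pw <- pseudowords[sample.int(length(pseudowords), n_rows)]
  lapply(seq_len(n_lists), function(l) {
    tw <- stimuli$word[sample.int(length(stimuli$word))]
    fw <- fillers[sample.int(length(fillers), 11L * n_rows)]
    pw_pos <- sample(rep(1:7, length.out = n_rows))
    rows <- lapply(seq_len(2L * n_rows), function(r) {
      if (r <= n_rows) {
        items <- character(7L)
        items[c(3L, 5L)] <- tw[c(2L * r - 1L, 2L * r)]
        items[-c(3L, 5L)] <- fw[(5L * (r - 1L) + 1L):(5L * r)]
        type <- rep("filler", 7L)
        type[c(3L, 5L)] <- "target"
      } else {
        k <- r - n_rows
        items <- fw[(5L * n_rows + 6L * (k - 1L) + 1L):(5L * n_rows + 6L * k)]
        items <- append(items, pw[k], after = pw_pos[k] - 1L)
        type <- rep("filler", 7L)
        type[pw_pos[k]] <- "pseudoword"
      }
      data.frame(list_id = l, row_id = r, position = 1:7, item = items,
                 type = type, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate the word-row recognition experiment
#'
#' Builds, per pseudorandomised list, 180 seven-word target rows (targets
#' at interest areas 3 and 5) and 180 rows containing one pseudoword, then
#' generates first-pass measures for the targets as in [simulate_exp1()]
#' with two additions: a per-subject random slope for row position and a
#' launch-site effect on FFD, with launch sites drawn from a Gamma
#' distribution (quarter-letter resolution). Fixation sequences walk the
#' row left to right so that [compute_measures_exp2()] reconstructs the
#' intended measures and launch sites exactly. Only target rows are
#' emitted as fixations; pseudoword rows appear in the `rows` design
#' table.
#'
#' @param stimuli stimulus data.frame (360 targets).
#' @param fillers character vector of filler words (>= 1980).
#' @param pseudowords character vector (>= 180) to place in pseudoword rows.
#' @param predictors list with named vectors `early` and `late` (bits).
#' @param config a [sim_config()] with `design = "exp2"`.
#' @return list with `fixations`, `measures`, and `rows` (the list
#'   designs).
#' @export
simulate_exp2 <- function(stimuli, fillers, pseudowords, predictors,
                          config = sim_config("exp2")) {
  stopifnot(config$design == "exp2")
  words <- stimuli$word
  xe <- predictors$early[words]; xl <- predictors$late[words]
  if (anyNA(xe) || anyNA(xl)) stop("predictors must cover all stimulus words")
  lists <- build_exp2_lists(stimuli, fillers, pseudowords, config$n_lists,
                            config$seed)
  set.seed(config$seed + 1L)
  S <- config$n_subjects
  n_rows_total <- max(lists[[1L]]$row_id)
  n_target_rows <- n_rows_total / 2L
  u_f <- stats::rnorm(S, 0, config$sd_subj_ffd)
  u_g <- stats::rnorm(S, 0, config$sd_subj_gmf)
  v_f <- stats::setNames(stats::rnorm(length(words), 0, config$sd_item_ffd), words)
  v_g <- stats::setNames(stats::rnorm(length(words), 0, config$sd_item_gmf), words)
  pos_slope <- stats::rnorm(S, 0, config$pos_slope_sd)
  list_of_subj <- rep(seq_along(lists), length.out = S)
  fix_list <- list()
  meas_list <- list()
  for (s in seq_len(S)) {
    design <- lists[[list_of_subj[s]]]
    row_order <- sample.int(n_rows_total)  # presentation order of rows
    for (r in seq_len(n_target_rows)) {
      row <- design[design$row_id == r, ]
      ord <- row_order[r]
      oc <- ord - (n_rows_total + 1) / 2
      lens <- nchar(row$item)
      durs <- list(); areas <- integer(0); idx <- integer(0)
      xoff <- numeric(0); rowpos <- integer(0)
      for (a in 1:7) {
        if (a %in% c(3L, 5L)) {
          w <- row$item[a]
          xpos <- if (a == 5L) 0.5 else -0.5
          launch <- round(stats::rgamma(1L, config$launch_shape,
                                        scale = config$launch_scale) * 4) / 4
          launch <- min(max(launch, 1), lens[a - 1L] + 1)
          ffd <- max(round(config$intercept_ffd + config$beta_early * xe[w] +
                             u_f[s] + v_f[w] + config$order_slope * oc +
                             config$launch_slope * launch +
                             pos_slope[s] * xpos +
                             stats::rnorm(1L, 0, config$sd_resid_ffd)), 30)
          single <- stats::runif(1L) < config$single_fixation_prob
          gmf <- if (single) NA_real_ else
            max(round(config$intercept_gmf + config$beta_late * xl[w] +
                        u_g[s] + v_g[w] + config$order_slope * oc +
                        pos_slope[s] * xpos +
                        stats::rnorm(1L, 0, config$sd_resid_gmf)), 20)
          gd <- ffd + if (is.na(gmf)) 0 else gmf
          # previous-area fixation placed so the computed launch site is exact
          xoff[length(xoff)] <- lens[a - 1L] - launch + 1
          durs <- c(durs, list(ffd), if (!single) list(gmf))
          areas <- c(areas, a, if (!single) a)
          xoff <- c(xoff, 0, if (!single) 0)
          rowpos <- c(rowpos, a, if (!single) a)
          meas_list[[length(meas_list) + 1L]] <- measure_row(
            s, w, trial = r, FFD = ffd, GD = gd, GmF = gmf,
            presentation_order = ord, launch_site = launch,
            row_position = a, list_id = list_of_subj[s])
        } else {
          durs <- c(durs, list(200))
          areas <- c(areas, a)
          xoff <- c(xoff, 0)
          rowpos <- c(rowpos, NA_integer_)
        }
      }
      d <- unlist(durs)
      fix_list[[length(fix_list) + 1L]] <- data.frame(
        subject = s, trial = r, item = row$item[areas],
        fixation_index = seq_along(d), interest_area = areas,
        onset_ms = cumsum(c(0, d[-length(d)])), duration_ms = d,
        x_offset_letters = xoff, area_len = lens[areas],
        response_correct = NA, rt_ms = NA_real_,
        list_id = list_of_subj[s], row_position = rowpos,
        presentation_order = ord, stringsAsFactors = FALSE)
    }
  }
  measures <- do.call(rbind, meas_list)
  rownames(measures) <- NULL
  fixations <- do.call(rbind, fix_list)
  rownames(fixations) <- NULL
  list(fixations = fixations, measures = measures,
       rows = do.call(rbind, lists))
}
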