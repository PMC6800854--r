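#' Specification of a mixed-effects regression
#'
#' @param dependent measure name (`"FFD"`, `"GD"` or `"GmF"`).
#' @param fixed_effects character vector of covariate column names.
#' @param random_intercepts character vector of grouping-factor columns.
#' @param random_slopes optional list of `c(factor, covariate)` pairs,
#'   fitted as independent (uncorrelated) per-group slopes.
#' @param predictor_of_interest optional name of the surprisal column whose
#'   contribution is being evaluated.
#' @return list of class `regression_spec`.
#' @export
regression_spec <- function(dependent, fixed_effects = character(0),
                            random_intercepts, random_slopes = NULL,
                            predictor_of_interest = NULL) {
  structure(list(dependent = dependent, fixed_effects = fixed_effects,
                 random_intercepts = random_intercepts,
                 random_slopes = random_slopes,
                 predictor_of_interest = predictor_of_interest),
            class = "regression_spec")
}

spec_formula <- function(spec) {
  fe <- c(spec$fixed_effects, spec$predictor_of_interest)
  rhs <- c(if (length(fe)) fe else "1",
           sprintf("(1 | %s)", spec$random_intercepts),
           vapply(spec$random_slopes, function(rs)
             sprintf("(0 + %s | %s)", rs[2L], rs[1L]), ""))
  stats::as.formula(paste(spec$dependent, "~", paste(rhs, collapse = " + ")))
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Fits the spec's fixed effects, random intercepts and random slopes with
#' `lme4::lmer` under ML (not REML), since deviance comparisons across
#' different fixed-effect structures require ML fits. Continuous
#' fixed-effect covariates are standardised (mean 0, SD 1) before fitting;
#' this stabilises the optimizer and leaves deviance comparisons
#' unchanged. Rows with missing values in any used column are dropped.
#'
#' @param spec a [regression_spec()].
#' @param data data.frame containing all referenced columns.
#' @return object of class `fit_result`: `log_likelihood`, `deviance`
#'   (-2 log L at the ML fit), `aic` (= deviance + 2 * n_params),
#'   `n_params`, `coefficients` (estimate, SE), `converged`, `singular`,
#'   `n_obs`, and the underlying `fit`.
#' @export
fit_lmm <- function(spec, data) {
  used <- unique(c(spec$dependent, spec$fixed_effects,
                   spec$predictor_of_interest, spec$random_intercepts,
                   unlist(spec$random_slopes)))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  for (g in spec$random_intercepts) {
    d[[g]] <- factor(d[[g]])
    if (nlevels(d[[g]]) < 2L) stop("grouping factor ", g, " has < 2 levels")
  }
  scale_cols <- setdiff(c(spec$fixed_effects, spec$predictor_of_interest,
                          vapply(spec$random_slopes, `[`, "", 2L)),
                        spec$random_intercepts)
  for (v in scale_cols) {
    if (is.numeric(d[[v]]) && stats::sd(d[[v]]) > 0)
      d[[v]] <- as.numeric(scale(d[[v]]))
  }
  fit <- lme4::lmer(spec_formula(spec), data = d, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                      check.conv.singular = "ignore"))
  ll <- stats::logLik(fit)
  npar <- attr(ll, "df")
  conv_msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit)
  if (singular)
    message("variance estimate on the boundary (singular fit)")
  co <- summary(fit)$coefficients
  structure(
    list(log_likelihood = as.numeric(ll), deviance = -2 * as.numeric(ll),
         aic = -2 * as.numeric(ll) + 2 * npar, n_params = npar,
         coefficients = data.frame(term = rownames(co),
                                   estimate = co[, "Estimate"],
                                   se = co[, "Std. Error"],
                                   row.names = NULL),
         converged = is.null(conv_msgs), singular = singular,
         n_obs = nrow(d), spec = spec, fit = fit),
    class = "fit_result")
}

#' Compare an augmented model to its nested baseline
#'
#' The improvement is the decrease in ML deviance; its significance is a
#' likelihood-ratio chi-square test with `df` degrees of freedom (one per
#' added fixed-effect predictor).
#'
#' @param baseline,augmented `fit_result` objects fitted to the same rows.
#' @param df degrees of freedom of the likelihood-ratio test.
#' @param model_name label for the comparison row.
#' @return one-row data.frame: `model`, `aic`, `delta_deviance`, `p_value`.
#' @export
compare_to_baseline <- function(baseline, augmented, df = 1L,
                                model_name = NULL) {
  if (baseline$n_obs != augmented$n_obs)
    stop("baseline and augmented fits use different row counts; ",
         "apply a shared missing-data mask before fitting")
  delta <- baseline$deviance - augmented$deviance
  if (delta < -1e-6)
    stop("non-nested or optimizer failure: augmented deviance exceeds baseline")
  delta <- max(delta, 0)
  if (is.null(model_name))
    model_name <- augmented$spec$predictor_of_interest %||% "augmented"
  data.frame(model = model_name, aic = augmented$aic,
             delta_deviance = delta,
             p_value = stats::pchisq(delta, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

baseline_spec <- function(dependent, design, joint_word_unigram = FALSE) {
  if (design == "exp1") {
    regression_spec(dependent,
                    fixed_effects = c("presentation_order",
                                      if (joint_word_unigram) "word_unigram"),
                    random_intercepts = c("subject", "item"))
  } else {
    regression_spec(dependent,
                    fixed_effects = c("presentation_order", "launch_site",
                                      if (joint_word_unigram) "word_unigram"),
                    random_intercepts = c("subject", "item", "list_id"),
                    random_slopes = list(c("subject", "position")))
  }
}

prepare_ranking_data <- function(measures, surprisals, design) {
  d <- measures[!measures$excluded, , drop = FALSE]
  miss <- setdiff(unique(d$item), surprisals$word)
  if (length(miss))
    stop("missing surprisal for retained items: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  model_cols <- setdiff(names(surprisals), "word")
  nas <- vapply(model_cols, function(m) {
    v <- surprisals[[m]][match(unique(d$item), surprisals$word)]
    any(is.na(v))
  }, TRUE)
  if (any(nas))
    stop("unscorable retained items under model(s): ",
         paste(model_cols[nas], collapse = ", "))
  d <- merge(d, surprisals, by.x = "item", by.y = "word", sort = FALSE)
  if (design == "exp2")
    d$position <- ifelse(d$row_position == 5, 0.5, -0.5)
  d
}

#' Rank language models by deviance decrease
#'
#' For each dependent measure and each surprisal model, fits the
#' design-specific baseline regression (single-word design: presentation
#' order plus subject and item intercepts; word-row design: order and
#' launch site, subject/item/list intercepts and a per-subject slope for
#' row position) and the same model augmented with the language model's
#' surprisal, and reports AIC, deviance decrease, and the likelihood-ratio
#' p value. Rows dropped for GmF (single-fixation trials) are dropped from
#' that measure's baseline as well, never from the other measures.
#'
#' @param measures measure table (exclusions applied; excluded rows are
#'   ignored).
#' @param surprisals data.frame with a `word` column and one bits column
#'   per model.
#' @param design `"exp1"` or `"exp2"`.
#' @param dependents measures to analyse.
#' @param joint_word_unigram if TRUE the baseline additionally contains the
#'   word-unigram surprisal, so each model's delta measures improvement
#'   beyond surface frequency (the word unigram itself is then skipped).
#' @return data.frame with columns `measure`, `model`, `aic`,
#'   `delta_deviance`, `p_value`, sorted by delta within measure.
#' @export
run_model_ranking <- function(measures, surprisals, design = c("exp1", "exp2"),
                              dependents = c("GD", "FFD", "GmF"),
                              joint_word_unigram = FALSE) {
  design <- match.arg(design)
  d <- prepare_ranking_data(measures, surprisals, design)
  model_cols <- setdiff(names(surprisals), "word")
  if (joint_word_unigram) {
    if (!"word_unigram" %in% model_cols)
      stop("joint analysis requires a word_unigram surprisal column")
    model_cols <- setdiff(model_cols, "word_unigram")
  }
  out <- lapply(dependents, function(dep) {
    dd <- d[!is.na(d[[dep]]), , drop = FALSE]
    b_spec <- baseline_spec(dep, design, joint_word_unigram)
    base <- fit_lmm(b_spec, dd)
    rows <- lapply(model_cols, function(m) {
      a_spec <- b_spec
      a_spec$predictor_of_interest <- m
      aug <- fit_lmm(a_spec, dd)
      compare_to_baseline(base, aug, df = 1L, model_name = m)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$delta_deviance), ]
    cbind(measure = dep, tab)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Model ranking beyond surface frequency
#'
#' Convenience wrapper around [run_model_ranking()] with the word-unigram
#' surprisal added to the baseline.
#'
#' @inheritParams run_model_ranking
#' @export
joint_with_word_unigram <- function(measures, surprisals,
                                    design = c("exp1", "exp2"),
                                    dependents = c("GD", "FFD", "GmF")) {
  run_model_ranking(measures, surprisals, design, dependents,
                    joint_word_unigram = TRUE)
}

#' Item-level correlations between predictors and gaze measures
#'
#' Measures are first aggregated to item means over subjects (included
#' rows only), then Pearson correlations with two-sided p values are
#' computed against each predictor column. Stars mark p < .05 / .01 /
#' .001; constant columns yield missing correlations.
#'
#' @param measures measure table.
#' @param predictors data.frame with a `word` column and numeric predictor
#'   columns.
#' @param dependents measures to correlate.
#' @return data.frame with `predictor`, `measure`, `r`, `p`, `stars`, `n`.
#' @export
correlations <- function(measures, predictors,
                         dependents = c("GD", "FFD", "GmF")) {
  d <- measures[!measures$excluded, , drop = FALSE]
  agg <- stats::aggregate(d[dependents], by = list(item = d$item),
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg <- merge(agg, predictors, by.x = "item", by.y = "word")
  pred_cols <- setdiff(names(predictors), "word")
  rows <- list()
  for (p in pred_cols) for (m in dependents) {
    x <- agg[[p]]; y <- agg[[m]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, measure = m, r = NA_real_, p = NA_real_,
        stars = "", n = sum(ok))
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
      else if (ct$p.value < 0.05) "*" else ""
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = p, measure = m, r = unname(ct$estimate),
      p = ct$p.value, stars = stars, n = sum(ok))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
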