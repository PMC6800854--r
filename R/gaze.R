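#' @name fixation-report
#' @title Fixation report schema
#' @description
#' Fixation-level input is a plain TSV with a header and one row per
#' fixation, ordered by onset within trial:
#' `subject`, `trial`, `item` (word string of the fixated interest area),
#' `fixation_index`, `interest_area` (word slot, 1 for the single-word
#' design, 1-7 for the word-row design), `onset_ms`, `duration_ms`,
#' `x_offset_letters` (letters right of the interest area's left border),
#' `area_len` (interest-area width in letters), `response_correct`,
#' `rt_ms`, `list_id`, `row_position` (3 or 5 on target-area fixations,
#' NA otherwise), `presentation_order`.
NULL

#' Read / write a fixation report TSV
#' @param path file path.
#' @return data.frame in the schema described in [fixation-report].
#' @export
read_fixation_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_fixation_report
#' @param fixations fixation data.frame.
#' @export
write_fixation_report <- function(fixations, path) {
  utils::write.table(fixations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

measure_row <- function(subject, item, trial, FFD, GD, GmF,
                        presentation_order = NA, launch_site = NA,
                        row_position = NA, list_id = NA,
                        response_correct = NA, rt_ms = NA,
                        excluded = FALSE, reason = NA_character_) {
  data.frame(subject = subject, item = item, trial = trial,
             FFD = FFD, GD = GD, GmF = GmF,
             presentation_order = presentation_order,
             launch_site = launch_site, row_position = row_position,
             list_id = list_id, response_correct = response_correct,
             rt_ms = rt_ms, excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Trial-level gaze measures for the single-word design
#'
#' For each subject-by-trial block of fixations on a single word:
#' FFD is the duration of the first fixation, GD the sum of all fixation
#' durations on the word, and GmF = GD - FFD, entered as missing when the
#' trial has exactly one fixation.
#'
#' @param fixations fixation report data.frame ([fixation-report]).
#' @return measure table: one row per subject x trial with FFD, GD, GmF,
#'   covariates, and exclusion flags (all FALSE here).
#' @export
compute_measures_exp1 <- function(fixations) {
  f <- fixations[order(fixations$subject, fixations$trial,
                       fixations$onset_ms), ]
  key <- interaction(f$subject, f$trial, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(f)), key), function(ix) {
    g <- f[ix, ]
    ffd <- g$duration_ms[1L]
    gd <- sum(g$duration_ms)
    gmf <- if (nrow(g) == 1L) NA_real_ else gd - ffd
    measure_row(g$subject[1L], g$item[1L], g$trial[1L], ffd, gd, gmf,
                presentation_order = g$presentation_order[1L],
                response_correct = g$response_correct[1L],
                rt_ms = g$rt_ms[1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trial-level first-pass gaze measures for the word-row design
#'
#' Measures are restricted to first-pass reading: for each target interest
#' area, the defining run is the maximal block of consecutive fixations on
#' that area starting at its first entry. FFD is the first fixation of the
#' run, GD the sum over the run only (refixations after leaving the area
#' are excluded), and GmF = GD - FFD, missing for single-fixation runs.
#' The launch site is the letter distance from the last fixation in the
#' previous interest area to the left border of the target area, computed
#' from the immediately preceding fixation (`area_len - x_offset_letters
#' + 1`). Targets never fixated yield an excluded row with reason
#' `"skipped"`.
#'
#' @param fixations fixation report data.frame; target areas are the
#'   interest areas whose fixations carry a non-missing `row_position`.
#' @param targets optional data.frame (`subject`, `trial`,
#'   `interest_area`, `item`, `row_position`) declaring the target areas
#'   explicitly; required to emit `"skipped"` rows for targets that were
#'   never fixated (those cannot be discovered from the fixations alone).
#' @return measure table with one row per subject x trial x target area.
#' @export
compute_measures_exp2 <- function(fixations, targets = NULL) {
  f <- fixations[order(fixations$subject, fixations$trial,
                       fixations$onset_ms), ]
  key <- interaction(f$subject, f$trial, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(f)), key), function(ix) {
    g <- f[ix, ]
    target_items <- unique(g[!is.na(g$row_position),
                             c("interest_area", "item", "row_position")])
    if (!is.null(targets)) {
      extra <- targets[targets$subject == g$subject[1L] &
                         targets$trial == g$trial[1L],
                       c("interest_area", "item", "row_position")]
      target_items <- unique(rbind(target_items, extra))
      target_items <- target_items[!duplicated(target_items$interest_area), ]
    }
    do.call(rbind, lapply(target_items$interest_area, function(a) {
      ti <- target_items[target_items$interest_area == a, ]
      on_target <- which(g$interest_area == a)
      if (length(on_target) == 0L)
        return(measure_row(g$subject[1L], ti$item[1L], g$trial[1L],
                           NA_real_, NA_real_, NA_real_,
                           presentation_order = g$presentation_order[1L],
                           row_position = ti$row_position[1L],
                           list_id = g$list_id[1L],
                           excluded = TRUE, reason = "skipped"))
      first <- on_target[1L]
      run_end <- first
      while (run_end + 1L <= nrow(g) && g$interest_area[run_end + 1L] == a)
        run_end <- run_end + 1L
      run <- g[first:run_end, ]
      ffd <- run$duration_ms[1L]
      gd <- sum(run$duration_ms)
      gmf <- if (nrow(run) == 1L) NA_real_ else gd - ffd
      launch <- if (first > 1L) {
        prev <- g[first - 1L, ]
        prev$area_len - prev$x_offset_letters + 1
      } else NA_real_
      measure_row(g$subject[1L], ti$item[1L], g$trial[1L], ffd, gd, gmf,
                  presentation_order = g$presentation_order[1L],
                  launch_site = launch, row_position = ti$row_position[1L],
                  list_id = g$list_id[1L])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject outlier trimming
#'
#' Single-pass rule: for each subject, rows of the named measure outside
#' `mean +/- k_sd * SD` of that subject's currently included rows are
#' marked excluded with reason `"outlier"`. The sample SD (n-1) is used;
#' subjects with fewer than two included rows, or zero SD, are left
#' untrimmed. Bounds are not re-iterated.
#'
#' @param table measure table.
#' @param measure column name to trim on (e.g. `"rt_ms"` for the
#'   single-word design, `"GD"` for first-run gaze durations).
#' @param k_sd number of standard deviations.
#' @return the table with updated `excluded` / `reason` columns.
#' @export
trim_outliers <- function(table, measure, k_sd = 3) {
  stopifnot(measure %in% names(table))
  for (s in unique(table$subject)) {
    ix <- which(table$subject == s & !table$excluded &
                  !is.na(table[[measure]]))
    if (length(ix) < 2L) next
    m <- mean(table[[measure]][ix])
    sd_ <- stats::sd(table[[measure]][ix])
    if (!is.finite(sd_) || sd_ == 0) next
    out <- ix[table[[measure]][ix] < m - k_sd * sd_ |
                table[[measure]][ix] > m + k_sd * sd_]
    table$excluded[out] <- TRUE
    table$reason[out] <- "outlier"
  }
  table
}

#' Exclude error trials and high-error subjects
#'
#' Error trials are excluded first (reason `"error"`); then any subject
#' whose error rate across their trials strictly exceeds
#' `max_error_rate` is excluded entirely (reason `"subject-error-rate"`).
#'
#' @param table measure table with a logical `response_correct` column.
#' @param max_error_rate proportion; the criterion is a strict `>`.
#' @return updated measure table.
#' @export
exclude_error_and_subjects <- function(table, max_error_rate = 0.15) {
  if (all(is.na(table$response_correct)))
    stop("response_correct is required for error-based exclusion")
  err <- !table$response_correct
  table$excluded[err & !table$excluded] <- TRUE
  table$reason[err & is.na(table$reason)] <- "error"
  rate <- tapply(err, table$subject, mean)
  bad <- names(rate)[rate > max_error_rate]
  ix <- table$subject %in% bad
  table$reason[ix & !table$excluded] <- "subject-error-rate"
  table$excluded[ix] <- TRUE
  table
}

#' Split items into short and long sets by letter length
#'
#' @param items character vector of words.
#' @param threshold_letters short means `length <= threshold_letters`;
#'   long means at least one letter more.
#' @return list with `short` and `long` character vectors.
#' @export
split_by_length <- function(items, threshold_letters = 8L) {
  list(short = items[nchar(items) <= threshold_letters],
       long = items[nchar(items) >= threshold_letters + 1L])
}

#' Write a measure table as TSV
#' @param table measure table.
#' @param path output file.
#' @export
write_measure_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
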