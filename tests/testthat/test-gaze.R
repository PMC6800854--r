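fix_row <- function(subject, trial, item, idx, area, onset, dur,
                    x = 0, len = nchar(item), correct = NA, rt = NA,
                    rowpos = NA_integer_) {
  data.frame(subject = subject, trial = trial, item = item,
             fixation_index = idx, interest_area = area, onset_ms = onset,
             duration_ms = dur, x_offset_letters = x, area_len = len,
             response_correct = correct, rt_ms = rt, list_id = NA,
             row_position = rowpos, presentation_order = 1L)
}

test_that("single-word measures follow the FFD/GD/GmF definitions", {
  f <- rbind(fix_row(1, 1, "talossa", 1, 1, 0, 200),
             fix_row(1, 1, "talossa", 2, 1, 200, 150),
             fix_row(1, 2, "kala", 1, 1, 0, 250),
             fix_row(1, 3, "kalassa", 1, 1, 0, 100),
             fix_row(1, 3, "kalassa", 2, 1, 100, 100),
             fix_row(1, 3, "kalassa", 3, 1, 200, 100))
  m <- compute_measures_exp1(f)
  m <- m[order(m$trial), ]
  expect_equal(m$FFD, c(200, 250, 100))
  expect_equal(m$GD, c(350, 250, 300))
  expect_equal(m$GmF, c(150, NA, 200))
  # GmF missing exactly on single-fixation trials
  expect_identical(is.na(m$GmF), c(FALSE, TRUE, FALSE))
})

test_that("first-run measures exclude refixations after leaving the area", {
  f <- rbind(fix_row(1, 1, "aa", 1, 2, 0, 150, x = 1, len = 4),
             fix_row(1, 1, "target", 2, 3, 150, 180, rowpos = 3L),
             fix_row(1, 1, "target", 3, 3, 330, 120, rowpos = 3L),
             fix_row(1, 1, "bb", 4, 4, 450, 200, len = 5),
             fix_row(1, 1, "target", 5, 3, 650, 90, rowpos = 3L))
  m <- compute_measures_exp2(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$FFD, 180)
  expect_equal(m$GD, 300)   # 180 + 120; the 90 ms regression is excluded
  expect_equal(m$GmF, 120)
  # launch: last fixation in area 2 at offset 1 of a 4-letter word
  expect_equal(m$launch_site, 4 - 1 + 1)
})

test_that("never-fixated targets are excluded as skipped", {
  f <- rbind(fix_row(1, 1, "aa", 1, 2, 0, 150),
             fix_row(1, 1, "t3", 2, 3, 150, 180, rowpos = 3L),
             fix_row(1, 1, "bb", 3, 4, 330, 200))
  tg <- data.frame(subject = 1, trial = 1,
                   interest_area = c(3L, 5L), item = c("t3", "t5"),
                   row_position = c(3L, 5L))
  m <- compute_measures_exp2(f, targets = tg)
  expect_equal(nrow(m), 2L)
  skipped <- m[m$row_position == 5, ]
  expect_true(skipped$excluded)
  expect_equal(skipped$reason, "skipped")
  expect_false(m$excluded[m$row_position == 3])
})
test_that("single-fixation first runs yield missing GmF", {
  f <- rbind(fix_row(1, 1, "aa", 1, 2, 0, 150),
             fix_row(1, 1, "target", 2, 3, 150, 180, rowpos = 3L),
             fix_row(1, 1, "bb", 3, 4, 330, 100))
  m <- compute_measures_exp2(f)
  expect_true(is.na(m$GmF))
  expect_equal(m$GD, m$FFD)
})

test_that("per-subject 3-SD trimming excludes extreme rows once", {
  tab <- measure_row(subject = rep(1, 20), item = paste0("w", 1:20),
                     trial = 1:20, FFD = 100, GD = 100, GmF = NA,
                     rt_ms = c(rep(500, 19), 900))
  # mean 520, sample SD sqrt(152000/19) = 89.4; 900 > 520 + 3 * 89.4
  out <- trim_outliers(tab, "rt_ms", k_sd = 3)
  expect_true(out$excluded[20])
  expect_equal(out$reason[20], "outlier")
  expect_false(any(out$excluded[1:19]))
  # single pass: re-applying on its own output changes nothing further
  again <- trim_outliers(out, "rt_ms", k_sd = 3)
  expect_identical(again$excluded, out$excluded)

  same <- measure_row(subject = rep(1, 5), item = paste0("w", 1:5),
                      trial = 1:5, FFD = 1, GD = 1, GmF = NA, rt_ms = 400)
  expect_false(any(trim_outliers(same, "rt_ms")$excluded))

  expect_identical(trim_outliers(tab, "rt_ms", k_sd = Inf)$excluded,
                   tab$excluded)

  few <- measure_row(subject = 1, item = "w", trial = 1, FFD = 1, GD = 1,
                     GmF = NA, rt_ms = 1e6)
  expect_false(any(trim_outliers(few, "rt_ms")$excluded))
})

test_that("error-based exclusion applies the strict 15% subject criterion", {
  mk <- function(subject, n_err, n = 100) {
    measure_row(subject = rep(subject, n), item = paste0("w", 1:n),
                trial = 1:n, FFD = 100, GD = 200, GmF = 100,
                response_correct = c(rep(FALSE, n_err), rep(TRUE, n - n_err)))
  }
  tab <- rbind(mk(1, 16), mk(2, 15), mk(3, 2))
  out <- exclude_error_and_subjects(tab, max_error_rate = 0.15)
  expect_true(all(out$excluded[out$subject == 1]))
  expect_true(all(out$reason[out$subject == 1] %in%
                    c("error", "subject-error-rate")))
  s2 <- out[out$subject == 2, ]
  expect_equal(sum(s2$excluded), 15)           # only the error trials
  expect_true(all(s2$reason[s2$excluded] == "error"))
  s3 <- out[out$subject == 3, ]
  expect_equal(sum(s3$excluded), 2)
})

test_that("length split uses the eight-letter boundary", {
  words <- c("abcd", "abcdefgh", "abcdefghi", strrep("a", 16))
  sp <- split_by_length(words, 8)
  expect_setequal(sp$short, words[1:2])
  expect_setequal(sp$long, words[3:4])

  all8 <- rep(strrep("x", 8), 3)
  expect_length(split_by_length(all8, 8)$long, 0L)
  expect_length(split_by_length(words, 0)$short, 0L)
})

test_that("fixation reports round-trip through TSV", {
  f <- fix_row(1, 1, "talossa", 1, 1, 0, 200)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_report(f, p)
  back <- read_fixation_report(p)
  expect_equal(back$duration_ms, f$duration_ms)
  expect_equal(back$item, f$item)
})

test_that("whole-trial gaze duration bounds the first-run gaze duration", {
  f <- rbind(fix_row(1, 1, "aa", 1, 2, 0, 150, x = 1, len = 4),
             fix_row(1, 1, "target", 2, 3, 150, 180, rowpos = 3L),
             fix_row(1, 1, "target", 3, 3, 330, 120, rowpos = 3L),
             fix_row(1, 1, "bb", 4, 4, 450, 200, len = 5),
             fix_row(1, 1, "target", 5, 3, 650, 90, rowpos = 3L))
  whole <- compute_measures_exp1(f)       # sums every fixation in the trial
  first_run <- compute_measures_exp2(f)
  expect_gte(whole$GD, first_run$GD)
})
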