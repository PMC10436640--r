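test_that("config invariants are enforced", {
  expect_error(cohort_config(n_patients = 96, n_male = 50, n_female = 47),
               "n_male")
  expect_error(cohort_config(score_sd = c(male = 0, female = 15.17)),
               "positive")
  expect_error(cohort_config(dropout_count = 96), "dropout")
  expect_error(cohort_config(improved_items = c("Q1", "Q99")), "subset")
  expect_error(cohort_config(improved_items = character(0),
                             score_effect_12mo = 15), "non-empty")
  expect_s3_class(cohort_config(improved_items = character(0),
                                score_effect_12mo = 0), "cohort_config")
})

test_that("generation is deterministic and respects the study structure", {
  cfg <- cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # 96 patients x 4 timepoints minus one dropout's timepoints 3 and 4
  expect_equal(nrow(a), 96 * 4 - 2)
  dropped <- attr(a, "dropout_ids")
  expect_length(dropped, 1)
  expect_equal(sort(unique(a$timepoint[a$patient_id == dropped])), c(1, 2))
  expect_equal(sum(a$sex[a$timepoint == 1] == "male"), 49)
})

test_that("generated records satisfy the record invariants for random configs", {
  for (seed in 1:5) {
    cfg <- random_cohort_config(seed)
    co <- generate_cohort(cfg)
    items <- as.matrix(co[questionnaire_items])
    expect_true(all(items == round(items) & items >= 1 & items <= 5))
    expect_true(all(co$completion_time_min >= 0))
    expect_true(all(co$sbp > co$dbp & co$dbp > 0))
    expect_silent(validate_cohort_records(co))
  }
})

test_that("sex-stratified moments match the configured targets in expectation", {
  # average over 5 cohorts, compared at the sampling tolerance (2 x SE)
  # of a single cohort
  ms <- sapply(1:5, function(s) {
    sc <- score_cohort(generate_cohort(cohort_config(seed = s)))
    b <- sc[sc$timepoint == 1, ]
    p <- sc[sc$timepoint == 4, ]
    c(mean(b$sbp[b$sex == "male"]), mean(b$sbp[b$sex == "female"]),
      mean(b$dbp[b$sex == "male"]), mean(b$dbp[b$sex == "female"]),
      mean(b$total_score[b$sex == "male"]),
      mean(b$total_score[b$sex == "female"]),
      mean(p$total_score[p$sex == "male"]),
      mean(p$total_score[p$sex == "female"]))
  })
  target <- c(143.04, 133.66, 94.71, 88.77, 93.78, 99.02, 108.73, 114.77)
  sds <- c(16.41, 16.63, 12.71, 12.81, 12.90, 15.17, 9.99, 6.79)
  n <- c(49, 47, 49, 47, 49, 47, 49, 47)
  expect_true(all(abs(rowMeans(ms) - target) < 2 * sds / sqrt(n)))
})

test_that("a null-effect config leaves pre/post means indistinguishable", {
  diffs <- sapply(1:20, function(s) {
    cfg <- cohort_config(sbp_effect_3mo = 0, dbp_effect_3mo = 0,
                         score_effect_12mo = 0, dropout_count = 0, seed = s)
    sc <- score_cohort(generate_cohort(cfg))
    mean(sc$total_score[sc$timepoint == 4]) -
      mean(sc$total_score[sc$timepoint == 1])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 0.5)
})

test_that("the injected score effect flows only through the improved items", {
  cfg <- cohort_config(seed = 3)
  sc <- score_cohort(generate_cohort(cfg))
  b <- sc[sc$timepoint == 1, ]
  p <- sc[sc$timepoint == 4, ]
  d <- colMeans(p[questionnaire_items]) - colMeans(b[questionnaire_items])
  others <- setdiff(questionnaire_items, cfg$improved_items)
  expect_gt(min(d[cfg$improved_items]), 0.8)  # ~1.5 points injected per item
  expect_lt(max(abs(d[others])), 0.4)
  # reverse-coded improved items decrease on the raw scale
  co <- generate_cohort(cfg)
  rev_imp <- intersect(cfg$improved_items, reverse_items)
  raw_d <- colMeans(co[co$timepoint == 4, rev_imp, drop = FALSE]) -
    colMeans(co[co$timepoint == 1, rev_imp, drop = FALSE])
  expect_true(all(raw_d < 0))
})

test_that("completion times follow the configured per-questionnaire moments", {
  cfg <- cohort_config(seed = 21)
  set.seed(100)
  x <- generate_completion_times(cfg, 2, n = 96)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 6.25), 2 * 3.19 / sqrt(96) + 0.1)
  cfg0 <- cohort_config(time_mean = c(5, 5, 5, 5), time_sd = rep(0, 4))
  expect_equal(generate_completion_times(cfg0, 1, n = 10), rep(5, 10))
  cfg00 <- cohort_config(time_mean = rep(0, 4), time_sd = rep(0, 4))
  expect_equal(generate_completion_times(cfg00, 3, n = 4), rep(0, 4))
  expect_error(generate_completion_times(cfg, 9), "timepoint")
  expect_error(cohort_config(time_mean = c(-1, 6, 5, 4)), "nonnegative")
})

test_that("cohort CSV fixtures round-trip and malformed rows are diagnosed", {
  co <- generate_cohort(cohort_config(n_patients = 12, n_male = 6,
                                      n_female = 6, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back, as.data.frame(co), ignore_attr = TRUE)
  # same seed, same config -> byte-identical files
  path2 <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(cohort_config(n_patients = 12, n_male = 6,
                                                 n_female = 6, seed = 8)),
                   path2)
  expect_identical(readLines(path), readLines(path2))
  # empty table -> header-only file that reads back empty
  empty <- co[0, ]
  path3 <- tempfile(fileext = ".csv")
  write_cohort_csv(empty, path3)
  expect_length(readLines(path3), 1)
  expect_equal(nrow(read_cohort_csv(path3)), 0)
  # a hand-corrupted score is rejected with a row/field diagnostic
  bad <- co
  bad$Q7[3] <- 7
  path4 <- tempfile(fileext = ".csv")
  write.csv(bad, path4, row.names = FALSE)
  expect_error(read_cohort_csv(path4), "row 3.*Q7")
})
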