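test_that("condition sampling is deterministic, bounded, and uniform", {
  spec <- cohort_spec("lr91", list(severe = 10000), seed = 7)
  draws <- sample_conditions(spec)
  expect_equal(nrow(draws), 10000)
  expect_identical(draws, sample_conditions(spec))  # same seed, same draws

  r <- default_config()$cohort$ranges$severe
  expect_true(all(draws$ko_mm >= r$ko[1] & draws$ko_mm <= r$ko[2]))
  expect_true(all(draws$phi >= r$phi[1] & draws$phi <= r$phi[2]))
  expect_true(all(draws$gkatp_ms_uf >= r$gkatp[1] &
                    draws$gkatp_ms_uf <= r$gkatp[2]))
  # law of large numbers: mean within 1% of the range midpoint
  # (1% of the midpoint value, a few empirical SEs at n = 10,000)
  expect_lt(abs(mean(draws$ko_mm) - mean(r$ko)), 0.01 * mean(r$ko))
  expect_lt(abs(mean(draws$phi) - mean(r$phi)), 0.01 * mean(r$phi))
  expect_lt(abs(mean(draws$gkatp_ms_uf) - mean(r$gkatp)),
            0.01 * mean(r$gkatp) + 3 * 0.15 / sqrt(12) / 100)
})

test_that("zero counts yield an empty cohort and bad specs are rejected", {
  spec <- cohort_spec("lr91", list(healthy = 0, moderate = 0, severe = 0),
                      seed = 1)
  expect_equal(nrow(sample_conditions(spec)), 0)
  expect_error(cohort_spec("lr91", list(mild = 5), seed = 1),
               class = "apdecon_spec_error")
  expect_error(cohort_spec("lr91", list(severe = -1), seed = 1),
               class = "apdecon_spec_error")
  bad <- default_config()$cohort$ranges
  bad$severe$ko <- c(9, 99)  # outside the global hyperkalemia bound
  expect_error(cohort_spec("lr91", list(severe = 5), seed = 1, ranges = bad),
               class = "apdecon_spec_error")
})

test_that("generated feature tables are labeled, complete and in-range", {
  tbl <- default_run()$train_table
  expect_equal(nrow(tbl), 150)
  expect_equal(as.integer(table(tbl$category)[c("healthy", "moderate", "severe")]),
               c(50L, 50L, 50L))
  expect_true(all(tbl$model == "lr91"))
  expect_false(any(is.na(tbl)))
  # every label triple inside its category's configured range
  ranges <- default_config()$cohort$ranges
  for (cat in names(ranges)) {
    sub <- dplyr::filter(tbl, category == cat)
    r <- ranges[[cat]]
    expect_true(all(sub$ko_mm >= r$ko[1] & sub$ko_mm <= r$ko[2]))
    expect_true(all(sub$phi >= r$phi[1] & sub$phi <= r$phi[2]))
    expect_true(all(sub$gkatp_ms_uf >= r$gkatp[1] &
                      sub$gkatp_ms_uf <= r$gkatp[2]))
  }
  # ischemia severity is visible in the waveforms
  expect_lt(mean(tbl$rmp_mv[tbl$category == "healthy"]),
            mean(tbl$rmp_mv[tbl$category == "severe"]))
  expect_gt(mean(tbl$apd90_ms[tbl$category == "healthy"]),
            mean(tbl$apd90_ms[tbl$category == "severe"]))
})

test_that("regeneration from the same spec is bit-identical at the CSV level", {
  spec <- cohort_spec("lr91", list(healthy = 2, severe = 2), seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(generate_dataset(spec), p1)
  write_feature_table(generate_dataset(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("feature tables and traces round-trip through their CSV writers", {
  spec <- cohort_spec("tt06", list(moderate = 2), seed = 3)
  tdir <- withr::local_tempdir()
  tbl <- generate_dataset(spec, traces_dir = tdir)
  expect_equal(nrow(tbl), 2)
  files <- list.files(tdir, full.names = TRUE)
  expect_length(files, 2)
  back <- read_ap_trace(files[1])
  expect_equal(attr(back, "model"), "tt06")

  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, p)
  expect_equal(as.data.frame(read_feature_table(p)), as.data.frame(tbl),
               tolerance = 1e-12)
})

test_that("stratified split keeps proportions and partitions the table", {
  tbl <- default_run()$train_table
  sp <- split_cohort(tbl, test_fraction = 0.2, seed = 5)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tbl))
  expect_equal(as.integer(table(sp$test$category)), c(10L, 10L, 10L))
  expect_equal(nrow(dplyr::inner_join(sp$train, sp$test,
                                      by = colnames(tbl))), 0)
  # deterministic under the seed
  sp2 <- split_cohort(tbl, test_fraction = 0.2, seed = 5)
  expect_identical(sp$test, sp2$test)
})
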