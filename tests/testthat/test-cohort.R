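test_that("generator is deterministic: same params and seed give byte-identical files", {
  p <- cohort_params(n = 95, seed = 20)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(p), f1)
  write_cohort(generate_cohort(p), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p2 <- cohort_params(n = 95, seed = 21)
  f3 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(p2), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("covariate draws respect the configured marginal frequencies", {
  coh <- generate_cohort(cohort_params(n = 95, seed = 8))
  adv <- mean(coh$t_stage == "T3-T4")
  half_width <- 1.96 * sqrt(0.68 * 0.32 / 95)
  expect_gt(adv, 0.68 - half_width)
  expect_lt(adv, 0.68 + half_width)

  big <- generate_cohort(cohort_params(n = 2000, seed = 9))
  expect_equal(mean(big$n_stage == "N+"), 0.44, tolerance = 0.05)
  expect_equal(mean(big$pni), 0.21, tolerance = 0.04)
})

test_that("morphometric marginals match the configured distributions at n = 2000", {
  big <- generate_cohort(cohort_params(n = 2000, seed = 10))
  expect_lt(abs(mean(big$Vt_cm3) / 13.6 - 1), 0.10)
  expect_lt(abs(mean(big$St) - 0.63), 0.02)
  expect_true(all(big$Vt_cm3 >= 0.1 & big$Vt_cm3 <= 96.2))
  expect_true(all(big$St > 0 & big$St < 1))
  expect_true(all(big$time_to_recurrence >= 0))
  expect_true(all(big$time_to_recurrence <= 122))
  expect_true(all(big$recurrence_event %in% 0:1))
})

test_that("a strong volume effect induces shorter observed recurrence times", {
  p <- cohort_params(n = 400, seed = 11,
                     log_hazard = list(recurrence = c(vt = 0.08)))
  coh <- generate_cohort(p)
  tau <- stats::cor(coh$Vt_cm3, coh$time_to_recurrence, method = "kendall")
  expect_lt(tau, 0)
})

test_that("cohort tables round-trip losslessly, including zero-event cohorts", {
  coh <- generate_cohort(cohort_params(n = 95, seed = 12))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  for (col in names(back)) {
    expect_identical(back[[col]], unname(as.data.frame(coh)[[col]]),
                     label = col)
  }
  # zero-event cohort: negligible hazards
  p0 <- cohort_params(n = 40, seed = 13,
                      baseline_hazard = c(recurrence = 1e-9, death = 1e-9))
  coh0 <- generate_cohort(p0)
  expect_equal(sum(coh0$recurrence_event), 0)
  f0 <- tempfile(fileext = ".csv")
  write_cohort(coh0, f0)
  back0 <- read_cohort(f0)
  expect_equal(sum(back0$recurrence_event), 0)
  expect_equal(sum(back0$death_event), 0)
})

test_that("malformed cohort tables produce named-column and row-level errors", {
  coh <- generate_cohort(cohort_params(n = 10, seed = 14))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  lines <- readLines(f)
  # drop a required column
  short <- tempfile(fileext = ".csv")
  tab <- utils::read.csv(f)
  tab$St <- NULL
  utils::write.csv(tab, short, row.names = FALSE)
  expect_error(read_cohort(short), "St")
  # corrupt one numeric cell
  bad <- tempfile(fileext = ".csv")
  lines[4] <- sub('","([0-9.]+)","', '","volume?","', lines[4])
  writeLines(lines, bad)
  expect_error(read_cohort(bad), "row 3")
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_params(n = 1), "at least 2")
  expect_error(cohort_params(covariate_frequencies = list(pni = 1.4)),
               "frequencies")
  expect_error(cohort_params(st_sd = 0.5), "Beta")
  expect_error(cohort_params(log_hazard = list(recurrence = c(bogus = 1))),
               "unknown log-hazard")
})
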