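test_that("cohort CSV round-trips through write and read unchanged", {
  co <- make_cohort(3, breed = c("Crossbred", "Cockapoo", "Shih-tzu"),
                    age_years = c(0.5, 4.2, 9.9),
                    bodyweight_cat = c("<10", "not recorded", ">=30"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)
})

test_that("validation rejects unknown category levels naming row and field", {
  co <- make_cohort(3)
  co$breed <- as.character(co$breed)
  co$breed[2] <- "Labradoodle"
  expect_error(validate_cohort(co), "breed.*Labradoodle.*row 2")
})

test_that("a missing mandatory column is a schema error", {
  co <- make_cohort(2)
  co$vomiting <- NULL
  expect_error(validate_cohort(co), "missing mandatory column.*vomiting")
})

test_that("category aliases map onto canonical levels", {
  co <- make_cohort(2)
  co$bodyweight_cat <- c("under 10kg", "<10")
  out <- validate_cohort(co,
    aliases = list(bodyweight_cat = c("under 10kg" = "<10")))
  expect_equal(as.character(out$bodyweight_cat), c("<10", "<10"))
})

test_that("eligibility applies each rule with fixed precedence", {
  raw <- make_raw(9,
    age_years = c(0.2, 10, 4, 4, 4, 4, 4, 4, 4),
    prior_diarrhoea_within_30d = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    prior_exposure_within_30d = c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    excluded_diagnosis = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    duration_days_prior = c(1, 1, 1, 1, 1, 8, 7, 1, 1),
    iv_fluids = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L))
  out <- apply_eligibility(raw)
  # record 2 fails both age and prior exposure: tallied under age (first rule)
  expect_equal(unname(out$tally[c("age", "prior_diarrhoea", "prior_exposure",
                                  "excluded_diagnosis", "duration",
                                  "iv_fluids")]),
               c(2L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(unname(out$tally[["retained"]]), 2L)
  expect_equal(sum(out$tally) - out$tally[["retained"]], nrow(raw) - 2L)
  # boundary handling: age 0.25 in, 10 out; 7 days' duration retained
  expect_true(all(out$cohort$age_years %in% c(4)))
  expect_equal(nrow(out$cohort), 2L)
})

test_that("eligibility retains passing records unchanged and is idempotent", {
  raw <- make_raw(5, age_years = c(0.25, 3, 6, 9.99, 5))
  out <- apply_eligibility(raw)
  expect_equal(nrow(out$cohort), 5L)
  expect_equal(out$cohort$age_years, raw$age_years)
  again <- apply_eligibility(raw[rep(TRUE, 5), ])
  expect_equal(again$cohort, out$cohort)
})

test_that("arm summaries report within-arm percentages to one decimal", {
  co <- make_cohort(1, antimicrobial = 1L)
  s <- summarize_cohort(co, "antimicrobial")
  expect_equal(s$n_exposed, 1L)
  yes <- s$table[s$table$variable == "vomiting" & s$table$level == "No", ]
  expect_equal(yes$pct_exposed, 100.0)
  # percentages within one covariate and arm sum to 100 (up to rounding)
  co2 <- make_cohort(37, antimicrobial = rep_len(c(1L, 0L), 37),
                     bodyweight_cat = rep_len(cohort_levels()$bodyweight_cat, 37))
  s2 <- summarize_cohort(co2, "antimicrobial")
  for (v in unique(s2$table$variable)) {
    sub <- s2$table[s2$table$variable == v, ]
    expect_lt(abs(sum(sub$pct_exposed) - 100), 0.26)
    expect_lt(abs(sum(sub$pct_unexposed) - 100), 0.26)
  }
})

test_that("an empty cohort summarises to n = 0", {
  s <- summarize_cohort(make_cohort(0), "antimicrobial")
  expect_equal(s$n, 0L)
})
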