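test_that("product-limit curves match hand computation on toy data", {
  # no events: flat at 1
  km <- km_curve(c(5, 10, 30, 30), c(0, 0, 0, 0), rep(1, 4))
  expect_true(all(km$surv == 1))
  # events at day 1 and 2, no censoring: S(2) = (3/4)(2/3) = 0.5
  km <- km_curve(c(1, 2, 30, 30), c(1, 1, 0, 0), rep(1, 4))
  expect_equal(km$surv[km$day == 0], 1)
  expect_equal(km$surv[km$day == 1], 0.75)
  expect_equal(km$surv[km$day == 2], 0.5)
  expect_equal(km$surv[km$day == 30], 0.5)
  # all four events on day 1
  km <- km_curve(rep(1, 4), rep(1, 4), rep(1, 4))
  expect_equal(km$surv[km$day == 1], 0)
  expect_error(km_curve(1, 1, factor("a", levels = c("a", "b"))), "zero records")
})

test_that("log-rank agrees with a first-principles tabulation", {
  # identical event patterns: statistic 0, p = 1
  lr <- logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0), rep(0:1, each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # all early events in one group: match the hand tabulation exactly
  times <- c(1, 2, 3, 10, 12, 30); events <- c(1, 1, 1, 1, 1, 0)
  grp <- c(1, 1, 1, 0, 0, 0)
  lr <- logrank(times, events, grp)
  expect_equal(lr$chisq, logrank_oracle(times, events, grp), tolerance = 1e-10)
  # label permutation leaves the statistic unchanged
  lr2 <- logrank(times, events, 1 - grp)
  expect_equal(lr2$chisq, lr$chisq, tolerance = 1e-12)
  # no events at all: undefined, flagged
  lr3 <- logrank(c(3, 4), c(0, 0), c(0, 1))
  expect_true(is.na(lr3$chisq))
  expect_match(lr3$note, "no events")
})

test_that("person-day expansion conserves events and maps day 0 to day 1", {
  times <- c(0, 1, 3, 30, 12); events <- c(1L, 1L, 0L, 0L, 1L)
  pd <- person_day_expand(times, events)
  expect_equal(sum(pd$event), sum(events))
  expect_equal(nrow(pd), 1 + 1 + 3 + 30 + 12)
  expect_equal(pd$day[pd$id == 1], 1L)     # day-0 revisit counted on day 1
  expect_equal(max(pd$day[pd$id == 3]), 3L) # censored dog at risk through day 3
})

test_that("saturated IP-weighted hazards with unit weights reproduce KM", {
  out <- generate_cohort(default_study_config(n = 600, seed = 9))
  co <- out$cohort
  ws <- fit_propensity(co, propensity_spec("antimicrobial", character()))
  tte <- ipw_survival(co, "antimicrobial", ws,
                      time_model = "per-day-indicators", n_boot = 1, seed = 1)
  km <- km_curve(co$escalation_day, co$escalated, co$antimicrobial)
  for (arm in 0:1) {
    s_ipw <- tte$curve$surv[tte$curve$arm == arm]
    s_km <- km$surv[km$group == as.character(arm)]
    expect_lt(max(abs(s_ipw - s_km)), 1e-6)
  }
})

test_that("standardised curves are proper survival functions", {
  out <- generate_cohort(default_study_config(n = 500, seed = 13))
  ws <- fit_propensity(out$cohort, default_propensity_spec("antimicrobial"))
  tte <- ipw_survival(out$cohort, "antimicrobial", ws, n_boot = 25, seed = 2)
  for (arm in 0:1) {
    s <- tte$curve$surv[tte$curve$arm == arm]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
  with(tte$curve[-c(1, 32), ], {           # day 0 has no bootstrap spread
    expect_true(all(ci_low <= surv + 1e-9 & ci_high >= surv - 1e-9))
  })
  expect_equal(tte$table$day, c(1, 5, 10, 15, 20, 25, 30))
  expect_equal(tte$table$diff, tte$table$surv_exposed - tte$table$surv_unexposed)
  # bootstrap determinism
  tte2 <- ipw_survival(out$cohort, "antimicrobial", ws, n_boot = 25, seed = 2)
  expect_identical(tte$curve, tte2$curve)
  expect_identical(tte$table, tte2$table)
})

test_that("equal escalation hazards give null differences at every timepoint", {
  out <- generate_cohort(default_study_config(n = 2000, seed = 11))
  ws <- fit_propensity(out$cohort, default_propensity_spec("antimicrobial"))
  tte <- ipw_survival(out$cohort, "antimicrobial", ws, n_boot = 200, seed = 5)
  expect_true(all(tte$table$ci_low <= 0 & tte$table$ci_high >= 0))
  expect_lte(tte$discarded, 20)
})
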