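test_that("unadjusted risk differences follow the rounded-percent convention", {
  est <- unadjusted_rd(100, 80, 100, 80)
  expect_equal(est$rd, 0)
  expect_error(unadjusted_rd(0, 0, 10, 5), "non-empty")
  expect_error(unadjusted_rd(10, 11, 10, 5), "resolved")
})

test_that("unit weights reduce the IPTW estimate to the crude contrast", {
  co <- make_cohort(40, antimicrobial = rep_len(c(1L, 0L), 40),
                    resolved_30d = rep_len(c(1L, 1L, 0L), 40))
  ws <- fit_propensity(co, propensity_spec("antimicrobial", character()))
  est <- iptw_rd(co, "antimicrobial", ws)
  a <- co$antimicrobial
  crude <- 100 * (mean(co$resolved_30d[a == 1]) - mean(co$resolved_30d[a == 0]))
  expect_equal(est$rd, crude, tolerance = 1e-8)
})

test_that("IPTW with a saturated propensity equals exact standardisation", {
  co <- fixture_confounded_8()
  ws <- fit_propensity(co, propensity_spec("antimicrobial", "comorbidity"))
  est <- iptw_rd(co, "antimicrobial", ws)
  expect_equal(est$risk_exposed, 100 * 5 / 6, tolerance = 1e-8)
  expect_equal(est$risk_unexposed, 100 * 1 / 6, tolerance = 1e-8)
  expect_equal(est$rd, standardize_oracle(co, "antimicrobial", "comorbidity"),
               tolerance = 1e-8)
  expect_equal(est$rd, 66.6667, tolerance = 1e-3)

  # property: the equivalence holds on random discretely-confounded cohorts
  for (s in 1:5) {
    set.seed(s)
    n <- 120
    L <- rbinom(n, 1, 0.45)
    a <- rbinom(n, 1, plogis(-0.5 + 1.4 * L))
    y <- rbinom(n, 1, plogis(0.4 - 0.9 * L))
    if (length(unique(a[L == 0])) < 2 || length(unique(a[L == 1])) < 2) next
    coh <- make_cohort(n, comorbidity = L, antimicrobial = a, resolved_30d = y)
    wss <- fit_propensity(coh, propensity_spec("antimicrobial", "comorbidity"))
    expect_equal(iptw_rd(coh, "antimicrobial", wss)$rd,
                 standardize_oracle(coh, "antimicrobial", "comorbidity"),
                 tolerance = 1e-8)
  }
})

test_that("a degenerate arm suppresses the interval but keeps the risks", {
  co <- make_cohort(20, antimicrobial = rep_len(c(1L, 0L), 20),
                    resolved_30d = ifelse(rep_len(c(1L, 0L), 20) == 1L, 1L,
                                          rep_len(c(1L, 0L), 20)))
  ws <- fit_propensity(co, propensity_spec("antimicrobial", character()))
  est <- iptw_rd(co, "antimicrobial", ws)
  expect_true(est$degenerate)
  expect_true(is.na(est$ci_low))
  expect_equal(est$risk_exposed, 100)
})

test_that("under the confounded null the IPTW estimate is unbiased at scale", {
  out <- generate_cohort(default_study_config(n = 2000, seed = 11, true_rd = 0))
  ws <- fit_propensity(out$cohort, default_propensity_spec("antimicrobial"))
  est <- iptw_rd(out$cohort, "antimicrobial", ws)
  expect_lt(abs(est$rd), 2 * est$se)
})

test_that("weighting removes confounding bias where it dominates noise", {
  spec <- default_propensity_spec("antimicrobial")
  wins <- vapply(1:40, function(r) {
    co <- generate_cohort(default_study_config(n = 4000, seed = 5000 + r))$cohort
    a <- co$antimicrobial
    crude <- 100 * (mean(co$resolved_30d[a == 1]) - mean(co$resolved_30d[a == 0]))
    est <- iptw_rd(co, "antimicrobial", fit_propensity(co, spec))
    abs(crude) > abs(est$rd)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
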