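test_that("design encoding expands categoricals with missing indicators", {
  co <- make_cohort(10,
    bodyweight_cat = rep_len(cohort_levels()$bodyweight_cat, 10),
    age_years = seq(1, 9, length.out = 10))
  spec <- propensity_spec("antimicrobial", c("bodyweight_cat"),
                          quadratic_terms = "age_years")
  enc <- encode_design(co, spec)
  bw_cols <- grep("^bodyweight_cat=", colnames(enc$X), value = TRUE)
  expect_length(bw_cols, 4L)             # 5 levels -> 4 indicators
  expect_true("bodyweight_cat=not recorded" %in% bw_cols)
  expect_equal(unname(enc$X[, "age_years^2"]), co$age_years^2)
})

test_that("an empty level is dropped from the design with a warning", {
  co <- make_cohort(6, bodyweight_cat = c("<10", "10-<20", "20-<30", ">=30",
                                          "<10", "10-<20"))
  spec <- propensity_spec("antimicrobial", "bodyweight_cat")
  expect_warning(enc <- encode_design(co, spec), "not recorded")
  expect_false("bodyweight_cat=not recorded" %in% colnames(enc$X))
})

test_that("a spec with no terms gives the intercept-only model: sw all 1", {
  co <- make_cohort(12, antimicrobial = rep_len(c(1L, 0L, 0L), 12))
  ws <- fit_propensity(co, propensity_spec("antimicrobial", character()))
  expect_equal(ws$e, rep(ws$p_A, 12), tolerance = 1e-9)
  expect_equal(ws$sw, rep(1, 12), tolerance = 1e-9)
})

test_that("saturated weights equal the stratified closed form", {
  # stratum L=0: 1 exposed / 3 unexposed (e = 0.25); L=1: 3/1 (e = 0.75)
  co <- make_cohort(8,
    comorbidity = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    antimicrobial = c(1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L))
  ws <- fit_propensity(co, propensity_spec("antimicrobial", "comorbidity"))
  expect_equal(ws$e, c(0.25, 0.25, 0.25, 0.25, 0.75, 0.75, 0.75, 0.75),
               tolerance = 1e-8)
  expect_equal(ws$p_A, 0.5)
  # sw = p_A/e for exposed, (1-p_A)/(1-e) for unexposed
  expect_equal(ws$sw[1], 2.0, tolerance = 1e-8)
  expect_equal(ws$sw[2], 0.5 / 0.75, tolerance = 1e-8)
  expect_equal(ws$sw[5], 0.5 / 0.75, tolerance = 1e-8)
  expect_equal(ws$sw[8], 0.5 / 0.25, tolerance = 1e-8)
  expect_true(all(ws$sw > 0))
})

test_that("stabilised weights preserve the pseudo-population size", {
  out <- generate_cohort(default_study_config(n = 894, seed = 21))
  ws <- fit_propensity(out$cohort, default_propensity_spec("antimicrobial"))
  expect_true(ws$converged)
  expect_lt(abs(mean(ws$sw) - 1), 0.05)
  expect_lt(abs(sum(ws$sw) - nrow(out$cohort)) / nrow(out$cohort), 0.05)
  a <- out$cohort$antimicrobial
  expect_lt(abs(sum(ws$sw[a == 1]) - nrow(out$cohort) * ws$p_A) /
              (nrow(out$cohort) * ws$p_A), 0.1)
})

test_that("interaction selection keeps only balance-improving candidates", {
  base <- propensity_spec("antimicrobial", c("age_years", "vomiting"))
  sel <- select_interactions(make_cohort(40,
      antimicrobial = rep_len(c(1L, 0L), 40), vomiting = rep_len(c(0L, 0L, 1L), 40)),
    base, candidates = list())
  expect_identical(sel$spec, base)
  expect_equal(nrow(sel$log), 0L)

  cfg <- default_study_config(n = 3000, seed = 42)
  cfg$treatment_coefs$antimicrobial$coefs[["age_x_vomiting"]] <- 1.2
  co <- generate_cohort(cfg)$cohort
  base <- propensity_spec("antimicrobial",
    c("age_years", "comorbidity", "vomiting", "reduced_appetite",
      "haematochezia", "pyrexia", "duration_cat", "vet_group",
      "nutraceutical", "diet_advice", "antiparasitic", "gi_agent"),
    quadratic_terms = "age_years")
  sel <- select_interactions(co, base,
    list(c("age_years", "vomiting"), c("haematochezia", "pyrexia")))
  expect_true(sel$log$kept[sel$log$candidate == "age_years*vomiting"])
  expect_equal(length(sel$spec$interaction_terms),
               sum(sel$log$kept))
})
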