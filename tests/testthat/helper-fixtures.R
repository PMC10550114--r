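# Fixture builders: all test data is constructed in code.

# minimal valid analysis cohort; any field can be overridden with a vector
# recycled to length n
make_cohort <- function(n, ...) {
  base <- list(
    dog_id = sprintf("d%03d", seq_len(n)), age_years = 4,
    breed = "Crossbred", bodyweight_cat = "<10", insured = 0L,
    comorbidity = 0L, vomiting = 0L, reduced_appetite = 0L,
    haematochezia = 0L, pyrexia = 0L, duration_cat = "<24h",
    vet_group = "1", antimicrobial = 0L, nutraceutical = 0L,
    diet_advice = 0L, antiparasitic = 0L, gi_agent = 0L,
    resolved_30d = 1L, escalation_day = 30, escalated = 0L)
  ov <- list(...)
  base[names(ov)] <- ov
  df <- as.data.frame(lapply(base, rep_len, n), stringsAsFactors = FALSE)
  validate_cohort(df)
}

# raw presentation records: cohort fields plus pre-filter attributes, all
# passing eligibility unless overridden
make_raw <- function(n, ...) {
  co <- make_cohort(n)
  raw <- cbind(co, data.frame(
    prior_diarrhoea_within_30d = 0L, prior_exposure_within_30d = 0L,
    excluded_diagnosis = 0L, duration_days_prior = 1,
    iv_fluids = 0L, hospitalised = 0L, died_at_presentation = 0L))
  ov <- list(...)
  for (f in names(ov)) raw[[f]] <- rep_len(ov[[f]], n)
  validate_cohort(raw, raw = TRUE)
}

# single-binary-confounder cohort; stratum L = comorbidity:
#   L=0: exposed {Y=1}, unexposed {1,0,0};  L=1: exposed {1,1,0}, unexposed {0}
fixture_confounded_8 <- function() {
  make_cohort(8,
              comorbidity = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
              antimicrobial = c(1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L),
              resolved_30d = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
}

# brute-force standardisation over discrete strata:
# sum_L P(L) * (E[Y|A=1,L] - E[Y|A=0,L]), percentage points
standardize_oracle <- function(cohort, exposure, stratum) {
  L <- cohort[[stratum]]; a <- cohort[[exposure]]; y <- cohort$resolved_30d
  lev <- unique(L)
  rd <- sum(vapply(lev, function(l) {
    pl <- mean(L == l)
    pl * (mean(y[L == l & a == 1]) - mean(y[L == l & a == 0]))
  }, numeric(1)))
  100 * rd
}

# 894-dog cohort reproducing the published arm sizes and resolution counts
# for both trials (antimicrobial 355 exposed / 314 resolved vs 539 / 471;
# nutraceutical 597 / 527 vs 297 / 258; 207 dogs with both exposures)
table5_cohort <- function() {
  cell <- function(n, a, g, y_n) {
    make_cohort(n, antimicrobial = a, nutraceutical = g,
                resolved_30d = rep(c(1L, 0L), c(y_n, n - y_n)),
                escalated = rep(c(1L, 0L), c(10L, n - 10L)),
                escalation_day = c(rep_len(1:5, 10L), rep(30, n - 10L)))
  }
  co <- rbind(cell(207, 1L, 1L, 185), cell(148, 1L, 0L, 129),
              cell(390, 0L, 1L, 342), cell(149, 0L, 0L, 129))
  co$dog_id <- sprintf("d%04d", seq_len(nrow(co)))
  co
}

# two-sample log-rank chi-square computed from first principles
logrank_oracle <- function(times, events, group) {
  tt <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    n1 <- sum(times >= t & group == 1); n0 <- sum(times >= t & group == 0)
    d1 <- sum(times == t & events == 1 & group == 1)
    d <- sum(times == t & events == 1)
    n <- n1 + n0
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
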