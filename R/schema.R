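# Cohort data model: one row per dog, baseline covariates measured at first
# presentation for acute diarrhoea, two candidate exposures, a binary 30-day
# clinical-resolution outcome and a time-to-treatment-escalation outcome.

#' Enumerated levels of the categorical cohort fields
#'
#' Category labels follow the study's covariate definitions. "not recorded"
#' is a legal level only for bodyweight and duration (the missing-indicator
#' categories).
#'
#' @return Named list of character vectors, one per categorical field.
#' @export
cohort_levels <- function() {
  list(
    breed = c("Crossbred", "Purebred - Other", "Labrador Retriever",
              "German Shepherd Dog", "Cockapoo", "Shih-tzu",
              "Staffordshire Bull Terrier", "French Bulldog",
              "Jack Russell Terrier", "Yorkshire Terrier"),
    bodyweight_cat = c("<10", "10-<20", "20-<30", ">=30", "not recorded"),
    duration_cat = c("<24h", "24-48h", "48-96h", "5-7d", "not recorded"),
    vet_group = c("1", "2", "3", "4", "5")
  )
}

# field -> type map for the analysis cohort (post-eligibility)
.cohort_fields <- function() {
  c(dog_id = "character", age_years = "numeric",
    breed = "factor", bodyweight_cat = "factor", insured = "binary",
    comorbidity = "binary", vomiting = "binary", reduced_appetite = "binary",
    haematochezia = "binary", pyrexia = "binary", duration_cat = "factor",
    vet_group = "factor",
    antimicrobial = "binary", nutraceutical = "binary",
    diet_advice = "binary", antiparasitic = "binary", gi_agent = "binary",
    resolved_30d = "binary", escalation_day = "numeric", escalated = "binary")
}

# additional pre-filter fields carried by raw presentation records
.raw_extra_fields <- function() {
  c(prior_diarrhoea_within_30d = "binary", prior_exposure_within_30d = "binary",
    excluded_diagnosis = "binary", duration_days_prior = "numeric",
    iv_fluids = "binary", hospitalised = "binary",
    died_at_presentation = "binary")
}

#' Validate a cohort data frame against the schema
#'
#' Checks column presence, coerces each field to its declared type and
#' rejects values outside the enumerated category levels. Optional field
#' aliases allow alternative spellings of category labels.
#'
#' @param df data frame to validate.
#' @param raw logical; if `TRUE` the pre-eligibility columns are also required.
#' @param aliases optional named list mapping field name to a named character
#'   vector `c(alias = canonical_level)`.
#' @return The validated, coerced data frame.
#' @export
validate_cohort <- function(df, raw = FALSE, aliases = NULL) {
  stopifnot(is.data.frame(df))
  fields <- .cohort_fields()
  if (raw) fields <- c(fields, .raw_extra_fields())
  missing_cols <- setdiff(names(fields), names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  lv <- cohort_levels()
  for (f in names(fields)) {
    x <- df[[f]]
    type <- fields[[f]]
    if (type == "character") {
      df[[f]] <- as.character(x)
    } else if (type == "numeric") {
      xn <- suppressWarnings(as.numeric(x))
      if (anyNA(xn))
        stop("validation error: field '", f, "' non-numeric at row ",
             which(is.na(xn))[1])
      df[[f]] <- xn
    } else if (type == "binary") {
      xn <- suppressWarnings(as.integer(x))
      bad <- which(is.na(xn) | !(xn %in% c(0L, 1L)))
      if (length(bad))
        stop("validation error: field '", f, "' not 0/1 at row ", bad[1])
      df[[f]] <- xn
    } else { # factor with enumerated levels
      xc <- as.character(x)
      if (!is.null(aliases[[f]])) {
        hit <- xc %in% names(aliases[[f]])
        xc[hit] <- unname(aliases[[f]][xc[hit]])
      }
      bad <- which(!(xc %in% lv[[f]]))
      if (length(bad))
        stop("validation error: field '", f, "' has unknown level '",
             xc[bad[1]], "' at row ", bad[1])
      df[[f]] <- factor(xc, levels = lv[[f]])
    }
  }
  if (any(df$escalation_day < 0 | df$escalation_day > 30))
    stop("validation error: escalation_day outside [0, 30]")
  df
}

#' Read a cohort CSV
#'
#' Reads a one-row-per-dog cohort table (UTF-8, header required) and
#' validates it against the schema.
#'
#' @param path path to a CSV file.
#' @param raw logical; expect the pre-eligibility (raw presentation) columns.
#' @param aliases see [validate_cohort()].
#' @return Validated data frame.
#' @export
read_cohort <- function(path, raw = FALSE, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  validate_cohort(df, raw = raw, aliases = aliases)
}

#' Write a cohort CSV
#'
#' @param df validated cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the target-trial eligibility rules
#'
#' Retains dogs aged >= 3 months (0.25 years) and < 10 years with no
#' recorded diarrhoea in the preceding 30 days, no antimicrobial or
#' nutraceutical prescription in the preceding 30 days, none of the
#' excluding diagnoses, diarrhoea of at most 7 days' prior duration, and no
#' intravenous fluids, hospitalisation or death at first presentation.
#' Each excluded record is tallied once under the first failing rule, in
#' the fixed order documented below.
#'
#' @param records validated raw presentation records (see [read_cohort()]
#'   with `raw = TRUE`).
#' @return List with `cohort` (retained records, raw-only columns dropped)
#'   and `tally` (named integer vector per exclusion rule plus `retained`).
#' @export
apply_eligibility <- function(records) {
  rules <- list(
    age             = with(records, age_years < 0.25 | age_years >= 10),
    prior_diarrhoea = records$prior_diarrhoea_within_30d == 1L,
    prior_exposure  = records$prior_exposure_within_30d == 1L,
    excluded_diagnosis = records$excluded_diagnosis == 1L,
    duration        = records$duration_days_prior > 7,
    iv_fluids       = records$iv_fluids == 1L,
    hospitalised    = records$hospitalised == 1L,
    death           = records$died_at_presentation == 1L
  )
  assigned <- rep(NA_character_, nrow(records))
  for (r in names(rules)) {
    hit <- rules[[r]] & is.na(assigned)
    assigned[hit] <- r
  }
  tally <- vapply(names(rules), function(r) sum(assigned == r, na.rm = TRUE),
                  integer(1))
  keep <- is.na(assigned)
  cohort <- records[keep, names(.cohort_fields()), drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, tally = c(tally, retained = sum(keep)))
}

#' Per-level counts and percentages by exposure arm
#'
#' Tabulates every categorical and binary baseline covariate by arm of the
#' given exposure, with percentages within arm to one decimal place.
#'
#' @param cohort validated cohort data frame.
#' @param exposure `"antimicrobial"` or `"nutraceutical"`.
#' @return List with `n`, `n_exposed`, `n_unexposed`, `pct_exposed`
#'   (one-decimal percentage exposed) and `table`, a data frame with
#'   columns variable, level, count/pct per arm.
#' @export
summarize_cohort <- function(cohort, exposure = c("antimicrobial", "nutraceutical")) {
  exposure <- match.arg(exposure)
  n <- nrow(cohort)
  if (n == 0L)
    return(list(n = 0L, n_exposed = 0L, n_unexposed = 0L,
                pct_exposed = NA_real_, table = data.frame()))
  a <- cohort[[exposure]]
  n1 <- sum(a == 1L); n0 <- sum(a == 0L)
  vars <- setdiff(names(.cohort_fields()),
                  c("dog_id", "age_years", exposure,
                    "resolved_30d", "escalation_day", "escalated"))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.factor(x)) lvls <- levels(x) else { x <- factor(x, c(0, 1), c("No", "Yes")); lvls <- c("No", "Yes") }
    c1 <- table(x[a == 1L]); c0 <- table(x[a == 0L])
    data.frame(variable = v, level = lvls,
               count_exposed = as.integer(c1[lvls]),
               pct_exposed = round(100 * as.integer(c1[lvls]) / max(n1, 1L), 1),
               count_unexposed = as.integer(c0[lvls]),
               pct_unexposed = round(100 * as.integer(c0[lvls]) / max(n0, 1L), 1),
               stringsAsFactors = FALSE)
  })
  list(n = n, n_exposed = n1, n_unexposed = n0,
       pct_exposed = round(100 * n1 / n, 1),
       table = do.call(rbind, rows))
}
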