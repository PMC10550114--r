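# Treatment-assignment (propensity) modelling and stabilised
# inverse-probability-of-treatment weights.

#' Specify a propensity model
#'
#' @param exposure exposure field (`"antimicrobial"` or `"nutraceutical"`).
#' @param main_terms character vector of cohort fields entering as main
#'   effects.
#' @param quadratic_terms continuous fields whose square is appended.
#' @param interaction_terms list of length-2 character vectors (field pairs).
#' @return A `vetemulate_pspec` list.
#' @export
propensity_spec <- function(exposure, main_terms, quadratic_terms = character(),
                            interaction_terms = list()) {
  stopifnot(is.character(exposure), length(exposure) == 1L)
  for (pr in interaction_terms)
    if (length(pr) != 2L || pr[1] == pr[2])
      stop("interaction terms must be pairs of distinct fields")
  structure(list(exposure = exposure, main_terms = main_terms,
                 quadratic_terms = quadratic_terms,
                 interaction_terms = interaction_terms),
            class = c("vetemulate_pspec", "list"))
}

#' Default propensity model for each emulated trial
#'
#' The default covariate sets reproduce the final assignment models of the
#' source study: all baseline covariates and concurrent treatments, a
#' quadratic age term, and the trial-specific interactions (antimicrobial
#' trial: age x vomiting, haematochezia x pyrexia, nutraceutical x dietary
#' advice; nutraceutical trial: age x haematochezia).
#'
#' @param exposure `"antimicrobial"` or `"nutraceutical"`.
#' @return A `vetemulate_pspec`.
#' @export
default_propensity_spec <- function(exposure = c("antimicrobial", "nutraceutical")) {
  exposure <- match.arg(exposure)
  other <- setdiff(c("antimicrobial", "nutraceutical"), exposure)
  main <- c("age_years", "breed", "bodyweight_cat", "insured", "comorbidity",
            "vomiting", "reduced_appetite", "haematochezia", "pyrexia",
            "duration_cat", "vet_group", other, "diet_advice",
            "antiparasitic", "gi_agent")
  ints <- if (exposure == "antimicrobial")
    list(c("age_years", "vomiting"), c("haematochezia", "pyrexia"),
         c("nutraceutical", "diet_advice"))
  else list(c("age_years", "haematochezia"))
  propensity_spec(exposure, main, quadratic_terms = "age_years",
                  interaction_terms = ints)
}

# reference-coded column block for one field; reference level = most
# frequent level (coding not stated by the source study). "not recorded"
# levels become ordinary indicator columns: the missing-indicator method.
.encode_field <- function(cohort, f) {
  x <- cohort[[f]]
  if (is.null(x)) stop("unknown field in model spec: ", f)
  if (is.numeric(x) && !all(x %in% c(0, 1))) {
    m <- matrix(x, ncol = 1, dimnames = list(NULL, f))
    return(list(X = m, dropped = character()))
  }
  if (is.numeric(x)) {
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, f))
    return(list(X = m, dropped = character()))
  }
  if (!is.factor(x)) x <- factor(x)   # factor(x) on a factor would drop empty levels
  counts <- table(x)
  present <- names(counts)[counts > 0L]
  dropped <- setdiff(levels(x), present)
  ref <- present[which.max(counts[present])]
  others <- setdiff(present, ref)
  m <- matrix(0, nrow = length(x), ncol = length(others))
  if (length(others)) {
    colnames(m) <- paste0(f, "=", others)
    for (l in others) m[, paste0(f, "=", l)] <- as.numeric(x == l)
  }
  list(X = m, dropped = if (length(dropped)) paste0(f, "=", dropped) else character())
}

#' Build the propensity design matrix
#'
#' Expands categorical fields to reference-coded indicators (reference =
#' most frequent level; empty levels dropped with a warning), encodes
#' "not recorded" as its own indicator (missing-indicator method), and
#' appends quadratic and interaction columns (elementwise products of the
#' paired fields' column blocks).
#'
#' @param cohort validated cohort data frame.
#' @param spec a [propensity_spec()].
#' @return List with `X` (numeric matrix, no intercept column) and
#'   `dropped` (names of empty levels removed).
#' @export
encode_design <- function(cohort, spec) {
  blocks <- lapply(spec$main_terms, function(f) .encode_field(cohort, f))
  names(blocks) <- spec$main_terms
  dropped <- unlist(lapply(blocks, `[[`, "dropped"))
  if (length(dropped))
    warning("empty level(s) dropped from design: ",
            paste(dropped, collapse = ", "))
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  for (f in spec$quadratic_terms) {
    q <- matrix(cohort[[f]]^2, ncol = 1,
                dimnames = list(NULL, paste0(f, "^2")))
    X <- cbind(X, q)
  }
  for (pr in spec$interaction_terms) {
    b1 <- .encode_field(cohort, pr[1])$X
    b2 <- .encode_field(cohort, pr[2])$X
    for (i in seq_len(ncol(b1))) for (j in seq_len(ncol(b2))) {
      cl <- matrix(b1[, i] * b2[, j], ncol = 1,
                   dimnames = list(NULL, paste0(colnames(b1)[i], ":", colnames(b2)[j])))
      X <- cbind(X, cl)
    }
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  list(X = X, dropped = dropped)
}

#' Fit the propensity model and derive IPT weights
#'
#' Maximum-likelihood logistic regression of the exposure on the encoded
#' design. The stabilised weight replaces the unit numerator of the
#' unstabilised weight 1/e (exposed) or 1/(1-e) (unexposed) with the crude
#' exposure probability from the intercept-only model, i.e. the sample
#' prevalence.
#'
#' @param cohort validated cohort data frame.
#' @param spec a [propensity_spec()].
#' @return A `vetemulate_weights` object: propensity `e`, prevalence `p_A`,
#'   stabilised `sw` and unstabilised `w` weights, convergence flag,
#'   coefficient table, and the indices of records with `sw` outside
#'   [0.1, 10] (`extreme`).
#' @export
fit_propensity <- function(cohort, spec) {
  A <- cohort[[spec$exposure]]
  if (is.null(A)) stop("exposure field not in cohort: ", spec$exposure)
  if (!length(unique(A)) == 2L) stop("both exposure arms must be non-empty")
  enc <- encode_design(cohort, spec)
  X <- enc$X
  dat <- as.data.frame(X)
  orig <- colnames(X)
  names(dat) <- if (ncol(X)) paste0("x", seq_len(ncol(X))) else character()
  dat$.A <- A
  fit <- suppressWarnings(
    stats::glm(.A ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  e <- as.numeric(stats::fitted(fit))
  cf <- stats::coef(fit)
  separated <- any(e < 1e-8 | e > 1 - 1e-8) ||
    any(abs(cf[-1]) > 15, na.rm = TRUE) || anyNA(cf)
  converged <- isTRUE(fit$converged) && !separated
  bad_terms <- orig[which(abs(cf[-1]) > 15 | is.na(cf[-1]))]
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  p_A <- mean(A)
  sw <- ifelse(A == 1L, p_A / e, (1 - p_A) / (1 - e))
  w <- ifelse(A == 1L, 1 / e, 1 / (1 - e))
  structure(list(
    exposure = spec$exposure, spec = spec, e = e, p_A = p_A, sw = sw, w = w,
    converged = converged, problem_terms = bad_terms,
    coefficients = data.frame(term = c("(Intercept)", orig),
                              estimate = unname(cf), se = unname(se),
                              stringsAsFactors = FALSE),
    extreme = which(sw < 0.1 | sw > 10), n = length(A)),
    class = c("vetemulate_weights", "list"))
}

#' @export
print.vetemulate_weights <- function(x, ...) {
  cat("Stabilised IPT weights for exposure '", x$exposure, "'\n", sep = "")
  cat(sprintf("  n = %d, prevalence = %.3f, mean sw = %.3f, range sw = [%.3f, %.3f]\n",
              x$n, x$p_A, mean(x$sw), min(x$sw), max(x$sw)))
  cat("  converged:", x$converged,
      if (length(x$extreme)) paste0(" (", length(x$extreme), " extreme weight(s))"),
      "\n")
  invisible(x)
}

#' Balance-driven greedy interaction selection
#'
#' Walks the candidate pairs in the supplied order; a candidate is retained
#' if and only if adding it strictly reduces the maximum post-weighting
#' standardised mean difference across the adjustment covariates.
#' Candidates whose augmented model fails to converge are skipped.
#'
#' @param cohort validated cohort data frame.
#' @param base_spec starting [propensity_spec()].
#' @param candidates list of length-2 character vectors, in assessment order.
#' @param balance_fn function(cohort, weight_set) returning the scalar
#'   balance summary to minimise; defaults to the maximum weighted SMD over
#'   the spec's main terms.
#' @return List with `spec` (augmented spec) and `log` (per-candidate
#'   decision data frame).
#' @export
select_interactions <- function(cohort, base_spec, candidates,
                                balance_fn = NULL) {
  if (is.null(balance_fn))
    balance_fn <- function(cohort, ws) {
      bt <- balance_table(cohort, ws$exposure, ws,
                          covariates = setdiff(base_spec$main_terms, ws$exposure))
      max(bt$by_covariate$smd_weighted, na.rm = TRUE)
    }
  spec <- base_spec
  ws <- fit_propensity(cohort, spec)
  current <- balance_fn(cohort, ws)
  log <- list()
  for (pr in candidates) {
    cand_spec <- spec
    cand_spec$interaction_terms <- c(spec$interaction_terms, list(pr))
    ws_c <- tryCatch(fit_propensity(cohort, cand_spec), error = function(e) NULL)
    if (is.null(ws_c) || !ws_c$converged) {
      log[[length(log) + 1L]] <- data.frame(
        candidate = paste(pr, collapse = "*"), max_smd_before = current,
        max_smd_with = NA_real_, kept = FALSE, note = "non-convergence",
        stringsAsFactors = FALSE)
      next
    }
    val <- balance_fn(cohort, ws_c)
    kept <- is.finite(val) && val < current
    log[[length(log) + 1L]] <- data.frame(
      candidate = paste(pr, collapse = "*"), max_smd_before = current,
      max_smd_with = val, kept = kept, note = "",
      stringsAsFactors = FALSE)
    if (kept) { spec <- cand_spec; current <- val }
  }
  list(spec = spec,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(candidate = character(), max_smd_before = numeric(),
                    max_smd_with = numeric(), kept = logical(),
                    note = character(), stringsAsFactors = FALSE))
}
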