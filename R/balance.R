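# Covariate balance diagnostics: standardised mean differences between
# exposure arms, before and after IPT weighting.

#' Standardised mean difference between two arms
#'
#' |weighted mean1 - weighted mean0| / sqrt((v1 + v0) / 2), where for a
#' binary covariate the arm variance is p(1-p) and for a continuous
#' covariate the frequency-weighted variance sum(w (x - xbar_w)^2) / sum(w).
#' Equal means give 0 even under zero pooled variance; zero pooled variance
#' with unequal means gives `Inf` (degenerate contrast).
#'
#' @param x1,x0 covariate values in the exposed / unexposed arm.
#' @param w1,w0 positive weights (default all 1, the unweighted SMD).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
smd <- function(x1, x0, w1 = NULL, w0 = NULL) {
  if (!length(x1) || !length(x0)) stop("both arms must be non-empty")
  if (is.null(w1)) w1 <- rep(1, length(x1))
  if (is.null(w0)) w0 <- rep(1, length(x0))
  stopifnot(all(w1 > 0), all(w0 > 0))
  m1 <- sum(w1 * x1) / sum(w1)
  m0 <- sum(w0 * x0) / sum(w0)
  binary <- all(c(x1, x0) %in% c(0, 1))
  v1 <- if (binary) m1 * (1 - m1) else sum(w1 * (x1 - m1)^2) / sum(w1)
  v0 <- if (binary) m0 * (1 - m0) else sum(w0 * (x0 - m0)^2) / sum(w0)
  pooled <- (v1 + v0) / 2
  d <- abs(m1 - m0)
  if (d == 0) return(0)
  if (pooled == 0) return(Inf)
  d / sqrt(pooled)
}

#' Balance table before and after weighting
#'
#' One row per covariate level (multi-level categoricals expanded to level
#' indicators), with unweighted and weighted SMD, a balance flag at the 0.1
#' threshold, and a degeneracy flag for levels absent from an arm or with
#' a zero-variance contrast. The per-covariate summary is the maximum over
#' its levels (conservative).
#'
#' @param cohort validated cohort data frame.
#' @param exposure exposure field name.
#' @param weight_set optional `vetemulate_weights`; when absent the
#'   weighted column equals the unweighted column.
#' @param covariates covariate fields to assess; default is the full
#'   adjustment set (all baseline covariates and concurrent treatments
#'   other than the exposure).
#' @param threshold balance threshold on the weighted SMD (default 0.1).
#' @return A `vetemulate_balance` list: `table` (per-level rows),
#'   `by_covariate` (max per covariate), arm sizes and effective sample
#'   sizes (sum(sw)^2 / sum(sw^2)) per arm.
#' @export
balance_table <- function(cohort, exposure, weight_set = NULL,
                          covariates = NULL, threshold = 0.1) {
  if (is.null(covariates))
    covariates <- setdiff(
      c("age_years", "breed", "bodyweight_cat", "insured", "comorbidity",
        "vomiting", "reduced_appetite", "haematochezia", "pyrexia",
        "duration_cat", "vet_group", "antimicrobial", "nutraceutical",
        "diet_advice", "antiparasitic", "gi_agent"), exposure)
  a <- cohort[[exposure]]
  i1 <- a == 1L; i0 <- a == 0L
  sw <- if (is.null(weight_set)) rep(1, nrow(cohort)) else weight_set$sw
  rows <- list()
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.factor(x)) {
      for (l in levels(x)) {
        z <- as.numeric(x == l)
        degen <- sum(z[i1]) == 0 || sum(z[i0]) == 0
        su <- smd(z[i1], z[i0])
        sb <- smd(z[i1], z[i0], sw[i1], sw[i0])
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = v, level = l, smd_unweighted = su, smd_weighted = sb,
          balanced = is.finite(sb) && sb < threshold,
          degenerate = degen || !is.finite(sb) || !is.finite(su),
          stringsAsFactors = FALSE)
      }
    } else {
      su <- smd(x[i1], x[i0])
      sb <- smd(x[i1], x[i0], sw[i1], sw[i0])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = "", smd_unweighted = su, smd_weighted = sb,
        balanced = is.finite(sb) && sb < threshold,
        degenerate = !is.finite(sb) || !is.finite(su),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  byc <- stats::aggregate(cbind(smd_unweighted, smd_weighted) ~ covariate,
                          data = tab, FUN = max)
  byc$balanced <- is.finite(byc$smd_weighted) & byc$smd_weighted < threshold
  structure(list(
    table = tab, by_covariate = byc, threshold = threshold,
    n_exposed = sum(i1), n_unexposed = sum(i0),
    ess_exposed = sum(sw[i1])^2 / sum(sw[i1]^2),
    ess_unexposed = sum(sw[i0])^2 / sum(sw[i0]^2)),
    class = c("vetemulate_balance", "list"))
}

#' @export
print.vetemulate_balance <- function(x, ...) {
  cat(sprintf("Balance table: %d exposed / %d unexposed (ESS %.1f / %.1f)\n",
              x$n_exposed, x$n_unexposed, x$ess_exposed, x$ess_unexposed))
  cat(sprintf("  max weighted SMD = %.4f (threshold %.2f), %d/%d covariates balanced\n",
              max(x$by_covariate$smd_weighted), x$threshold,
              sum(x$by_covariate$balanced), nrow(x$by_covariate)))
  invisible(x)
}
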