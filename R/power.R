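# Equivalence-trial design: per-arm sample size for two proportions on the
# risk-difference scale, with dropout inflation, plus a Monte-Carlo TOST
# verification of the achieved power.

#' Specify an equivalence design
#'
#' @param p1,p2 anticipated resolution proportions per arm.
#' @param margin equivalence bound on the risk-difference scale.
#' @param alpha one-sided significance level of each TOST test.
#' @param power target power.
#' @param dropout anticipated attrition fraction.
#' @param allocation_ratio exposed:unexposed allocation (default 1).
#' @return A `vetemulate_eqdesign` list.
#' @export
equivalence_design <- function(p1 = 0.95, p2 = 0.95, margin = 0.1,
                               alpha = 0.05, power = 0.80, dropout = 0.25,
                               allocation_ratio = 1) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, alpha > 0, alpha < 1,
            power > 0, power < 1, dropout >= 0, dropout < 1,
            allocation_ratio > 0)
  if (margin <= abs(p1 - p2))
    stop("infeasible design: margin must exceed |p1 - p2|")
  structure(list(p1 = p1, p2 = p2, margin = margin, alpha = alpha,
                 power = power, dropout = dropout,
                 allocation_ratio = allocation_ratio),
            class = c("vetemulate_eqdesign", "list"))
}

#' Per-arm sample size for an equivalence trial
#'
#' Normal-approximation formula
#' n = (z_{1-alpha} + z_{power})^2 [p1(1-p1)/k + p2(1-p2)] / margin^2
#' with k the allocation ratio, rounded up, then inflated by 1/(1-dropout)
#' and rounded up again. The single z_{power} term (rather than the
#' z_{power/2}-style TOST correction) is the convention of the calculator
#' the source design used; it reproduces the published 79 per arm.
#'
#' @param design an [equivalence_design()].
#' @return Integer dogs per (larger) arm; for a 1:1 design, both arms.
#' @export
equivalence_n_per_arm <- function(design) {
  stopifnot(inherits(design, "vetemulate_eqdesign"))
  z <- stats::qnorm(1 - design$alpha) + stats::qnorm(design$power)
  k <- design$allocation_ratio
  core <- z^2 * (design$p1 * (1 - design$p1) / k +
                   design$p2 * (1 - design$p2)) / design$margin^2
  ceiling(ceiling(core) / (1 - design$dropout))
}

#' Monte-Carlo power of the two-one-sided-tests procedure
#'
#' Draws binomial outcomes per arm with a true risk difference `true_rd`
#' (arm 2 risk = p1 - true_rd) and declares equivalence when the Wald
#' (1 - 2 alpha) confidence interval for the risk difference lies entirely
#' within (-margin, margin).
#'
#' @param design an [equivalence_design()].
#' @param true_rd true risk difference between the arms.
#' @param n_per_arm analysed dogs per arm.
#' @param reps Monte-Carlo replicates (>= 1).
#' @param seed integer seed.
#' @return Empirical probability of declaring equivalence.
#' @export
simulate_power <- function(design, true_rd, n_per_arm, reps, seed = 1) {
  stopifnot(inherits(design, "vetemulate_eqdesign"), reps >= 1, n_per_arm >= 1)
  p1 <- design$p1
  p2 <- p1 - true_rd
  stopifnot(p2 > 0, p2 < 1)
  set.seed(seed)
  x1 <- stats::rbinom(reps, n_per_arm, p1)
  x2 <- stats::rbinom(reps, n_per_arm, p2)
  ph1 <- x1 / n_per_arm; ph2 <- x2 / n_per_arm
  d <- ph1 - ph2
  se <- sqrt(ph1 * (1 - ph1) / n_per_arm + ph2 * (1 - ph2) / n_per_arm)
  z <- stats::qnorm(1 - design$alpha)
  mean(d + z * se < design$margin & d - z * se > -design$margin)
}
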