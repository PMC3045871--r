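#' High-risk strategy: antihypertensive medication policy
#'
#' Bundles the parameters of the medication intervention. A person with SBP
#' `x` consults a physician with probability
#' \eqn{s(x) = 1 - \exp(-(x - a)\,b)} (clamped to \[0, 1\]); medication is
#' initiated at or above the threshold `e`, lowers SBP towards the target `c`
#' with adherence `d`, and half of the achieved decrease (the `contribution`
#' factor, reflecting how much of a blood-pressure drop converts into risk
#' reduction within a few years) is credited inside the risk function.
#'
#' @param a Alarming SBP in mm Hg, above which people become concerned about
#'   their blood pressure.
#' @param b Accessibility factor to a primary physician, per mm Hg; positive.
#' @param c Target SBP of treatment in mm Hg.
#' @param d Adherence for reaching the target, in \[0, 1\] (combines physician
#'   guideline compliance and patient drug adherence).
#' @param e SBP threshold at which medication is initiated, in mm Hg; must be
#'   at least `c`.
#' @param contribution Fraction of the SBP decrease credited to risk
#'   reduction, in (0, 1\]. Default 0.5.
#' @param label Optional scenario label (used in grids and output).
#' @return An object of class `medication_policy`.
#' @examples
#' pol <- medication_policy(a = 140, b = 0.03, c = 140, d = 0.7, e = 150)
#' consultation_rate(160, pol)  # 0.45
#' @export
medication_policy <- function(a, b, c, d, e, contribution = 0.5,
                              label = NULL) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    v
  }
  a <- num1(a, "a"); b <- num1(b, "b"); c <- num1(c, "c")
  d <- num1(d, "d"); e <- num1(e, "e")
  contribution <- num1(contribution, "contribution")
  if (b <= 0) stop("accessibility `b` must be positive", call. = FALSE)
  if (d < 0 || d > 1) stop("adherence `d` must lie in [0, 1]", call. = FALSE)
  if (contribution <= 0 || contribution > 1)
    stop("`contribution` must lie in (0, 1]", call. = FALSE)
  if (e < c)
    stop("initiation threshold `e` must be at least the target `c`",
         call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, e = e,
                 contribution = contribution, label = label),
            class = "medication_policy")
}

#' @export
print.medication_policy <- function(x, ...) {
  cat(sprintf(paste0("Medication policy%s: a = %g, b = %g, c = %g, d = %g, ",
                     "e = %g, contribution = %g\n"),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$a, x$b, x$c, x$d, x$e, x$contribution))
  invisible(x)
}

#' Physician consultation rate after a health check
#'
#' Probability that a person diagnosed with hypertension at the annual health
#' check visits a primary physician, as a function of SBP:
#' \eqn{s(x) = 1 - \exp(-(x - a)\,b)}, clamped to 0 below the alarming level
#' `a` (where the raw formula would go negative). The rate approaches 1 as
#' SBP rises.
#'
#' @param x SBP in mm Hg (vectorised).
#' @param policy A [medication_policy()].
#' @return Consultation probability in \[0, 1\].
#' @export
consultation_rate <- function(x, policy) {
  stopifnot(inherits(policy, "medication_policy"))
  pmax(0, 1 - exp(-(x - policy$a) * policy$b))
}

#' Density of physician consultations over SBP
#'
#' The product of the population SBP density and the consultation rate: the
#' per-mm-Hg density of people who consult a physician after the health
#' check.
#'
#' @param x SBP in mm Hg (vectorised).
#' @param dist An [sbp_distribution()].
#' @param policy A [medication_policy()].
#' @return Density per mm Hg.
#' @export
consultation_probability_density <- function(x, dist, policy) {
  sbp_density(x, dist) * consultation_rate(x, policy)
}

#' Risk-credited SBP reduction under treatment
#'
#' The effective SBP decrease credited inside the risk function for a treated
#' person: \eqn{(x - c)\,d \times \mathrm{contribution}} above the target
#' `c`, and 0 below it. A treated SBP therefore never falls below the target.
#'
#' @inheritParams consultation_rate
#' @return Effective reduction in mm Hg.
#' @examples
#' pol <- medication_policy(140, 0.03, 140, 0.7, 150)
#' sbp_lowering_effect(160, pol)  # (160 - 140) * 0.7 * 0.5 = 7
#' @export
sbp_lowering_effect <- function(x, policy) {
  stopifnot(inherits(policy, "medication_policy"))
  pmax(0, x - policy$c) * policy$d * policy$contribution
}

#' Post-treatment incidence rate for one individual
#'
#' Incidence rate of a treated person with pre-treatment SBP `x`: the risk
#' function evaluated at `x` minus the risk-credited reduction. Only defined
#' at or above the initiation threshold `e`.
#'
#' @param x SBP in mm Hg (vectorised); every value must be `>= e`.
#' @param risk A [risk_model()].
#' @param policy A [medication_policy()].
#' @return Incidence rate in events/year, never exceeding the untreated rate.
#' @export
treated_individual_ir <- function(x, risk, policy) {
  stopifnot(inherits(policy, "medication_policy"))
  if (any(x < policy$e))
    stop(sprintf("treated_individual_ir applies at or above e = %g mm Hg",
                 policy$e), call. = FALSE)
  risk_at(x - sbp_lowering_effect(x, policy), risk)
}

# Nodes of `grid` restricted to [from, grid$upper]; `from` must sit on the
# grid so the integral splits cleanly at the initiation threshold.
subgrid_from <- function(grid, from) {
  off <- (from - grid$lower) / grid$step
  if (from < grid$lower || from > grid$upper || abs(off - round(off)) > 1e-8)
    stop(sprintf(paste0("initiation threshold %g mm Hg must lie on the ",
                        "integration grid [%g, %g] (step %g)"),
                 from, grid$lower, grid$upper, grid$step), call. = FALSE)
  n <- round((grid$upper - from) / grid$step)
  from + grid$step * (0:n)
}

#' Population incidence rate after antihypertensive medication
#'
#' Evaluates the three-term post-medication integral: below the initiation
#' threshold `e` the population is untouched; above it, the consulting
#' fraction \eqn{s(x)} carries the treated risk \eqn{P(x - g(x))} (with
#' \eqn{g} the risk-credited lowering) and the non-consulting fraction
#' \eqn{1 - s(x)} keeps its baseline risk:
#' \deqn{\int_L^e f P\,dx + \int_e^H f\,P(x - g(x))\,s(x)\,dx +
#'       \int_e^H f P (1 - s(x))\,dx.}
#' The result never exceeds the baseline [cumulative_ir()], with equality
#' when nobody consults or adherence is zero.
#'
#' @inheritParams cumulative_ir
#' @param policy A [medication_policy()]; its threshold `e` must lie on the
#'   grid.
#' @return Post-intervention cumulative incidence rate in events/year.
#' @export
post_medication_ir <- function(dist, risk, policy, grid = default_grid(dist),
                               rule = "trapezoid") {
  stopifnot(inherits(dist, "sbp_distribution"), inherits(risk, "risk_model"),
            inherits(policy, "medication_policy"),
            inherits(grid, "integration_grid"))
  xt <- subgrid_from(grid, policy$e)
  f <- sbp_density(xt, dist)
  s <- consultation_rate(xt, policy)
  g <- sbp_lowering_effect(xt, policy)
  # baseline minus the treated-region improvement: algebraically identical to
  # the three-term sum, but keeps the smooth baseline integral on one grid
  reduction <- quad_sum(xt, f * s * (risk_at(xt, risk) -
                                       risk_at(xt - g, risk)), rule = rule)
  cumulative_ir(dist, risk, grid, rule = rule) - reduction
}
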