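#' Stratified success-rate table of a health-promotion campaign
#'
#' The promotion program reaches the population through stratified support
#' systems (an affirmative campaign with repeated nurse contacts, a motivating
#' campaign, information-only mailing, and an indifferent remainder). Each
#' stratum holds a share of the population and a per-stratum success rate;
#' their share-weighted sum is the program-wide success fraction beta.
#'
#' @param shares Population shares per stratum (fractions summing to 1).
#' @param rates Success rate per stratum, each in \[0, 1\].
#' @param labels Optional stratum labels; defaults to the four campaign
#'   strata when four values are supplied.
#' @return An object of class `success_rate_table`.
#' @examples
#' tab <- success_rate_table(c(0.10, 0.20, 0.50, 0.20),
#'                           c(0.375, 0.25, 0.10, 0))
#' aggregate_success_rate(tab)  # 0.1375
#' @export
success_rate_table <- function(shares, rates, labels = NULL) {
  if (length(shares) != length(rates))
    stop("`shares` and `rates` must have the same length", call. = FALSE)
  if (!is.numeric(shares) || any(!is.finite(shares)) || any(shares < 0))
    stop("`shares` must be non-negative numbers", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-12)
    stop("population `shares` must sum to 1", call. = FALSE)
  if (!is.numeric(rates) || any(!is.finite(rates)) ||
      any(rates < 0 | rates > 1))
    stop("every success rate must lie in [0, 1]", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (length(shares) == 4L)
      c("affirmative", "motivating", "information", "indifferent")
    else paste0("stratum", seq_along(shares))
  }
  structure(list(labels = as.character(labels), shares = as.numeric(shares),
                 rates = as.numeric(rates)),
            class = "success_rate_table")
}

#' @export
print.success_rate_table <- function(x, ...) {
  cat("Success-rate table (shares and rates in %):\n")
  m <- rbind(share = 100 * x$shares, success = 100 * x$rates)
  colnames(m) <- x$labels
  print(m)
  cat(sprintf("aggregate beta = %.4g%%\n",
              100 * aggregate_success_rate(x)))
  invisible(x)
}

#' Aggregate success fraction of a campaign table
#'
#' Share-weighted mean of the per-stratum success rates; this is the beta
#' entering [promotion_policy()]. The realistic, optimistic and ideal
#' campaign patterns aggregate to 13.75%, 27.5% and 50%.
#'
#' @param table A [success_rate_table()].
#' @return The aggregate success fraction in \[0, 1\].
#' @export
aggregate_success_rate <- function(table) {
  stopifnot(inherits(table, "success_rate_table"))
  sum(table$shares * table$rates)
}

#' The three canonical campaign patterns
#'
#' Convenience constructor for the realistic, optimistic and ideal
#' success-rate tables (shares 10/20/50/20%, per-stratum rates as published
#' for each pattern).
#'
#' @param pattern One of `"realistic"`, `"optimistic"`, `"ideal"`.
#' @return A [success_rate_table()].
#' @export
campaign_pattern <- function(pattern = c("realistic", "optimistic", "ideal")) {
  pattern <- match.arg(pattern)
  rates <- switch(pattern,
                  realistic  = c(0.375, 0.25, 0.10, 0),
                  optimistic = c(0.75, 0.50, 0.20, 0),
                  ideal      = c(1.00, 0.75, 0.50, 0))
  success_rate_table(c(0.10, 0.20, 0.50, 0.20), rates)
}

#' Population strategy: health-promotion policy
#'
#' The promotion program is modelled as a uniform SBP-lowering effect `alpha`
#' achieved by the successful fraction `beta` of the population; as for
#' medication, only the `contribution` share (default 50%) of the achieved
#' decrease is credited inside the risk function. `beta` may be given
#' directly or aggregated from a [success_rate_table()].
#'
#' @param alpha SBP-lowering effect in mm Hg; non-negative.
#' @param beta Success fraction in \[0, 1\]; ignored if `table` is supplied.
#' @param table Optional [success_rate_table()] from which beta is
#'   aggregated.
#' @param contribution Fraction of the SBP decrease credited to risk
#'   reduction, in (0, 1\]. Default 0.5.
#' @param label Optional scenario label.
#' @return An object of class `promotion_policy`.
#' @examples
#' promotion_policy(alpha = 10, table = campaign_pattern("optimistic"))
#' @export
promotion_policy <- function(alpha, beta = NULL, table = NULL,
                             contribution = 0.5, label = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  if (!is.null(table)) {
    beta <- aggregate_success_rate(table)
  }
  if (is.null(beta) || !is.numeric(beta) || length(beta) != 1L ||
      !is.finite(beta) || beta < 0 || beta > 1)
    stop("`beta` must be a single fraction in [0, 1] (or supply `table`)",
         call. = FALSE)
  if (!is.numeric(contribution) || length(contribution) != 1L ||
      contribution <= 0 || contribution > 1)
    stop("`contribution` must lie in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, contribution = contribution,
                 table = table, label = label),
            class = "promotion_policy")
}

#' @export
print.promotion_policy <- function(x, ...) {
  cat(sprintf(paste0("Promotion policy%s: alpha = %g mm Hg, beta = %g, ",
                     "contribution = %g\n"),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$alpha, x$beta, x$contribution))
  invisible(x)
}

#' Population incidence rate after health promotion
#'
#' Evaluates the two-term mixture integral: the successful fraction beta
#' carries the risk at an SBP shifted down by `alpha * contribution`, the
#' remainder keeps its baseline risk:
#' \deqn{\beta \int f\,P(x - \alpha\,\mathrm{contribution})\,dx +
#'       (1 - \beta) \int f P\,dx.}
#' Equals the baseline when `alpha = 0` or `beta = 0` and never exceeds it.
#'
#' @inheritParams cumulative_ir
#' @param policy A [promotion_policy()].
#' @return Post-intervention cumulative incidence rate in events/year.
#' @export
post_promotion_ir <- function(dist, risk, policy, grid = default_grid(dist),
                              rule = "trapezoid") {
  stopifnot(inherits(dist, "sbp_distribution"), inherits(risk, "risk_model"),
            inherits(policy, "promotion_policy"),
            inherits(grid, "integration_grid"))
  shift <- policy$alpha * policy$contribution
  base <- cumulative_ir(dist, risk, grid, rule = rule)
  shifted <- quad_fun(function(x)
    sbp_density(x, dist) * risk_at(x - shift, risk), grid, rule = rule)
  policy$beta * shifted + (1 - policy$beta) * base
}

#' Closed-form post-promotion incidence rate
#'
#' A constant downward SBP shift of an exponential risk rescales it by
#' \eqn{\exp(-\alpha\,\mathrm{contribution}/k)}, so over the untruncated
#' real line the post-promotion rate is
#' \eqn{C\,(1 - \beta\,(1 - e^{-\alpha\,\mathrm{contribution}/k}))} with
#' \eqn{C} the closed-form baseline. Serves as the analytic oracle for
#' [post_promotion_ir()].
#'
#' @inheritParams post_promotion_ir
#' @return Post-intervention cumulative incidence rate in events/year.
#' @export
post_promotion_ir_closed_form <- function(dist, risk, policy) {
  stopifnot(inherits(policy, "promotion_policy"))
  C <- cumulative_ir_closed_form(dist, risk)
  shift <- policy$alpha * policy$contribution
  C * (1 - policy$beta * (1 - exp(-shift / risk$k)))
}

#' Write a success-rate table as CSV
#'
#' Mirrors the published layout: one row of population shares, one row of
#' per-stratum success rates (both in percent) and an aggregate column.
#'
#' @param table A [success_rate_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_success_table <- function(table, path) {
  stopifnot(inherits(table, "success_rate_table"))
  df <- data.frame(row = c("share_pct", "success_pct"),
                   stats::setNames(as.data.frame(rbind(100 * table$shares,
                                                       100 * table$rates)),
                                   table$labels),
                   aggregate_pct = c(100, 100 * aggregate_success_rate(table)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
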