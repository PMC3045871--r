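#' Incidence-rate reduction of an intervention
#'
#' The difference between the baseline and post-intervention cumulative
#' incidence rates. A negative difference means the supplied policy raises
#' population risk, which no valid policy in this model can do, so it is
#' signalled as an error rather than returned.
#'
#' @param baseline Baseline cumulative incidence rate, events/year.
#' @param post Post-intervention cumulative incidence rate, events/year.
#' @return The reduction in events/year (non-negative).
#' @export
delta_ir <- function(baseline, post) {
  stopifnot(is.numeric(baseline), is.numeric(post),
            all(baseline >= 0), all(post >= 0))
  d <- baseline - post
  if (any(d < -1e-12 * pmax(baseline, 1e-300)))
    stop("post-intervention incidence exceeds baseline: invalid policy",
         call. = FALSE)
  pmax(d, 0)
}

#' Number of health checks needed to prevent one event per year
#'
#' The reciprocal of the incidence-rate reduction: how many people must take
#' the annual health check for the intervention to avert one cardiovascular
#' event per year. Undefined (infinite) when the reduction is zero.
#'
#' @param delta Incidence-rate reduction in events/year.
#' @return Health checks per event prevented per year; `Inf` when
#'   `delta <= 0`. The value is unrounded; see [format_n_hc()] for display.
#' @export
n_hc <- function(delta) {
  stopifnot(is.numeric(delta))
  ifelse(delta > 0, 1 / delta, Inf)
}

#' Display rounding for N_HC
#'
#' Rounds half-up to the nearest whole number of health checks; infinite
#' values print as `"undefined"`.
#'
#' @param x Value(s) from [n_hc()].
#' @return Character vector.
#' @export
format_n_hc <- function(x) {
  ifelse(is.finite(x), as.character(floor(x + 0.5)), "undefined")
}

#' Pointwise pre/post expected event-rate curves
#'
#' Samples, at every grid node, the expected event-rate density before the
#' intervention (`pre = f(x) P(x)`) and after it (`post` = the integrand of
#' the corresponding post-intervention integral). For a medication policy the
#' post curve jumps at the initiation threshold `e`; the node at `e` is
#' therefore duplicated, carrying the left (untreated) and right (treated)
#' limits, so that trapezoidal integration of `gap = pre - post` over the
#' returned abscissae reproduces the cumulative reduction to machine
#' precision.
#'
#' @inheritParams cumulative_ir
#' @param policy A [medication_policy()] or [promotion_policy()].
#' @return A data frame with columns `x`, `pre`, `post`, `gap` (all densities
#'   per mm Hg).
#' @seealso [curve_gap_area()]
#' @export
pointwise_risk_curves <- function(dist, risk, policy,
                                  grid = default_grid(dist)) {
  stopifnot(inherits(dist, "sbp_distribution"), inherits(risk, "risk_model"),
            inherits(grid, "integration_grid"))
  if (inherits(policy, "medication_policy")) {
    xl <- grid_points(integration_grid(grid$lower, policy$e, grid$step))
    xr <- subgrid_from(grid, policy$e)
    x <- c(xl, xr)
    f <- sbp_density(x, dist)
    pre <- f * risk_at(x, risk)
    s <- consultation_rate(xr, policy)
    g <- sbp_lowering_effect(xr, policy)
    post_r <- sbp_density(xr, dist) *
      (risk_at(xr - g, risk) * s + risk_at(xr, risk) * (1 - s))
    post <- c(pre[seq_along(xl)], post_r)
  } else if (inherits(policy, "promotion_policy")) {
    x <- grid_points(grid)
    f <- sbp_density(x, dist)
    pre <- f * risk_at(x, risk)
    shift <- policy$alpha * policy$contribution
    post <- policy$beta * f * risk_at(x - shift, risk) +
      (1 - policy$beta) * pre
  } else {
    stop("`policy` must be a medication_policy or promotion_policy",
         call. = FALSE)
  }
  data.frame(x = x, pre = pre, post = post, gap = pre - post)
}

#' Area between the pre and post curves
#'
#' Trapezoidal integral of the pointwise gap returned by
#' [pointwise_risk_curves()]; equals the intervention's incidence-rate
#' reduction up to quadrature consistency.
#'
#' @param curves Data frame from [pointwise_risk_curves()].
#' @return Events/year.
#' @export
curve_gap_area <- function(curves) {
  stopifnot(is.data.frame(curves), all(c("x", "gap") %in% names(curves)))
  sum(diff(curves$x) *
        (utils::head(curves$gap, -1) + utils::tail(curves$gap, -1)) / 2)
}

#' Evaluate one intervention scenario end to end
#'
#' Computes the baseline and post-intervention cumulative incidence rates,
#' their difference, the number of health checks per event prevented, and
#' the pointwise pre/post curves for a single policy.
#'
#' @inheritParams pointwise_risk_curves
#' @param scenario_id Optional label carried into printed and written output;
#'   defaults to the policy's own label.
#' @param rule Quadrature rule passed to the integrators.
#' @return An object of class `intervention_outcome` with fields
#'   `baseline_ir`, `post_ir`, `delta_ir`, `n_hc`, `scenario_id`, `curves`.
#' @examples
#' pol <- medication_policy(140, 0.03, 140, 0.7, 150, label = "optimistic")
#' out <- intervention_outcome(sbp_distribution(), risk_model(), pol)
#' out$delta_ir
#' @export
intervention_outcome <- function(dist, risk, policy,
                                 grid = default_grid(dist),
                                 scenario_id = NULL, rule = "trapezoid") {
  base <- cumulative_ir(dist, risk, grid, rule = rule)
  post <- if (inherits(policy, "medication_policy"))
    post_medication_ir(dist, risk, policy, grid, rule = rule)
  else if (inherits(policy, "promotion_policy"))
    post_promotion_ir(dist, risk, policy, grid, rule = rule)
  else stop("`policy` must be a medication_policy or promotion_policy",
            call. = FALSE)
  d <- delta_ir(base, post)
  structure(list(baseline_ir = base, post_ir = post, delta_ir = d,
                 n_hc = n_hc(d),
                 scenario_id = scenario_id %||% policy$label,
                 policy = policy,
                 curves = pointwise_risk_curves(dist, risk, policy, grid)),
            class = "intervention_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.intervention_outcome <- function(x, ...) {
  cat(sprintf("Intervention outcome%s\n",
              if (is.null(x$scenario_id)) "" else
                paste0(" [", x$scenario_id, "]")))
  cat(sprintf("  baseline IR: %s events/year\n", signif(x$baseline_ir, 3)))
  cat(sprintf("  post IR:     %s events/year\n", signif(x$post_ir, 3)))
  cat(sprintf("  delta IR:    %s events/year\n", signif(x$delta_ir, 3)))
  cat(sprintf("  N_HC:        %s health checks\n", format_n_hc(x$n_hc)))
  invisible(x)
}

#' The four published medication scenario columns
#'
#' The (a, b, c, d) parameter columns of the medication grid, varied jointly
#' per scenario: ideal (130, 0.05, 130, 0.8), optimistic (140, 0.03, 140,
#' 0.7), realistic (150, 0.02, 150, 0.6) and minimal (160, 0.01, 160, 0.5).
#' The initiation threshold `e` is supplied per grid row.
#'
#' @return A list of parameter lists with elements `a`, `b`, `c`, `d`,
#'   `label`.
#' @export
medication_columns <- function() {
  list(list(a = 130, b = 0.05, c = 130, d = 0.8, label = "ideal"),
       list(a = 140, b = 0.03, c = 140, d = 0.7, label = "optimistic"),
       list(a = 150, b = 0.02, c = 150, d = 0.6, label = "realistic"),
       list(a = 160, b = 0.01, c = 160, d = 0.5, label = "minimal"))
}

#' The three published promotion success fractions
#'
#' Aggregates of the ideal, optimistic and realistic campaign patterns
#' (0.5, 0.275, 0.1375).
#'
#' @return A named numeric vector.
#' @export
promotion_betas <- function() {
  c(ideal = aggregate_success_rate(campaign_pattern("ideal")),
    optimistic = aggregate_success_rate(campaign_pattern("optimistic")),
    realistic = aggregate_success_rate(campaign_pattern("realistic")))
}

#' Medication scenario grid
#'
#' Runs the medication intervention over every combination of risk slope
#' `k`, scenario column and initiation threshold `e`, returning the
#' incidence-rate reduction per cell. Combinations in which the threshold
#' sits less than 10 mm Hg above the column's alarming level are absent in
#' the published layout and are reported as missing (`NA`), not zero.
#'
#' @inheritParams cumulative_ir
#' @param risk_models A list of [risk_model()]s (one block per model) or a
#'   numeric vector of `k` values (with `l = 100`, `m = 140`).
#' @param policy_columns Scenario columns as returned by
#'   [medication_columns()].
#' @param e_rows Initiation thresholds in mm Hg, one grid row each.
#' @param contribution Contribution factor applied in every cell.
#' @return An object of class `scenario_grid` (type `"medication"`): a 3-d
#'   cell array `[k-block, e-row, column]` of reductions in events/year.
#' @export
run_medication_grid <- function(dist = sbp_distribution(),
                                risk_models = c(20, 30, 40),
                                policy_columns = medication_columns(),
                                e_rows = c(140, 150, 160, 180),
                                grid = default_grid(dist),
                                contribution = 0.5) {
  risk_models <- as_risk_models(risk_models)
  kv <- vapply(risk_models, function(r) r$k, numeric(1))
  col_labels <- vapply(policy_columns, function(p)
    p$label %||% sprintf("a=%g", p$a), character(1))
  cells <- array(NA_real_,
                 dim = c(length(risk_models), length(e_rows),
                         length(policy_columns)),
                 dimnames = list(paste0("k=", kv), paste0("e=", e_rows),
                                 col_labels))
  for (i in seq_along(risk_models))
    for (j in seq_along(e_rows))
      for (h in seq_along(policy_columns)) {
        p <- policy_columns[[h]]
        if (e_rows[j] < p$a + 10) next  # absent in the published layout
        pol <- medication_policy(p$a, p$b, p$c, p$d, e_rows[j],
                                 contribution = contribution,
                                 label = p$label)
        base <- cumulative_ir(dist, risk_models[[i]], grid)
        post <- post_medication_ir(dist, risk_models[[i]], pol, grid)
        cells[i, j, h] <- delta_ir(base, post)
      }
  structure(list(type = "medication", cells = cells, k = kv,
                 rows = e_rows, columns = policy_columns,
                 row_name = "e", col_labels = col_labels),
            class = "scenario_grid")
}

#' Promotion scenario grid
#'
#' Runs the health-promotion intervention over every combination of risk
#' slope `k`, SBP-lowering effect `alpha` (columns) and success fraction
#' `beta` (rows), returning the incidence-rate reduction per cell. Within a
#' column the cells are exactly proportional to beta.
#'
#' @inheritParams run_medication_grid
#' @param alphas SBP-lowering effects in mm Hg, one column each.
#' @param betas Named vector of success fractions, one row each.
#' @return An object of class `scenario_grid` (type `"promotion"`): a 3-d
#'   cell array `[k-block, beta-row, alpha-column]`.
#' @export
run_promotion_grid <- function(dist = sbp_distribution(),
                               risk_models = c(20, 30, 40),
                               alphas = c(20, 10, 5),
                               betas = promotion_betas(),
                               grid = default_grid(dist),
                               contribution = 0.5) {
  risk_models <- as_risk_models(risk_models)
  kv <- vapply(risk_models, function(r) r$k, numeric(1))
  row_labels <- if (is.null(names(betas))) paste0("beta=", betas)
                else names(betas)
  cells <- array(NA_real_,
                 dim = c(length(risk_models), length(betas), length(alphas)),
                 dimnames = list(paste0("k=", kv), row_labels,
                                 paste0("alpha=", alphas)))
  for (i in seq_along(risk_models)) {
    base <- cumulative_ir(dist, risk_models[[i]], grid)
    for (j in seq_along(betas))
      for (h in seq_along(alphas)) {
        pol <- promotion_policy(alphas[h], beta = unname(betas[j]),
                                contribution = contribution,
                                label = row_labels[j])
        post <- post_promotion_ir(dist, risk_models[[i]], pol, grid)
        cells[i, j, h] <- delta_ir(base, post)
      }
  }
  structure(list(type = "promotion", cells = cells, k = kv,
                 rows = betas, columns = as.list(alphas),
                 row_name = "beta", col_labels = paste0("alpha=", alphas)),
            class = "scenario_grid")
}

as_risk_models <- function(risk_models) {
  if (is.numeric(risk_models))
    risk_models <- lapply(risk_models, function(k) risk_model(k = k))
  if (inherits(risk_models, "risk_model")) risk_models <- list(risk_models)
  stopifnot(all(vapply(risk_models, inherits, logical(1), "risk_model")))
  risk_models
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("%s scenario grid (reduction in events/year)\n",
              sub("^(.)", "\\U\\1", x$type, perl = TRUE)))
  for (i in seq_along(x$k)) {
    cat(sprintf("\nk = %g\n", x$k[i]))
    m <- x$cells[i, , , drop = FALSE]
    dim(m) <- dim(x$cells)[2:3]
    dimnames(m) <- dimnames(x$cells)[2:3]
    print(apply(m, c(1, 2), function(v)
      if (is.na(v)) "" else formatC(v, format = "e", digits = 2)),
      quote = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) {
  dn <- dimnames(x$cells)
  out <- expand.grid(k = x$k, row = dn[[2]], column = dn[[3]],
                     stringsAsFactors = FALSE)
  out$delta_ir <- as.vector(x$cells)
  out
}

#' Compare the high-risk and population strategies
#'
#' Given one medication outcome and one promotion outcome computed on the
#' same baseline, reports the ratio of their incidence-rate reductions, the
#' corresponding ratio of health-check numbers, and which strategy prevents
#' more events.
#'
#' @param med An [intervention_outcome()] for a medication policy.
#' @param promo An [intervention_outcome()] for a promotion policy.
#' @return An object of class `strategy_comparison` with fields
#'   `delta_ratio` (medication/promotion), `nhc_ratio`
#'   (promotion/medication) and `winner`.
#' @export
compare_strategies <- function(med, promo) {
  stopifnot(inherits(med, "intervention_outcome"),
            inherits(promo, "intervention_outcome"))
  if (abs(med$baseline_ir - promo$baseline_ir) >
      1e-9 * max(med$baseline_ir, promo$baseline_ir))
    stop("outcomes were not computed on the same baseline", call. = FALSE)
  if (med$delta_ir <= 0 || promo$delta_ir <= 0)
    stop("comparison undefined: an intervention has no effect",
         call. = FALSE)
  ratio <- med$delta_ir / promo$delta_ir
  winner <- if (ratio > 1) "medication" else if (ratio < 1) "promotion"
            else "tie"
  structure(list(delta_ratio = ratio,
                 nhc_ratio = promo$n_hc / med$n_hc,
                 winner = winner, med = med, promo = promo),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Strategy comparison\n")
  cat(sprintf("  medication delta IR: %s events/year (N_HC %s)\n",
              signif(x$med$delta_ir, 3), format_n_hc(x$med$n_hc)))
  cat(sprintf("  promotion  delta IR: %s events/year (N_HC %s)\n",
              signif(x$promo$delta_ir, 3), format_n_hc(x$promo$n_hc)))
  cat(sprintf("  delta ratio (med/promo): %s\n", signif(x$delta_ratio, 3)))
  cat(sprintf("  winner: %s\n", x$winner))
  invisible(x)
}
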