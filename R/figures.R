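utils::globalVariables(c("x", "value", "series", "panel"))

theme_sim <- function() {
  ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(legend.position = "bottom")
}

fig_risk_curves <- function(risks, xlim = c(90, 200)) {
  xs <- seq(xlim[1], xlim[2], by = 0.5)
  df <- do.call(rbind, lapply(risks, function(r)
    data.frame(x = xs, value = risk_at(xs, r),
               series = sprintf("k = %g", r$k))))
  ggplot2::ggplot(df, ggplot2::aes(x, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "SBP (mm Hg)", y = "IR_CVD (events/year)",
                  colour = NULL,
                  title = "SBP and cardiovascular event rate") +
    theme_sim()
}

fig_consultation <- function(dist, xlim = c(90, 200)) {
  xs <- seq(xlim[1], xlim[2], by = 0.5)
  situations <- list(list(a = 130, b = 0.05, lab = "ideal (a=130, b=0.05)"),
                     list(a = 140, b = 0.03,
                          lab = "optimistic (a=140, b=0.03)"),
                     list(a = 150, b = 0.02,
                          lab = "realistic (a=150, b=0.02)"))
  df <- do.call(rbind, lapply(situations, function(s) {
    pol <- medication_policy(s$a, s$b, s$a, 0.7, s$a + 10)
    rbind(data.frame(x = xs, value = consultation_rate(xs, pol),
                     series = s$lab, panel = "consultation rate"),
          data.frame(x = xs,
                     value = consultation_probability_density(xs, dist, pol),
                     series = s$lab,
                     panel = "consultation probability density"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~panel, nrow = 2, scales = "free_y") +
    ggplot2::labs(x = "SBP (mm Hg)", y = NULL, colour = NULL,
                  title = "SBP and physician consultation") +
    theme_sim()
}

fig_medication_curves <- function(dist, risk, grid) {
  scenarios <- list(list(col = 1, e = 140, lab = "ideal (e = 140)"),
                    list(col = 2, e = 150, lab = "optimistic (e = 150)"),
                    list(col = 3, e = 160, lab = "realistic (e = 160)"))
  cols <- medication_columns()
  base <- pointwise_risk_curves(
    dist, risk, promotion_policy(0, beta = 0), grid)
  df <- data.frame(x = base$x, value = base$pre, series = "no treatment")
  for (s in scenarios) {
    p <- cols[[s$col]]
    pol <- medication_policy(p$a, p$b, p$c, p$d, s$e)
    cur <- pointwise_risk_curves(dist, risk, pol, grid)
    df <- rbind(df, data.frame(x = cur$x, value = cur$post, series = s$lab))
  }
  ggplot2::ggplot(df, ggplot2::aes(x, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(90, 220)) +
    ggplot2::labs(x = "SBP (mm Hg)",
                  y = "expected event density (per mm Hg per year)",
                  colour = NULL,
                  title = "Event rate before and after medication") +
    theme_sim()
}

fig_promotion_curves <- function(dist, risk, grid) {
  scenarios <- list(
    list(alpha = 5, beta = "realistic", lab = "realistic (alpha = 5)"),
    list(alpha = 10, beta = "optimistic", lab = "optimistic (alpha = 10)"),
    list(alpha = 20, beta = "ideal", lab = "ideal (alpha = 20)"))
  betas <- promotion_betas()
  base <- pointwise_risk_curves(dist, risk, promotion_policy(0, beta = 0),
                                grid)
  df <- data.frame(x = base$x, value = base$pre, series = "no promotion")
  for (s in scenarios) {
    pol <- promotion_policy(s$alpha, beta = unname(betas[s$beta]))
    cur <- pointwise_risk_curves(dist, risk, pol, grid)
    df <- rbind(df, data.frame(x = cur$x, value = cur$post, series = s$lab))
  }
  ggplot2::ggplot(df, ggplot2::aes(x, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(90, 220)) +
    ggplot2::labs(x = "SBP (mm Hg)",
                  y = "expected event density (per mm Hg per year)",
                  colour = NULL,
                  title = "Event rate before and after health promotion") +
    theme_sim()
}

#' Render the model's standard figures
#'
#' Writes four figures: the exponential risk curves for each configured `k`;
#' the consultation rate and consultation probability density for the three
#' access situations; pre/post expected event-rate curves for the medication
#' scenarios; and the same for the promotion scenarios. A plotting failure
#' (e.g. no usable graphics device) is reported as a warning and skipped,
#' never an error.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param outdir Output directory, created if needed.
#' @param format `"png"` or `"svg"`.
#' @return Paths of the files written, invisibly.
#' @export
render_figures <- function(config = default_config(), outdir = ".",
                           format = c("png", "svg")) {
  stopifnot(inherits(config, "run_config"))
  format <- match.arg(format)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  risk1 <- config$risks[[1]]
  plots <- list(
    fig1_risk_curves = function() fig_risk_curves(config$risks),
    fig2_consultation = function() fig_consultation(config$population),
    fig3_medication = function()
      fig_medication_curves(config$population, risk1, config$grid),
    fig4_promotion = function()
      fig_promotion_curves(config$population, risk1, config$grid))
  written <- character(0)
  for (nm in names(plots)) {
    path <- file.path(outdir, paste0(nm, ".", format))
    ok <- tryCatch({
      ggplot2::ggsave(path, plots[[nm]](), width = 7, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      warning(sprintf("skipping figure %s: %s", nm, conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    if (ok) written <- c(written, path)
  }
  invisible(written)
}
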