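#' Default run configuration
#'
#' The configuration that reproduces the model's reference setting: SBP ~
#' Normal(130, 20) mm Hg, risk slopes k = 20/30/40 with l = 100 and m = 140,
#' a 1 mm Hg grid on \[10, 250\], the optimistic medication scenario
#' (a = 140, b = 0.03, c = 140, d = 0.7, e = 150) and the optimistic
#' promotion scenario (alpha = 10, beta aggregated from the optimistic
#' campaign table), both with a 50% contribution factor.
#'
#' @return An object of class `run_config`.
#' @export
default_config <- function() {
  dist <- sbp_distribution(130, 20)
  structure(list(
    population = dist,
    risks = lapply(c(20, 30, 40), function(k) risk_model(k, 100, 140)),
    grid = default_grid(dist),
    medication = medication_policy(140, 0.03, 140, 0.7, 150,
                                   label = "optimistic"),
    promotion = promotion_policy(10, table = campaign_pattern("optimistic"),
                                 label = "optimistic"),
    outdir = ".",
    plots = FALSE
  ), class = "run_config")
}

check_keys <- function(block, allowed, section) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s in `%s`: %s",
                 if (length(bad) > 1) "s" else "", section,
                 paste0("\"", bad, "\"", collapse = ", ")), call. = FALSE)
  invisible()
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file (YAML; JSON is accepted as a YAML subset),
#' fills unspecified sections with the defaults of [default_config()], and
#' validates every parameter against its type invariants before any
#' computation runs. Unknown keys are rejected with a message naming the
#' key. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(sprintf("cannot parse configuration file %s: %s", path,
                 conditionMessage(e)), call. = FALSE))
  config_from_list(raw)
}

#' Build a run configuration from a list
#'
#' @param raw A (possibly partial) nested list with sections `population`,
#'   `risk`, `grid`, `medication`, `promotion`, `output`.
#' @return A validated `run_config`.
#' @export
config_from_list <- function(raw) {
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  check_keys(raw, c("population", "risk", "grid", "medication", "promotion",
                    "output"), "top level")
  cfg <- default_config()

  p <- raw$population
  check_keys(p, c("mu", "sigma"), "population")
  if (!is.null(p))
    cfg$population <- sbp_distribution(p$mu %||% 130, p$sigma %||% 20)

  r <- raw$risk
  check_keys(r, c("k", "l", "m"), "risk")
  if (!is.null(r)) {
    kv <- r$k %||% c(20, 30, 40)
    cfg$risks <- lapply(kv, function(k)
      risk_model(k, r$l %||% 100, r$m %||% 140))
  }

  g <- raw$grid
  check_keys(g, c("lower", "upper", "step"), "grid")
  cfg$grid <- if (is.null(g)) default_grid(cfg$population, step = 1)
  else integration_grid(g$lower %||% (cfg$population$mu -
                                        6 * cfg$population$sigma),
                        g$upper %||% (cfg$population$mu +
                                        6 * cfg$population$sigma),
                        g$step %||% 1)

  m <- raw$medication
  check_keys(m, c("a", "b", "c", "d", "e", "contribution", "label"),
             "medication")
  if (!is.null(m))
    cfg$medication <- medication_policy(m$a %||% 140, m$b %||% 0.03,
                                        m$c %||% 140, m$d %||% 0.7,
                                        m$e %||% 150,
                                        m$contribution %||% 0.5,
                                        label = m$label)

  pr <- raw$promotion
  check_keys(pr, c("alpha", "beta", "table", "contribution", "label"),
             "promotion")
  if (!is.null(pr)) {
    tab <- NULL
    if (!is.null(pr$table)) {
      rows <- pr$table
      tab <- success_rate_table(
        shares = vapply(rows, function(x) x$share, numeric(1)),
        rates = vapply(rows, function(x) x$success_rate, numeric(1)),
        labels = vapply(rows, function(x) x$label %||% "", character(1)))
    }
    cfg$promotion <- promotion_policy(pr$alpha %||% 10, beta = pr$beta,
                                      table = tab %||%
                                        if (is.null(pr$beta))
                                          campaign_pattern("optimistic")
                                        else NULL,
                                      contribution = pr$contribution %||% 0.5,
                                      label = pr$label)
  }

  o <- raw$output
  check_keys(o, c("dir", "plots"), "output")
  if (!is.null(o)) {
    cfg$outdir <- o$dir %||% "."
    cfg$plots <- isTRUE(o$plots)
  }
  cfg
}

#' Serialise a run configuration to YAML
#'
#' Writes a configuration so that [load_config()] reproduces an equivalent
#' `run_config` (round trip).
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  med <- config$medication
  pro <- config$promotion
  lst <- list(
    population = list(mu = config$population$mu,
                      sigma = config$population$sigma),
    risk = list(k = vapply(config$risks, function(r) r$k, numeric(1)),
                l = config$risks[[1]]$l, m = config$risks[[1]]$m),
    grid = list(lower = config$grid$lower, upper = config$grid$upper,
                step = config$grid$step),
    medication = list(a = med$a, b = med$b, c = med$c, d = med$d, e = med$e,
                      contribution = med$contribution),
    promotion = list(alpha = pro$alpha, beta = pro$beta,
                     contribution = pro$contribution),
    output = list(dir = config$outdir, plots = config$plots))
  if (!is.null(med$label)) lst$medication$label <- med$label
  if (!is.null(pro$label)) lst$promotion$label <- pro$label
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$population)
  cat(sprintf("  risk: k = %s, l = %g, m = %g\n",
              paste(vapply(x$risks, function(r) r$k, numeric(1)),
                    collapse = "/"),
              x$risks[[1]]$l, x$risks[[1]]$m))
  print(x$grid)
  print(x$medication)
  print(x$promotion)
  invisible(x)
}
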