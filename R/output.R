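format_cell <- function(v) {
  ifelse(is.na(v), "", formatC(v, format = "e", digits = 2))
}

grid_csv_lines <- function(grid_result) {
  dn <- dimnames(grid_result$cells)
  lines <- character(0)
  for (i in seq_along(grid_result$k)) {
    lines <- c(lines, sprintf("k = %g", grid_result$k[i]))
    lines <- c(lines, paste(c(grid_result$row_name, grid_result$col_labels),
                            collapse = ","))
    for (j in seq_along(dn[[2]])) {
      cells <- format_cell(grid_result$cells[i, j, ])
      lines <- c(lines, paste(c(dn[[2]][j], cells), collapse = ","))
    }
    lines <- c(lines, "")
  }
  lines
}

grid_json_list <- function(grid_result) {
  dn <- dimnames(grid_result$cells)
  blocks <- lapply(seq_along(grid_result$k), function(i) {
    m <- grid_result$cells[i, , , drop = FALSE]
    dim(m) <- dim(grid_result$cells)[2:3]
    list(k = grid_result$k[i],
         rows = dn[[2]], columns = dn[[3]],
         cells = apply(m, 1, function(r) as.list(unname(r)),
                       simplify = FALSE))
  })
  list(type = grid_result$type, blocks = blocks)
}

#' Write scenario results as CSV and JSON
#'
#' Writes one CSV per result, mirroring the published table layouts
#' (medication: rows `e`, columns the scenario labels, one block per `k`;
#' promotion: rows the beta labels, columns `alpha`, one block per `k`;
#' comparison: metric/value pairs), with cells in scientific notation at 3
#' significant digits and missing cells blank. Each CSV gets a
#' full-precision JSON twin. Output is byte-deterministic for a fixed
#' configuration.
#'
#' @param results A list of [run_medication_grid()] /
#'   [run_promotion_grid()] / [compare_strategies()] results (a single
#'   result is accepted).
#' @param outdir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_tables <- function(results, outdir = ".") {
  if (inherits(results, c("scenario_grid", "strategy_comparison")))
    results <- list(results)
  stopifnot(length(results) > 0)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory: %s", outdir),
         call. = FALSE)
  written <- character(0)
  for (res in results) {
    if (inherits(res, "scenario_grid")) {
      stem <- if (res$type == "medication") "table2" else "table3"
      csv <- file.path(outdir, paste0(stem, ".csv"))
      writeLines(grid_csv_lines(res), csv)
      json <- file.path(outdir, paste0(stem, ".json"))
      jsonlite::write_json(grid_json_list(res), json, auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
      written <- c(written, csv, json)
    } else if (inherits(res, "strategy_comparison")) {
      csv <- file.path(outdir, "comparison.csv")
      df <- data.frame(
        metric = c("medication_delta_ir", "promotion_delta_ir",
                   "medication_n_hc", "promotion_n_hc",
                   "delta_ratio_med_over_promo", "winner"),
        value = c(formatC(c(res$med$delta_ir, res$promo$delta_ir),
                          format = "e", digits = 2),
                  format_n_hc(c(res$med$n_hc, res$promo$n_hc)),
                  formatC(res$delta_ratio, format = "g", digits = 3),
                  res$winner))
      utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
      json <- file.path(outdir, "comparison.json")
      jsonlite::write_json(
        list(medication_delta_ir = res$med$delta_ir,
             promotion_delta_ir = res$promo$delta_ir,
             medication_n_hc = res$med$n_hc,
             promotion_n_hc = res$promo$n_hc,
             delta_ratio_med_over_promo = res$delta_ratio,
             winner = res$winner),
        json, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      written <- c(written, csv, json)
    } else {
      stop("write_tables accepts scenario_grid and strategy_comparison ",
           "objects", call. = FALSE)
    }
  }
  invisible(written)
}
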