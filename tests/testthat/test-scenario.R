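test_that("delta and N_HC follow their definitions", {
  expect_equal(delta_ir(0.01, 9.001e-3), 9.99e-4, tolerance = 1e-9)
  expect_equal(delta_ir(0.0272, 0.0272), 0)
  expect_equal(delta_ir(0.0272, 0.0192), 0.0080, tolerance = 1e-12)
  expect_error(delta_ir(0.009, 0.01), "invalid policy")
  expect_equal(n_hc(1e-3), 1000)
  expect_equal(format_n_hc(n_hc(9.99e-4)), "1001")
  expect_equal(format_n_hc(n_hc(2.33e-3)), "429")
  expect_identical(n_hc(0), Inf)
  expect_identical(format_n_hc(n_hc(0)), "undefined")
})

test_that("an outcome object is internally consistent", {
  out <- intervention_outcome(dist0, risk0, opt_med, grid0)
  expect_s3_class(out, "intervention_outcome")
  expect_equal(out$delta_ir, out$baseline_ir - out$post_ir,
               tolerance = 1e-15)
  expect_gte(out$delta_ir, 0)
  expect_equal(out$n_hc, 1 / out$delta_ir, tolerance = 1e-15)
  expect_equal(out$scenario_id, "optimistic")
})

test_that("the medication grid reproduces the published block layout", {
  g <- run_medication_grid(dist0, c(20, 30, 40), grid = grid0)
  expect_equal(dim(g$cells), c(3L, 4L, 4L))
  # 4 + 3 + 2 + 1 populated cells per block, triangular absence pattern
  for (i in 1:3) {
    block <- g$cells[i, , ]
    expect_equal(sum(!is.na(block)), 10L)
    expect_equal(unname(colSums(!is.na(block))), c(4L, 3L, 2L, 1L))
  }
  # flagship cells
  expect_equal(g$cells["k=20", "e=150", "optimistic"], 9.99e-4,
               tolerance = 0.02)
  expect_equal(g$cells["k=20", "e=140", "ideal"], 2.33e-3, tolerance = 0.02)
  # within a column the reduction shrinks as the threshold rises
  for (i in 1:3)
    for (h in 1:4) {
      col <- g$cells[i, , h]
      col <- col[!is.na(col)]
      expect_true(all(diff(col) < 0))
    }
  # every populated cell shrinks as the risk slope k flattens
  for (j in 1:4)
    for (h in 1:4) {
      cell <- g$cells[, j, h]
      if (any(is.na(cell))) next
      expect_true(all(diff(cell) < 0))
    }
})

test_that("a zero-accessibility column produces vanishing reductions", {
  cols <- list(list(a = 140, b = 1e-13, c = 140, d = 0.7, label = "null"))
  g <- run_medication_grid(dist0, 20, policy_columns = cols,
                           e_rows = c(150, 160), grid = grid0)
  expect_true(all(abs(g$cells) < 1e-10, na.rm = TRUE))
})

test_that("the promotion grid is beta-proportional and ordered", {
  g <- run_promotion_grid(dist0, c(20, 30, 40), grid = grid0)
  expect_equal(dim(g$cells), c(3L, 3L, 3L))
  expect_true(all(!is.na(g$cells)))
  betas <- unname(g$rows)
  for (i in 1:3)
    for (h in 1:3) {
      col <- g$cells[i, , h]
      per_beta <- col / betas
      expect_lt(diff(range(per_beta)) / mean(per_beta), 1e-9)
      # ideal : realistic = 50 : 13.75 exactly
      expect_equal(unname(col["ideal"] / col["realistic"]), 50 / 13.75,
                   tolerance = 1e-9)
    }
  # decreasing in k, increasing in alpha (columns are alpha = 20, 10, 5)
  for (j in 1:3)
    for (h in 1:3) expect_true(all(diff(g$cells[, j, h]) < 0))
  for (i in 1:3)
    for (j in 1:3) expect_true(all(diff(g$cells[i, j, ]) < 0))
})

test_that("pointwise curves integrate back to the cumulative reduction", {
  for (pol in list(opt_med, ideal_med, opt_promo,
                   promotion_policy(20, beta = 0.5))) {
    out <- intervention_outcome(dist0, risk0, pol, grid0)
    expect_equal(curve_gap_area(out$curves), out$delta_ir,
                 tolerance = 1e-10)
    expect_lt(abs(curve_gap_area(out$curves) - out$delta_ir), 1e-6)
    expect_true(all(out$curves$gap >= 0))
  }
})

test_that("medication leaves the population below the threshold untouched", {
  cur <- pointwise_risk_curves(dist0, risk0, opt_med, grid0)
  below <- cur$x < 150
  expect_equal(cur$post[below], cur$pre[below], tolerance = 1e-15)
  # worked-example gap at 160 mm Hg: density x uptake x risk difference
  at160 <- cur$gap[cur$x == 160]
  expected <- sbp_density(160, dist0) * consultation_rate(160, opt_med) *
    (risk_at(160, risk0) - risk_at(153, risk0))
  expect_equal(at160, expected, tolerance = 1e-12)
  expect_equal(at160, 2.35e-5, tolerance = 0.01)
})

test_that("promotion and medication gaps cross at the threshold", {
  med <- pointwise_risk_curves(dist0, risk0, opt_med, grid0)
  pro <- pointwise_risk_curves(dist0, risk0, opt_promo, grid0)
  # medication curves duplicate the node at e; align on unique x
  med_gap <- med$gap[!duplicated(med$x)]
  xs <- med$x[!duplicated(med$x)]
  stopifnot(all(xs == pro$x))
  low <- xs >= 100 & xs < 150
  expect_true(all(pro$gap[low] > med_gap[low]))
  high <- xs >= 165 & xs <= 220
  expect_true(all(med_gap[high] > pro$gap[high]))
})

test_that("delta ratios are invariant to the absolute incidence scale l", {
  for (l in c(100, 1000)) {
    rk <- risk_model(20, l, 140)
    med <- intervention_outcome(dist0, rk, opt_med, grid0)
    pro <- intervention_outcome(dist0, rk, opt_promo, grid0)
    ratio <- med$delta_ir / pro$delta_ir
    if (l == 100) ratio100 <- ratio
  }
  expect_equal(ratio, ratio100, tolerance = 1e-12)
})

test_that("strategy comparison declares the larger reduction the winner", {
  med <- intervention_outcome(dist0, risk0, opt_med, grid0)
  pro <- intervention_outcome(dist0, risk0, opt_promo, grid0)
  comp <- compare_strategies(med, pro)
  expect_equal(comp$delta_ratio, med$delta_ir / pro$delta_ir)
  expect_equal(comp$winner, "medication")
  expect_equal(comp$nhc_ratio, comp$delta_ratio, tolerance = 1e-12)
  # identical outcomes tie
  tie <- compare_strategies(pro, pro)
  expect_equal(tie$delta_ratio, 1)
  expect_equal(tie$winner, "tie")
  # refusing mismatched baselines
  other <- intervention_outcome(dist0, risk_model(30), opt_promo, grid0)
  expect_error(compare_strategies(med, other), "same baseline")
  # undefined when an intervention does nothing
  null_pro <- intervention_outcome(dist0, risk0,
                                   promotion_policy(0, beta = 0.5), grid0)
  expect_error(compare_strategies(med, null_pro), "undefined")
})

test_that("grid results convert to a tidy data frame", {
  g <- run_promotion_grid(dist0, 20, grid = grid0)
  df <- as.data.frame(g)
  expect_equal(nrow(df), 9L)
  expect_true(all(c("k", "row", "column", "delta_ir") %in% names(df)))
  expect_true(all(df$delta_ir > 0))
})
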