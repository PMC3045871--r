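test_that("consultation rate follows the exponential uptake curve", {
  expect_equal(consultation_rate(160, opt_med), 0.4512, tolerance = 1e-4)
  expect_equal(round(consultation_rate(160, opt_med), 2), 0.45)
  expect_equal(consultation_rate(140, opt_med), 0)        # x = a
  expect_equal(consultation_rate(180, ideal_med), 1 - exp(-2.5),
               tolerance = 1e-12)
  # clamped to [0, 1] everywhere, including below the alarming level
  xs <- seq(60, 260, by = 2)
  r <- consultation_rate(xs, opt_med)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(r[xs < 140] == 0))
  # complement equals the published no-consultation rate above a
  above <- xs[xs >= 140]
  expect_equal(1 - consultation_rate(above, opt_med),
               exp(-(above - 140) * 0.03), tolerance = 1e-12)
})

test_that("consultation probability density is the density-rate product", {
  expect_equal(consultation_probability_density(160, dist0, opt_med),
               sbp_density(160, dist0) * consultation_rate(160, opt_med),
               tolerance = 1e-14)
  expect_equal(consultation_probability_density(160, dist0, opt_med),
               0.002923, tolerance = 1e-3)
  expect_equal(consultation_probability_density(120, dist0, opt_med), 0)
  # integrates to at most 1 (a density damped by a factor <= 1)
  xs <- grid_points(grid0)
  mass <- sum(consultation_probability_density(xs, dist0, opt_med)) *
    grid0$step
  expect_lte(mass, 1)
})

test_that("risk-credited SBP lowering matches the worked example", {
  expect_equal(sbp_lowering_effect(160, opt_med), 7)  # (160-140)*0.7*0.5
  expect_equal(sbp_lowering_effect(140, opt_med), 0)  # at the target
  expect_equal(sbp_lowering_effect(180, ideal_med), 20)
  # reduction never drags SBP below the target
  xs <- seq(140, 260, by = 5)
  expect_true(all(sbp_lowering_effect(xs, opt_med) <= xs - 140))
  expect_true(all(sbp_lowering_effect(xs, opt_med) >= 0))
})

test_that("treated individual risk composes lowering with the risk curve", {
  expect_equal(treated_individual_ir(160, risk0, opt_med),
               risk_at(153, risk0), tolerance = 1e-12)
  expect_equal(signif(treated_individual_ir(160, risk0, opt_med), 2), 0.019)
  expect_error(treated_individual_ir(145, risk0, opt_med), "at or above")
  # zero adherence leaves risk unchanged
  null_d <- medication_policy(140, 0.03, 140, 0, 150)
  expect_equal(treated_individual_ir(160, risk0, null_d),
               risk_at(160, risk0), tolerance = 1e-14)
  p18 <- medication_policy(130, 0.05, 130, 0.8, 150)
  expect_equal(treated_individual_ir(180, risk0, p18),
               risk_at(160, risk0), tolerance = 1e-12)
  expect_true(all(treated_individual_ir(seq(150, 250, 10), risk0, opt_med) <=
                    risk_at(seq(150, 250, 10), risk0)))
})

test_that("post-medication incidence collapses to baseline in null limits", {
  base <- cumulative_ir(dist0, risk0, grid0)
  # vanishing accessibility: nobody consults
  no_consult <- medication_policy(140, 1e-12, 140, 0.7, 150)
  expect_equal(post_medication_ir(dist0, risk0, no_consult, grid0), base,
               tolerance = 1e-9)
  # zero adherence: consulting changes nothing
  no_adhere <- medication_policy(140, 0.03, 140, 0, 150)
  expect_equal(post_medication_ir(dist0, risk0, no_adhere, grid0), base,
               tolerance = 1e-14)
})

test_that("post-medication incidence reproduces the flagship grid cells", {
  base <- cumulative_ir(dist0, risk0, grid0)
  d_opt <- base - post_medication_ir(dist0, risk0, opt_med, grid0)
  expect_equal(d_opt, 9.99e-4, tolerance = 0.02)
  d_ideal <- base - post_medication_ir(dist0, risk0, ideal_med, grid0)
  expect_equal(d_ideal, 2.33e-3, tolerance = 0.02)
})

test_that("medication strictly reduces incidence for active policies", {
  base <- cumulative_ir(dist0, risk0, grid0)
  for (pol in all_medication_policies()) {
    post <- post_medication_ir(dist0, risk0, pol, grid0)
    expect_lt(post, base)
    expect_gt(post, 0)
  }
})

test_that("1 mm Hg trapezoid agrees with a 0.01 mm Hg Simpson reference", {
  for (pol in all_medication_policies()) {
    d1 <- cumulative_ir(dist0, risk0, grid0) -
      post_medication_ir(dist0, risk0, pol, grid0)
    df <- cumulative_ir(dist0, risk0, fine_grid, rule = "simpson") -
      post_medication_ir(dist0, risk0, pol, fine_grid, rule = "simpson")
    expect_lt(abs(d1 - df) / df, 1e-3)
  }
})

test_that("policy validation catches inconsistent parameters", {
  expect_error(medication_policy(140, -0.01, 140, 0.7, 150), "b")
  expect_error(medication_policy(140, 0.03, 140, 1.5, 150), "d")
  expect_error(medication_policy(140, 0.03, 140, 0.7, 150,
                                 contribution = 0), "contribution")
  expect_error(medication_policy(140, 0.03, 150, 0.7, 140), "at least")
  # threshold must sit on the grid and inside its range
  off_grid <- medication_policy(140, 0.03, 140, 0.7, 150.5)
  expect_error(post_medication_ir(dist0, risk0, off_grid, grid0),
               "integration grid")
  outside <- medication_policy(140, 0.03, 140, 0.7, 260)
  expect_error(post_medication_ir(dist0, risk0, outside, grid0),
               "integration grid")
})
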