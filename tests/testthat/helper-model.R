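# Reference objects shared across the suite: the default virtual population,
# the k = 20 risk model, the 1 mm Hg grid, and the published scenarios.

dist0 <- sbp_distribution(130, 20)
risk0 <- risk_model(20, 100, 140)
grid0 <- default_grid(dist0)

opt_med <- medication_policy(140, 0.03, 140, 0.7, 150, label = "optimistic")
ideal_med <- medication_policy(130, 0.05, 130, 0.8, 140, label = "ideal")
opt_promo <- promotion_policy(10, table = campaign_pattern("optimistic"),
                              label = "optimistic")

fine_grid <- integration_grid(10, 250, 0.01)

# All published medication scenario cells (column params x initiation rows),
# skipping the absent low-e combinations.
all_medication_policies <- function() {
  out <- list()
  for (p in medication_columns())
    for (e in c(140, 150, 160, 180)) {
      if (e < p$a + 10) next
      out[[length(out) + 1L]] <-
        medication_policy(p$a, p$b, p$c, p$d, e, label = p$label)
    }
  out
}

# Independent quadrature oracle: adaptive integration via stats::integrate.
integrate_oracle <- function(f, lower = 10, upper = 250) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10)$value
}
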