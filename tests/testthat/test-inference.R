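test_that("Bonferroni thresholds divide the levels by the family size", {
  a <- sim_annual(20)
  fit <- fit_diversity_model(a, "qa_me", criteria = FALSE)
  eff <- effect_inference(fit, n_tests = 6)
  expect_equal(eff$thresholds, c(0.05, 0.01, 0.001) / 6)
  expect_equal(eff$thresholds[1], 0.05 / 6)
  eff1 <- effect_inference(fit, n_tests = 1)
  expect_equal(eff1$thresholds, c(0.05, 0.01, 0.001))
  expect_error(effect_inference(fit, n_tests = 0), ">= 1")
})

test_that("the pairwise table covers all ten pairs symmetrically", {
  a <- sim_annual(22)
  fit <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
  eff <- effect_inference(fit)
  expect_equal(nrow(eff$pairwise), 10)
  expect_false(any(duplicated(
    t(apply(eff$pairwise[, 1:2], 1, sort)))))
  # swapping a pair flips the sign of the difference, not the statistic
  V <- vcov(fit)
  cf <- coef(fit)
  i <- "managementextensive:d_term"; j <- "managementintensive:d_term"
  w_ij <- (cf[i] - cf[j])^2 / (V[i, i] + V[j, j] - 2 * V[i, j])
  w_ji <- (cf[j] - cf[i])^2 / (V[j, j] + V[i, i] - 2 * V[j, i])
  expect_equal(unname(w_ij), unname(w_ji))
  row <- eff$pairwise[eff$pairwise$management_1 == "extensive" &
                        eff$pairwise$management_2 == "intensive", ]
  expect_equal(row$wald, unname(w_ij), tolerance = 1e-10)
})

test_that("significance stars respect the adjusted thresholds", {
  a <- sim_annual(23)
  fit <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
  eff <- effect_inference(fit, n_tests = 6)
  for (k in seq_len(nrow(eff$slopes))) {
    p <- eff$slopes$p[k]; s <- eff$slopes$signif[k]
    expected <- if (p < 0.001 / 6) "***" else if (p < 0.01 / 6) "**"
                else if (p < 0.05 / 6) "*" else ""
    expect_identical(s, expected)
  }
})

test_that("the form race ranks candidates on a common observation set", {
  a <- sim_annual(25)
  race <- select_diversity_form(a, "biomass_yield")
  expect_setequal(race$form,
                  c("sqrt", "linear", "linear_squared", "log", "inverse"))
  expect_true(all(is.na(race$error)))
  expect_equal(length(unique(race$n_obs)), 1)
  expect_equal(sort(race$rank_bic), 1:5)
  # identical candidates tie exactly
  tie <- select_diversity_form(a, "biomass_yield", forms = c("sqrt", "sqrt"))
  expect_equal(tie$aic[1], tie$aic[2])
  expect_equal(tie$bic[1], tie$bic[2])
})

test_that("legume specifications agree when legumes are absent", {
  a <- sim_annual(26)
  no_leg <- a[!a$legume_present, ]
  # keep enough plots per block; absence of legumes collapses both variants
  no_leg$legume_share <- 0
  rob <- legume_robustness(no_leg, "biomass_yield")
  expect_equal(rob$comparison$slope_presence,
               rob$comparison$slope_sqrt_share, tolerance = 1e-6)
})

test_that("legume share enters as its square root at the boundary", {
  a <- sim_annual(27)
  f <- fit_diversity_model(a, "biomass_yield", legume_term = "sqrt_share",
                           criteria = FALSE)
  expect_equal(f$data$.legume, sqrt(a$legume_share))
  mono_leg <- a$richness == 1 & a$legume_present
  if (any(mono_leg))
    expect_true(all(f$data$.legume[mono_leg] == 1))
})

test_that("both legume variants recover presence-generated diversity slopes", {
  truth <- simulation_params()$diversity_slope
  est_p <- matrix(NA_real_, 15, 5); est_s <- est_p
  for (i in 1:15) {
    a <- sim_annual(6000 + i)
    rob <- legume_robustness(a, "biomass_yield")
    est_p[i, ] <- rob$comparison$slope_presence
    est_s[i, ] <- rob$comparison$slope_sqrt_share
  }
  expect_true(all(abs(colMeans(est_p) - truth) < 10))
  expect_true(all(abs(colMeans(est_s) - truth) < 10))
})
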