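test_that("itemized costs reproduce the published ledger values", {
  expect_equal(fertilizer_increment_cost(), 165.1185, tolerance = 1e-6)
  expect_equal(fertilizer_increment_cost(0, 0, 0), 0)
  expect_equal(fertilizer_increment_cost(50, 21.8, 41.5), 82.559,
               tolerance = 1e-3)
  expect_equal(task_cost("fertilizing"), 8.575)
  expect_equal(task_cost(c("cutting", "windrowing", "collecting")), 77.405)
  expect_equal(task_cost(character(0)), 0)
  expect_error(task_cost("ploughing"), "unknown task")
  expect_equal(reseeding_process_cost(), 12.245)

  hay <- hay_transfer_cost()
  expect_s3_class(hay, "cost_ledger")
  expect_equal(hay$total, 426.535)
  expect_equal(sum(hay$items), hay$total)
  no_opp <- hay_transfer_cost(economic_rates(hay_opportunity_cost = 0))
  expect_equal(no_opp$total, 176.535)
})

test_that("rate variations act linearly on the task costs", {
  expect_equal(reseeding_process_cost(economic_rates(labor_rate = 0)), 3.405)
  expect_equal(reseeding_process_cost(economic_rates(fuel_price = 0)), 8.84)
  hay2 <- hay_transfer_cost(economic_rates(labor_rate = 26))
  expect_equal(hay2$total - hay_transfer_cost()$total, 10.92 * 13)
  # doubling every rate doubles every ledger item
  r2 <- economic_rates(milk_price = 0.62, labor_rate = 26, fuel_price = 1.5,
                       can_price = 0.46, pk_price = 0.44,
                       hay_opportunity_cost = 500)
  expect_equal(hay_transfer_cost(r2)$items, 2 * hay_transfer_cost()$items)
  expect_equal(fertilizer_increment_cost(rates = r2),
               2 * fertilizer_increment_cost())
})

test_that("management switch costs match the published worked examples", {
  s1 <- management_switch_cost("less_intensive", "intensive")
  expect_equal(s1$total_printed, 174)
  expect_equal(s1$profit_change, -174)
  s2 <- management_switch_cost("less_intensive", "very_highly_intensive")
  expect_equal(s2$total_printed, 493)
  expect_equal(s2$profit_change, -493)
  expect_equal(management_switch_cost("intensive", "intensive")$total, 0)
  # full-precision chain additivity along monotone intensification
  mid <- management_switch_cost("intensive", "very_highly_intensive")
  expect_equal(s1$total + mid$total, s2$total, tolerance = 1e-10)
  expect_error(management_switch_cost("organic", "intensive"), "unknown")
})

test_that("revenue valuation is exact and homogeneous", {
  r <- revenue(1.0)
  expect_equal(r$milk_yield_ha, 10000)
  expect_equal(r$revenue, 3100)
  expect_equal(revenue(0)$revenue, 0)
  expect_equal(revenue(0.5, economic_rates(milk_price = 0.40))$revenue, 2000)
  expect_equal(revenue(2 * 0.7)$revenue, 2 * revenue(0.7)$revenue)
  expect_error(revenue(-1), "non-negative")
})

test_that("the equivalence solver inverts the sqrt diversity effect", {
  # deterministic revenue surface: slope 100 Euro per sqrt-species,
  # intensive management worth a flat +100 Euro over less intensive
  sw <- build_swards(build_design(seed = 31))
  base_rev <- c(extensive = 800, less_intensive = 1000, intensive = 1100,
                highly_intensive = 1200, very_highly_intensive = 1300)
  ann <- data.frame(sw,
                    revenue = base_rev[as.character(sw$management)] +
                      100 * sqrt(sw$richness))
  fit <- fit_diversity_model(ann, "revenue")
  expect_true(fit$degenerate)
  eq <- equivalent_diversity_change(fit, "less_intensive", "intensive",
                                    D_start = 1)
  expect_equal(eq$revenue_gap, 100, tolerance = 1e-6)
  expect_equal(eq$D_equivalent, 4, tolerance = 1e-6)
  expect_equal(eq$D_species, 4L)
  expect_false(eq$extrapolated)
  # zero management gap: no diversity change needed
  eq0 <- equivalent_diversity_change(fit, "intensive", "intensive",
                                     D_start = 9)
  expect_equal(eq0$D_equivalent, 9, tolerance = 1e-6)
  # gap beyond the design range is clipped and flagged
  ann2 <- transform(ann, revenue = revenue +
                      4000 * (management == "very_highly_intensive"))
  fit2 <- fit_diversity_model(ann2, "revenue")
  eq2 <- equivalent_diversity_change(fit2, "less_intensive",
                                     "very_highly_intensive", D_start = 1)
  expect_equal(eq2$D_equivalent, 60)
  expect_true(eq2$extrapolated)
})

test_that("the Welch test handles standard and degenerate inputs", {
  w <- welch_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(c(0, 0, 0), c(1, 1, 1)), "constant")
  w2 <- welch_test(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_equal(w2$t, 0)
  set.seed(1)
  w3 <- welch_test(rnorm(20), rnorm(20, 5))
  expect_lt(w3$p, 1e-6)
})
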