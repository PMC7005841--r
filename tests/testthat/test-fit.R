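test_that("noise-free data are a fixed point of the fit", {
  a <- sim_annual(6, noise_free_params(6), min_biomass = 0.5)
  fit <- fit_diversity_model(a, "biomass_yield")
  expect_true(fit$degenerate)
  p <- noise_free_params(6)
  expect_equal(fitted_slopes(fit), p$diversity_slope, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp), c(0, 0, 0))
  cf <- coef(fit)
  expect_equal(unname(cf["n_fg"]), p$fg_effect, tolerance = 1e-6)
  expect_equal(unname(cf[".grass"]), p$grass_effect, tolerance = 1e-6)
  leg <- cf[grep(":\\.legume$", names(cf))]
  names(leg) <- sub("^management", "", sub(":\\.legume$", "", names(leg)))
  expect_equal(leg[names(p$legume_effect)], p$legume_effect,
               tolerance = 1e-6)
  # noise-free predictions equal the generating means exactly
  expect_equal(predict(fit), a$biomass_yield, tolerance = 1e-8)
})

test_that("fit results are invariant to row and level ordering", {
  a <- sim_annual(8)
  f1 <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
  shuffled <- a[rev(seq_len(nrow(a))), ]
  shuffled$management <- as.character(shuffled$management)
  f2 <- fit_diversity_model(shuffled, "biomass_yield", criteria = FALSE)
  expect_equal(fitted_slopes(f1), fitted_slopes(f2), tolerance = 1e-6)
  g1 <- predict_diversity_grid(f1, D = c(1, 8, 60))
  g2 <- predict_diversity_grid(f2, D = c(1, 8, 60))
  expect_equal(g1$predicted, g2$predicted, tolerance = 1e-6)
})

test_that("variance components and robust covariance are well formed", {
  a <- sim_annual(13)
  fit <- fit_diversity_model(a, "qa_me")
  expect_true(all(fit$varcomp >= 0))
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_true(all(diag(vcov(fit, "model")) > 0))
  expect_false(is.na(fit$aic) || is.na(fit$bic))
})

test_that("sqrt-form predictions obey the 3-beta gap identity", {
  a <- sim_annual(10)
  fit <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
  covs <- list(legume = 0.5, n_fg = 2, grass = 0.6, tall_herb = 0.5)
  g <- predict_diversity_grid(fit, D = c(1, 16), policy = "fixed",
                              covariates = covs)
  gap <- g$predicted[g$richness == 16] - g$predicted[g$richness == 1]
  # sqrt(16) - sqrt(1) = 3, so the gap is 3 slopes, per management
  expect_equal(unname(gap), unname(3 * fitted_slopes(fit)),
               tolerance = 1e-8)
  p1 <- g[g$richness == 1 & g$management == "extensive", "predicted"]
  cf <- coef(fit)
  expect_equal(p1, unname(cf["managementextensive"] +
                            cf["managementextensive:d_term"] +
                            0.5 * cf["managementextensive:.legume"] +
                            2 * cf["n_fg"] + 0.6 * cf[".grass"] +
                            0.5 * cf[".tall_herb"]), tolerance = 1e-8)
})

test_that("degenerate designs give informative errors", {
  a <- sim_annual(14)
  expect_error(fit_diversity_model(a, "nonexistent"), "lacks columns")
  sub <- a[a$management != "intensive", ]
  expect_error(fit_diversity_model(sub, "biomass_yield"),
               "singular design.*intensive")
  a_na <- a; a_na$biomass_yield[3] <- NA
  expect_error(fit_diversity_model(a_na, "biomass_yield"), "missing values")
})

test_that("extrapolation beyond the design range warns", {
  a <- sim_annual(15)
  fit <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
  expect_warning(
    predict(fit, data.frame(richness = 100, management = "intensive",
                            legume_present = TRUE, n_fg = 2,
                            grass_present = TRUE, tall_herb_present = FALSE)),
    "extrapolating")
})

test_that("average slope estimates track the truth over replicates", {
  truth <- simulation_params()$diversity_slope
  n_rep <- 40
  est <- matrix(NA_real_, n_rep, 5)
  for (i in seq_len(n_rep)) {
    a <- sim_annual(4000 + i)
    f <- fit_diversity_model(a, "biomass_yield", criteria = FALSE)
    est[i, ] <- fitted_slopes(f)
  }
  z <- (colMeans(est) - truth) / (apply(est, 2, sd) / sqrt(n_rep))
  expect_true(all(abs(z) < 3.5))
})
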