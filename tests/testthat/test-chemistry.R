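test_that("estimation equations reproduce hand-computed values", {
  expect_equal(crude_protein(0), 0)
  expect_equal(crude_protein(24), 150)
  expect_equal(crude_protein(32), 200)

  expect_equal(metabolizable_energy(0, 0, 0), 3.16)
  expect_equal(metabolizable_energy(50, 150, 20), 9.9684)
  expect_equal(metabolizable_energy(40, 120, 25), 8.4994)

  expect_equal(net_energy_lactation(0, 0, 0), 1.64)
  expect_equal(net_energy_lactation(50, 150, 20), 5.965)

  expect_equal(utilizable_crude_protein(2, 5, 3, 200), 125)
  expect_equal(utilizable_crude_protein(1, 4, 2, 200), 93.75)
  expect_equal(utilizable_crude_protein(2, 5, 7, 200), 0)

  expect_equal(organic_matter(0), 1000)
  expect_equal(organic_matter(100), 900)
  expect_equal(organic_matter(1000), 0)

  expect_equal(milk_production_potential(6.4, 3.2), 2)
  expect_equal(milk_production_potential(3.2, 3.2), 1)
  expect_equal(milk_production_potential(0, 3.2), 0)
})

test_that("energy equations are increasing and ME dominates NEL", {
  set.seed(42)
  gas <- runif(200, 0, 80); cp <- runif(200, 0, 300); ee <- runif(200, 0, 60)
  expect_true(all(metabolizable_energy(gas, cp, ee) >
                    net_energy_lactation(gas, cp, ee)))
  expect_true(all(net_energy_lactation(gas + 1, cp, ee) >
                    net_energy_lactation(gas, cp, ee)))
  expect_true(all(metabolizable_energy(gas, cp + 1, ee) >
                    metabolizable_energy(gas, cp, ee)))
})

test_that("uCP is invariant to a common scaling of all masses", {
  expect_equal(utilizable_crude_protein(4, 10, 6, 400),
               utilizable_crude_protein(2, 5, 3, 200))
})

test_that("domain violations raise errors; impossible uCP warns", {
  expect_error(crude_protein(-1), "non-negative")
  expect_error(metabolizable_energy(-1, 0, 0), "non-negative")
  expect_error(net_energy_lactation(0, -5, 0), "non-negative")
  expect_error(utilizable_crude_protein(2, 5, 3, 0), "positive")
  expect_error(organic_matter(1200), "\\[0, 1000\\]")
  expect_error(milk_production_potential(5, 0), "positive")
  expect_warning(utilizable_crude_protein(1, 1, 5, 200), "negative uCP")
})

test_that("quality_profile composes the equations and handles missing uCP", {
  pr <- quality_profile(gas = 0, cp = 0, ee = 0, ndf = 300, ash = 0)
  expect_equal(pr$me, 3.16)
  expect_equal(pr$nel, 1.64)
  expect_equal(pr$om, 1000)
  expect_true(is.na(pr$ucp))

  pr2 <- quality_profile(gas = 50, cp = 150, ee = 20, ndf = 450, ash = 90,
                         nh3_n_blank = 2, n_sample = 5, nh3_n_sample = 3,
                         dm_mg = 200)
  expect_equal(pr2$ucp, 125)
  expect_equal(pr2$milk_potential, pr2$nel / 3.2)
  # purity: identical inputs, identical outputs
  expect_identical(pr2, quality_profile(gas = 50, cp = 150, ee = 20,
                                        ndf = 450, ash = 90,
                                        nh3_n_blank = 2, n_sample = 5,
                                        nh3_n_sample = 3, dm_mg = 200))
})

test_that("add_quality augments a cut table and respects optional uCP", {
  cuts <- data.frame(sward_id = "a", cut = 1:2, gas = c(50, 40),
                     cp = c(150, 120), ee = c(20, 25), ndf = c(450, 470),
                     ash = c(90, 95))
  q <- add_quality(cuts)
  expect_equal(q$me, metabolizable_energy(cuts$gas, cuts$cp, cuts$ee))
  expect_true(all(is.na(q$ucp)))
  expect_error(add_quality(cuts[, -3]), "chemistry columns")
})
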