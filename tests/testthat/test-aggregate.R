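test_that("interpolation is linear over cut number with exact endpoints", {
  expect_equal(interpolate_quality(12, 9, 4), c(12, 11, 10, 9))
  expect_equal(interpolate_quality(7, 7, 5), rep(7, 5))
  expect_equal(interpolate_quality(12, 9, 2), c(12, 9))
  expect_equal(interpolate_quality(12, 9, 1), 12)
  expect_error(interpolate_quality(1, 2, 0), "positive integer")
  # vector input: one column per variable, monotone when endpoints ordered
  m <- interpolate_quality(c(me = 12, ndf = 400), c(me = 9, ndf = 460), 4)
  expect_equal(dim(m), c(4, 2))
  expect_true(all(diff(m[, "me"]) < 0) && all(diff(m[, "ndf"]) > 0))
})

test_that("sward filter drops missing and very small cuts with reasons", {
  cuts <- data.frame(
    sward_id = rep(c("a", "b", "c"), each = 2),
    cut = rep(1:2, 3), cuts_per_year = 2,
    biomass = c(100, 200, 150, NA, 0.5, 300),
    richness = rep(c(1, 2, 4), each = 2)
  )
  f <- filter_swards(cuts, min_biomass = 1)
  expect_setequal(f$dropped$sward_id, c("b", "c"))
  expect_equal(f$dropped$reason[f$dropped$sward_id == "b"], "missing")
  expect_equal(f$dropped$reason[f$dropped$sward_id == "c"], "small_biomass")
  expect_equal(unique(f$kept$sward_id), "a")
  expect_equal(as.vector(f$richness_histogram), c(0, 1, 1))

  # nothing dropped with zero threshold and complete data
  f0 <- filter_swards(cuts[cuts$sward_id == "a", ], min_biomass = 0)
  expect_equal(nrow(f0$dropped), 0)

  # a sward with an absent cut row counts as missing
  f2 <- filter_swards(cuts[-2, ], min_biomass = 1)
  expect_true("a" %in% f2$dropped$sward_id)
})

test_that("annual aggregation reproduces the hand-worked example", {
  cuts <- data.frame(sward_id = "s", cut = 1:2, cuts_per_year = 2,
                     biomass = c(200, 300), me = c(10, 8))
  a <- aggregate_annual(cuts)
  expect_equal(a$biomass_yield, 500)
  expect_equal(a$quality_me, 8.8)
  expect_equal(a$qa_me, 4.4)
  expect_equal(a$n_cuts_used, 2)
})

test_that("single cuts collapse and equal weights give the plain mean", {
  one <- data.frame(sward_id = "s", cut = 1, cuts_per_year = 1,
                    biomass = 400, me = 9.5)
  a1 <- aggregate_annual(one)
  expect_equal(a1$quality_me, 9.5)
  expect_equal(a1$qa_me, 400 * 9.5 / 1000)

  eq <- data.frame(sward_id = "s", cut = 1:4, cuts_per_year = 4,
                   biomass = 250, me = c(12, 11, 10, 9))
  a2 <- aggregate_annual(eq)
  expect_equal(a2$quality_me, mean(interpolate_quality(12, 9, 4)))
})

test_that("yield identity holds to machine precision and scales linearly", {
  set.seed(7)
  n <- 50
  h <- sample(c(1, 2, 4), n, replace = TRUE)
  cuts <- data.frame(
    sward_id = rep(sprintf("s%02d", 1:n), h),
    cut = sequence(h), cuts_per_year = rep(h, h),
    biomass = runif(sum(h), 50, 400),
    me = runif(sum(h), 8, 12), cp = runif(sum(h), 100, 200)
  )
  a <- aggregate_annual(cuts)
  expect_equal(a$qa_me, a$biomass_yield * a$quality_me / 1000,
               tolerance = 1e-12)
  expect_equal(a$qa_cp, a$biomass_yield * a$quality_cp / 1000,
               tolerance = 1e-12)

  # permuting cut order changes nothing
  perm <- cuts[sample(nrow(cuts)), ]
  ap <- aggregate_annual(perm)
  ap <- ap[match(a$sward_id, ap$sward_id), ]
  expect_equal(a$biomass_yield, ap$biomass_yield)
  expect_equal(a$qa_me, ap$qa_me)

  # scaling biomass by k scales yields by k, weighted quality unchanged
  k <- 2.5
  cuts2 <- transform(cuts, biomass = biomass * k)
  a2 <- aggregate_annual(cuts2)
  expect_equal(a2$biomass_yield, k * a$biomass_yield)
  expect_equal(a2$qa_me, k * a$qa_me)
  expect_equal(a2$quality_me, a$quality_me)
})

test_that("uCP aggregates from the first cut only", {
  cuts <- data.frame(sward_id = "s", cut = 1:2, cuts_per_year = 2,
                     biomass = c(200, 300), me = c(10, 8),
                     ucp = c(120, NA))
  a <- aggregate_annual(cuts)
  expect_equal(a$ucp, 120)
  expect_equal(a$qa_ucp, 200 * 120 / 1000)
  expect_true(a$ucp_first_cut_only)
})
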