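# Horvitz-Thompson totals, the tripartite CE, group statistics and PROBE.

test_that("a count contributes count over sampling probability", {
  expect_equal(round(ht_contribution(2, 0.0496), 1), 40.3)
  expect_equal(ht_contribution(1, 1 / 21), 21)
  expect_equal(ht_contribution(0, 0.3), 0)
  expect_error(ht_contribution(1, 0), class = "pp_invalid_probability")
  expect_error(ht_contribution(-1, 0.5), class = "pp_invalid_config")
})

test_that("repetition totals sum multiplicity * x/p, with uniform-weight limit", {
  # equal weights: the HT total collapses to N_tiles * mean(x)
  ord <- smooth_order(make_tiles(rep(1, 20)))
  rep <- pps_systematic_draw(ord, 4, u = 2)
  x <- rep(0L, 20); x[rep$hits$tile_id] <- c(1L, 2L, 0L, 1L)
  rep <- attach_counts(rep, data.frame(tile_id = 1:20, x = x))
  expect_equal(repetition_total(rep), 20 * mean(c(1, 2, 0, 1)))

  # the single worked hit: x = 2 at p = 17/343 (~0.0496) contributes
  # 2 * 343/17 (~40.3 at the two-decimal probability)
  one <- make_tiles(c(17, 669))
  r <- pps_systematic_draw(smooth_order(one), 2, u = 10)
  r <- attach_counts(r, data.frame(tile_id = 1:2, x = c(2, 0)))
  expect_equal(repetition_total(r), 2 * 343 / 17, tolerance = 1e-12)

  # missing counts are an estimation failure, not a silent zero
  r2 <- pps_systematic_draw(smooth_order(one), 2, u = 10)
  expect_error(repetition_total(r2), class = "pp_estimation_impossible")
  expect_error(attach_counts(r2, data.frame(tile_id = 1L, x = 2)),
               class = "pp_estimation_impossible")
})

test_that("small enumeration instance averages to its true count", {
  expect_equal(ht_mean_over_starts(c(1, 2, 3), c(1, 0, 2), 2), 3,
               tolerance = 1e-12)
})

test_that("the animal estimate combines repetitions per the factor-2 rule", {
  est <- animal_estimate(c(224, 124, 214), sf = 1 / 25)
  expect_equal(round(est$ce, 2), 0.17)
  expect_equal(est$n_hat, mean(c(224, 124, 214)) * 25 / 2, tolerance = 1e-12)
  expect_equal(round(est$n_hat, 1), 2341.7)

  expect_equal(animal_estimate(c(100, 100, 100), sf = 1 / 6)$ce, 0)
  expect_error(animal_estimate(c(0, 0, 0), sf = 1 / 6),
               class = "pp_undefined_ce")
  expect_error(animal_estimate(224, sf = 1 / 25), class = "pp_invalid_config")

  # vertebra divisor and tile fraction enter as plain divisors
  est3 <- animal_estimate(c(224, 124, 214), sf = 1 / 6,
                          units_per_animal = 3, tile_fraction = 0.5)
  expect_equal(est3$n_hat, mean(c(224, 124, 214)) * 6 / 2 / 3 / 0.5)
})

test_that("group mean CE is the root mean square of per-animal CEs", {
  expect_equal(round(group_mean_ce(c(0.05, 0.08, 0.12)), 3), 0.088)
  expect_equal(round(group_mean_ce(c(0.11, 0.14, 0.01)), 3), 0.103)
  expect_equal(group_mean_ce(c(0.07, 0.07, 0.07)), 0.07)
})

test_that("group CV is sample SD over mean", {
  expect_equal(round(group_cv(c(41, 38, 27)), 2), 0.21)
  expect_equal(round(group_cv(c(90, 58, 187)), 2), 0.6)
  expect_equal(group_cv(c(5, 5, 5, 5)), 0)
})

test_that("biological variation subtracts the estimator imprecision in quadrature", {
  expect_equal(as.numeric(cv_animal(0.5, 0.3)), 0.4)
  expect_equal(round(as.numeric(cv_animal(0.21, 0.088)), 4), 0.1907)
  clamped <- cv_animal(0.1, 0.2)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_false(attr(cv_animal(0.5, 0.3), "clamped"))
})

test_that("PROBE classifies the precision balance into three branches", {
  veh <- probe(0.21, 0.088)
  expect_equal(round(veh$ratio, 1), 5.7)
  expect_identical(veh$recommendation, "reduce_effort")

  scl <- probe(0.60, 0.103)
  expect_equal(round(scl$ratio), 34)
  expect_identical(scl$recommendation, "reduce_effort")

  fract <- probe(0.21, 0.169)
  expect_equal(round(fract$ratio, 1), 1.5)
  expect_identical(fract$recommendation, "increase_sampling")

  expect_identical(probe(0.3, 0.3 / sqrt(3))$recommendation, "adequate")
  expect_error(probe(0.2, 0), class = "pp_undefined_probe")
  expect_match(veh$caution, "proportion less")
})

test_that("sparseness is total tiles per count-bearing tile", {
  sp <- sparseness_index(1900, 35)
  expect_identical(attr(sp, "rounded"), 54L)
  expect_equal(as.numeric(sparseness_index(100, 100)), 1)
  expect_equal(as.numeric(sparseness_index(10, 1)), 10)
  expect_error(sparseness_index(10, 0), class = "pp_undefined_sparseness")
})

test_that("group summaries tie the pieces together", {
  gs <- group_summary(c(41, 38, 27), c(0.05, 0.08, 0.12))
  expect_equal(round(gs$cv_obs, 2), 0.21)
  expect_equal(round(gs$ce_mean, 3), 0.088)
  expect_identical(gs$recommendation, "reduce_effort")
  expect_equal(gs$cv_ani, as.numeric(cv_animal(gs$cv_obs, gs$ce_mean)))
  expect_error(group_summary(c(1, 2), 0.1), class = "pp_invalid_config")
})
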