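# Smooth arrangement and probability-proportional-to-weight systematic
# sampling of the supersection.

test_that("smooth arrangement is the odd/even unimodal deal", {
  ord <- smooth_order(make_tiles(c(3, 1, 2)))
  expect_equal(ord$tiles$weight_px, c(1, 3, 2))
  expect_identical(smooth_order(make_tiles(7))$tiles$weight_px, 7)
})

test_that("smooth arrangement is a unimodal permutation, with deterministic ties", {
  for (seed in 1:30) {
    w <- withr_seed(seed, rpois(sample(1:40, 1), 3))
    ord <- smooth_order(make_tiles(w))
    expect_setequal(ord$tiles$tile_id, seq_along(w))
    expect_true(proportionator:::is_unimodal(ord$tiles$weight_px))
  }
  flat <- make_tiles(rep(5, 9))
  expect_identical(smooth_order(flat)$perm, smooth_order(flat)$perm)
})

test_that("a tile's sampling probability is its weight over T_z", {
  # supersection with Z = 686 sampled with n = 2 lines: T_z = 343
  ord <- smooth_order(make_tiles(c(17, 669)))
  rep <- pps_systematic_draw(ord, 2, u = 10)
  expect_equal(rep$T_z, 343)
  p17 <- rep$hits$p[rep$hits$weight_px == 17]
  expect_equal(round(p17, 4), 0.0496)
})

test_that("equal weights reduce PPS to uniform systematic sampling", {
  ord <- smooth_order(make_tiles(rep(5, 12)))
  rep <- pps_systematic_draw(ord, 4, u = 7)
  expect_identical(nrow(rep$hits), 4L)
  expect_true(all(rep$hits$multiplicity == 1))
  # hits are every 3rd tile of the arrangement
  pos <- match(rep$hits$tile_id, ord$tiles$tile_id)
  expect_equal(diff(sort(pos)), c(3, 3, 3))
  expect_equal(rep$hits$p, rep(4 / 12, 4))
})

test_that("zero-weight tiles are never sampled", {
  w <- c(0, 3, 0, 0, 5, 1, 0, 6)
  ord <- smooth_order(make_tiles(pad_divisible(w, 3)))
  zero_ids <- make_tiles(w)$tile_id[w == 0]
  for (rep in enumerate_pps_starts(ord, 3))
    expect_length(intersect(rep$hits$tile_id, zero_ids), 0)
  drawn <- pps_systematic_draw(ord, 3, seed = 99)
  expect_length(intersect(drawn$hits$tile_id, zero_ids), 0)
})

test_that("a draw with no signal anywhere is an error", {
  ord <- smooth_order(make_tiles(c(0, 0, 0)))
  expect_error(pps_systematic_draw(ord, 2, u = 1), class = "pp_no_signal")
})

test_that("inclusion expectations match min(z, T_z)/T_z exactly", {
  w <- c(1, 2, 3, 6, 30, 2, 4)  # Z = 48, n = 4 -> T_z = 12; one heavy tile
  ord <- smooth_order(make_tiles(w))
  reps <- enumerate_pps_starts(ord, 4)
  T_z <- 48 / 4
  hit_freq <- sapply(seq_along(w), function(id) {
    mean(vapply(reps, function(r) id %in% r$hits$tile_id, logical(1)))
  })
  expect_equal(hit_freq, pmin(w, T_z) / T_z)
  # expected multiplicities sum to the number of lines
  mult <- sapply(seq_along(w), function(id) {
    mean(vapply(reps, function(r) {
      m <- r$hits$multiplicity[r$hits$tile_id == id]
      if (length(m)) m else 0L
    }, numeric(1)))
  })
  expect_equal(sum(mult), 4)
  expect_equal(mult, w / T_z)  # per-tile expected multiplicity = p_i
})

test_that("enumeration over all starts is exactly design-unbiased", {
  for (seed in 1:10) {
    inst <- withr_seed(seed, {
      m <- sample(3:30, 1)
      w <- rpois(m, 4)
      x <- ifelse(w > 0, rpois(m, 1), 0)  # counts only where weight exists
      list(w = w, x = x, n = sample(2:4, 1))
    })
    if (sum(inst$w) == 0) next
    w <- pad_divisible(inst$w, inst$n)
    expect_equal(ht_mean_over_starts(w, inst$x, inst$n), sum(inst$x),
                 tolerance = 1e-9)
  }
})

test_that("smooth arrangement does not inflate systematic-sampling variance", {
  # compare enumeration variance of the HT total under the smooth order vs
  # random arrangements, for weight-correlated counts
  var_over_starts <- function(tiles, x, n) {
    cnt <- data.frame(tile_id = tiles$tile_id, x = x)
    tot <- vapply(enumerate_pps_starts(structure(
      list(tiles = tiles, Z = sum(tiles$weight_px), perm = seq_len(nrow(tiles))),
      class = "smooth_order"), n),
      function(r) repetition_total(attach_counts(r, cnt)), numeric(1))
    stats::var(tot)
  }
  v_smooth <- v_random <- numeric(10)
  for (seed in 1:10) {
    # sparse structure: many low-weight zero-count tiles, a few heavy
    # cell-bearing tiles -- count per unit weight correlates with weight
    inst <- withr_seed(seed, {
      w <- pad_divisible(c(rpois(30, 1.2), 15 + rpois(10, 8)), 5)
      list(w = w, x = c(rep(0, 30), 1 + rbinom(10, 1, 0.3)))
    })
    ord <- smooth_order(make_tiles(inst$w))
    x_ord <- inst$x[match(ord$tiles$tile_id, seq_along(inst$w))]
    v_smooth[seed] <- var_over_starts(ord$tiles, x_ord, 5)
    v_random[seed] <- mean(vapply(1:16, function(k) {
      perm <- withr_seed(5000 + seed * 20 + k, sample(length(inst$w)))
      var_over_starts(make_tiles(inst$w[perm]), inst$x[perm], 5)
    }, numeric(1)))
  }
  expect_lt(mean(v_smooth), mean(v_random))
  expect_gte(mean(v_smooth <= v_random), 0.5)
})

test_that("tripartite sampling presents 3 x n hits and is reproducible", {
  w <- withr_seed(7, rpois(400, 2))
  ord <- smooth_order(make_tiles(w))
  trip22 <- tripartite_sample(ord, 22, seed = 5)
  expect_identical(sum(trip22$presented$multiplicity), 66L)
  expect_length(trip22$repetitions, 3L)
  trip60 <- tripartite_sample(ord, 60, seed = 5)
  expect_identical(sum(trip60$presented$multiplicity), 180L)
  expect_identical(tripartite_sample(ord, 22, seed = 5),
                   tripartite_sample(ord, 22, seed = 5))
  expect_false(identical(trip22$us, tripartite_sample(ord, 22, seed = 6)$us))
})

test_that("tile subsampling keeps the stated systematic fraction", {
  tiles <- make_tiles(rep(1, 5000))
  whole <- subsample_tiles(tiles, 1, seed = 1)
  expect_equal(attr(whole, "tile_fraction"), 1)
  attr(whole, "tile_fraction") <- NULL
  expect_identical(whole, tiles)
  expect_warning(half <- subsample_tiles(tiles, 0.5, seed = 1),
                 "below 10,000")
  expect_identical(nrow(half), 2500L)
  expect_equal(attr(half, "tile_fraction"), 0.5)

  t100 <- make_tiles(rep(1, 100))
  a <- suppressWarnings(subsample_tiles(t100, 0.1, seed = 3))
  b <- suppressWarnings(subsample_tiles(t100, 0.1, seed = 3))
  expect_identical(a, b)
  expect_identical(nrow(a), 10L)
  expect_error(subsample_tiles(t100, 0, seed = 1),
               class = "pp_invalid_config")
  expect_error(subsample_tiles(t100, 1.2, seed = 1),
               class = "pp_invalid_config")
})
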