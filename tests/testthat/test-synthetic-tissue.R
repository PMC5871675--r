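# Virtual organ generation, sectioning, tessellation and stain weighting.

test_that("organ generation places the requested cells inside the block", {
  org <- generate_organ(height_um = 3000, width_um = 3162, depth_um = 3162,
                        n_cells = 50, seed = 1)
  expect_s3_class(org, "organ_truth")
  expect_identical(org$n_true, 50L)
  expect_identical(nrow(org$cells), 50L)
  with(org$cells, {
    expect_true(all(x_um >= 0 & x_um < 3162))
    expect_true(all(y_um >= 0 & y_um < 3162))
    r <- nucleus_diameter_um / 2
    expect_true(all(z_um - r >= 0 & z_um + r <= 3000))
  })
})

test_that("a zero-cell target yields an empty organ", {
  org <- generate_organ(n_cells = 0, seed = 3)
  expect_identical(org$n_true, 0L)
  expect_identical(nrow(org$cells), 0L)
})

test_that("organ generation is reproducible from its seed", {
  a <- generate_organ(n_cells = 40, seed = 11)
  b <- generate_organ(n_cells = 40, seed = 11)
  expect_identical(a, b)
  c <- generate_organ(n_cells = 40, seed = 12)
  expect_false(identical(a$cells, c$cells))
})

test_that("invalid organ dimensions are rejected", {
  expect_error(generate_organ(height_um = -1), class = "pp_invalid_config")
  expect_error(generate_organ(width_um = 0), class = "pp_invalid_config")
})

test_that("exhaustive sectioning gives floor(H/t) slabs and logs remnants", {
  org <- generate_organ(seed = 1)
  expect_identical(section_organ(org, 6)$n_sections, 500L)

  small <- generate_organ(height_um = 13, n_cells = 0, seed = 1)
  expect_message(sec <- section_organ(small, 6), "remnant")
  expect_identical(sec$n_sections, 2L)
  expect_equal(sec$remnant_um, 1)

  flat <- generate_organ(height_um = 10, n_cells = 0, seed = 1)
  expect_error(section_organ(flat, 10), class = "pp_invalid_config")
})

test_that("tessellation covers the cross section with whole tiles only", {
  pairs10 <- data.frame(pair_id = 1:10, section = seq(1, 91, 10),
                        lookup = seq(2, 92, 10))
  org <- generate_organ(height_um = 600, width_um = 1000, depth_um = 1000,
                        n_cells = 0, seed = 1)
  tiles <- tessellate_tiles(org, pairs10, 200)
  expect_identical(nrow(tiles), 250L)  # 25 per pair x 10 pairs
  expect_identical(anyDuplicated(tiles[c("pair_id", "x_um", "y_um")]), 0L)
  # supersection area ~ SumA / a(fra): 20 pairs x 3200^2 / 200^2
  org2 <- generate_organ(seed = 1)
  pairs20 <- data.frame(pair_id = 1:20, section = seq(1, 476, 25),
                        lookup = seq(2, 477, 25))
  expect_identical(nrow(tessellate_tiles(org2, pairs20, 200)), 5120L)

  one <- generate_organ(height_um = 600, width_um = 200, depth_um = 200,
                        n_cells = 0, seed = 1)
  expect_identical(nrow(tessellate_tiles(one, pairs10[1, ], 200)), 1L)
  expect_error(tessellate_tiles(one, pairs10, 300),
               class = "pp_invalid_config")
})

test_that("edge strips narrower than a frame are dropped with a message", {
  org <- generate_organ(height_um = 600, width_um = 1050, depth_um = 1000,
                        n_cells = 0, seed = 1)
  pairs <- data.frame(pair_id = 1L, section = 1L, lookup = 2L)
  expect_message(tiles <- tessellate_tiles(org, pairs, 200), "edge tiles")
  expect_identical(nrow(tiles), 25L)
})

weighted_fixture <- function(stain, n_cells = 30, seed = 9) {
  org <- generate_organ(height_um = 120, width_um = 1000, depth_um = 1000,
                        n_cells = n_cells, seed = 5)
  sec <- section_organ(org, 6)
  pairs <- data.frame(pair_id = 1:5, section = c(1, 5, 9, 13, 17),
                      lookup = c(2, 6, 10, 14, 18))
  tiles <- tessellate_tiles(org, pairs, 200)
  list(org = org, sec = sec, pairs = pairs,
       tiles = assign_weights(tiles, org, sec, pairs, stain, seed = seed))
}

test_that("weights are zero when nothing stains, and reproducible", {
  silent <- stain_model(background_rate = 0, artifact_rate = 0)
  fx <- weighted_fixture(silent, n_cells = 0)
  expect_true(all(fx$tiles$weight_px == 0))
  expect_true(all(fx$tiles$count == 0))

  fx1 <- weighted_fixture(stain_model(artifact_rate = 0.3), n_cells = 25)
  fx2 <- weighted_fixture(stain_model(artifact_rate = 0.3), n_cells = 25)
  expect_identical(fx1$tiles, fx2$tiles)
})

test_that("a total staining false-negative leaves only background weight", {
  blind <- stain_model(background_rate = 0, artifact_rate = 0,
                       false_negative_rate = 1)
  fx <- weighted_fixture(blind, n_cells = 40)
  expect_true(all(fx$tiles$weight_px == 0))
  expect_gt(sum(fx$tiles$count), 0)  # the cells are still there to count
})

test_that("pure artifacts decouple weight from count (high weight/low count)", {
  arty <- stain_model(background_rate = 0, artifact_rate = 1,
                      artifact_px_mean = 100)
  fx <- weighted_fixture(arty, n_cells = 0)
  expect_true(all(fx$tiles$weight_px > 0))
  expect_true(all(fx$tiles$count == 0))
})

test_that("with clean specific staining, weight > 0 iff a cell profile is present", {
  clean <- stain_model(background_rate = 0, artifact_rate = 0,
                       false_negative_rate = 0)
  fx <- weighted_fixture(clean, n_cells = 35)
  t_um <- fx$sec$thickness_um
  r <- fx$org$cells$nucleus_diameter_um / 2
  f <- 200
  present <- vapply(seq_len(nrow(fx$tiles)), function(i) {
    tl <- fx$tiles[i, ]
    pr <- fx$pairs[fx$pairs$pair_id == tl$pair_id, ]
    in1 <- (fx$org$cells$z_um + r) >= (pr$section - 1) * t_um &
      (fx$org$cells$z_um - r) < pr$section * t_um
    in2 <- (fx$org$cells$z_um + r) >= (pr$lookup - 1) * t_um &
      (fx$org$cells$z_um - r) < pr$lookup * t_um
    framed <- fx$org$cells$x_um >= tl$x_um & fx$org$cells$x_um < tl$x_um + f &
      fx$org$cells$y_um >= tl$y_um & fx$org$cells$y_um < tl$y_um + f
    any(framed & (in1 | in2))
  }, logical(1))
  expect_identical(fx$tiles$weight_px > 0, present)
})

test_that("an exhaustive disector census conserves the ground truth", {
  for (seed in 1:5) {
    org <- generate_organ(height_um = 120, width_um = 600, depth_um = 600,
                          n_cells = 30, cluster_sd_um = 40, seed = seed)
    sec <- section_organ(org, 6)
    n <- sec$n_sections
    # every consecutive pair, plus a virtual empty look-up past the end:
    # each nucleus tops out in exactly one counting section
    pairs <- data.frame(pair_id = seq_len(n), section = seq_len(n),
                        lookup = seq_len(n) + 1L)
    tiles <- tessellate_tiles(org, pairs, 200)
    cen <- proportionator:::census_counts(tiles, org, sec, pairs)
    expect_identical(sum(cen$q_forward), org$n_true)
  }
})
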