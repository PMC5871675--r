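# Builders for small deterministic fixtures used across the suite.

# tile table with given weights, spatially laid out one tile per column
make_tiles <- function(weights, frame_um = 200, pair_id = 1L) {
  n <- length(weights)
  data.frame(tile_id = seq_len(n),
             pair_id = pair_id,
             x_um = (seq_len(n) - 1) * frame_um,
             y_um = 0,
             frame_um = frame_um,
             weight_px = as.numeric(weights))
}

# organ with hand-placed cells (deterministic geometry fixtures)
manual_organ <- function(cells, height_um = 60, width_um = 1000,
                         depth_um = 1000) {
  structure(list(height_um = height_um,
                 cross_section_w_um = width_um,
                 cross_section_d_um = depth_um,
                 cells = cells,
                 n_true = nrow(cells),
                 seed = NA_integer_),
            class = "organ_truth")
}

cell_df <- function(x, y, z, d = 8) {
  data.frame(x_um = x, y_um = y, z_um = z, nucleus_diameter_um = d)
}

# random organ whose nuclei avoid the first/last sections, so that the
# bidirectional disector census conserves the total exactly
safe_band_organ <- function(n_cells, height_um, thickness_um, seed,
                            width_um = 1000, depth_um = 1000, d = 8) {
  r <- d / 2
  cells <- withr_seed(seed, {
    data.frame(x_um = runif(n_cells, 0, width_um),
               y_um = runif(n_cells, 0, depth_um),
               z_um = runif(n_cells, thickness_um + r,
                            height_um - thickness_um - r),
               nucleus_diameter_um = d)
  })
  manual_organ(cells, height_um, width_um, depth_um)
}

withr_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# pad the largest weight so that n divides Z (integer-start enumeration)
pad_divisible <- function(weights, n) {
  rem <- sum(weights) %% n
  if (rem != 0) {
    i <- which.max(weights)
    weights[i] <- weights[i] + (n - rem)
  }
  weights
}

ht_mean_over_starts <- function(weights, counts, n) {
  tiles <- make_tiles(weights)
  cnt <- data.frame(tile_id = tiles$tile_id, x = counts)
  reps <- enumerate_pps_starts(smooth_order(tiles), n)
  mean(vapply(reps, function(r) repetition_total(attach_counts(r, cnt)),
              numeric(1)))
}
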