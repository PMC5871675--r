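# Tile tessellation, image-analysis weights, and the optional raster path.

#' Tessellate the sampled section pairs into unbiased-frame tiles
#'
#' Lays a regular grid of non-overlapping, half-open square tiles
#' `[x, x+f) x [y, y+f)` over the organ cross section of every sampled
#' section pair. Partial tiles at the right/top edges are dropped (the frame
#' has a fixed size; a message reports the dropped margin).
#'
#' @param organ an \code{organ_truth}.
#' @param pairs pair table from \code{\link{sample_pairs}}.
#' @param frame_um side length f of the unbiased sampling frame (um), e.g.
#'   200 for a 40,000 um^2 frame.
#' @return tile table: \code{tile_id, pair_id, x_um, y_um, frame_um}, ordered
#'   by (pair_id, y, x).
#' @export
#' @examples
#' org <- generate_organ(seed = 1)
#' pairs <- sample_pairs(plan_design(3000, 6, 20), R = 1)
#' nrow(tessellate_tiles(org, pairs, 200))  # 16 x 16 x 20 = 5120
tessellate_tiles <- function(organ, pairs, frame_um) {
  stopifnot(inherits(organ, "organ_truth"))
  check_scalar_number(frame_um, "frame_um", lower = 0, strict_lower = TRUE)
  nx <- floor(organ$cross_section_w_um / frame_um)
  ny <- floor(organ$cross_section_d_um / frame_um)
  if (nx < 1 || ny < 1)
    abort_config("the ", frame_um, " um frame does not fit inside the ",
                 organ$cross_section_w_um, " x ", organ$cross_section_d_um,
                 " um cross section")
  mx <- organ$cross_section_w_um - nx * frame_um
  my <- organ$cross_section_d_um - ny * frame_um
  if (mx > 1e-9 || my > 1e-9)
    message("tessellate_tiles: dropping partial edge tiles (",
            signif(mx, 4), " um right margin, ", signif(my, 4),
            " um top margin)")
  one <- expand.grid(x_um = (seq_len(nx) - 1) * frame_um,
                     y_um = (seq_len(ny) - 1) * frame_um)
  one <- one[order(one$y_um, one$x_um), , drop = FALSE]
  np <- nrow(pairs)
  out <- data.frame(
    tile_id = seq_len(np * nrow(one)),
    pair_id = rep(pairs$pair_id, each = nrow(one)),
    x_um = rep(one$x_um, np),
    y_um = rep(one$y_um, np),
    frame_um = frame_um
  )
  rownames(out) <- NULL
  out
}

# One pair's stochastic weight components, from a seed derived off the pair
# id. Draw order is fixed (background, artifacts, per-cell pixels) so that
# assign_weights() and render_tile_raster() reproduce identical numbers.
pair_weight_draws <- function(pair_tiles, organ, sectioning, pair, stain,
                              seed) {
  n_tiles <- nrow(pair_tiles)
  t_um <- sectioning$thickness_um
  f <- pair_tiles$frame_um[1L]
  cells <- organ$cells
  s1 <- slab_bounds(pair$section, t_um)
  s2 <- slab_bounds(pair$lookup, t_um)
  r <- cells$nucleus_diameter_um / 2
  present <- which(sphere_intersects_slab(cells$z_um, r, s1$lo, s1$hi) |
                     sphere_intersects_slab(cells$z_um, r, s2$lo, s2$hi))
  # map present cells to tiles of this pair by centroid
  tkey <- paste(floor(round(pair_tiles$x_um / f, 9)),
                floor(round(pair_tiles$y_um / f, 9)))
  ckey <- paste(floor(cells$x_um[present] / f), floor(cells$y_um[present] / f))
  tile_idx <- match(ckey, tkey)
  keep <- !is.na(tile_idx)
  present <- present[keep]
  tile_idx <- tile_idx[keep]
  ord <- order(present)
  present <- present[ord]
  tile_idx <- tile_idx[ord]

  with_seed(derive_seed(seed, "pair", pair$pair_id), {
    background <- rpois(n_tiles, stain$background_rate)
    has_artifact <- runif(n_tiles) < stain$artifact_rate
    artifact <- integer(n_tiles)
    if (any(has_artifact))
      artifact[has_artifact] <-
        1L + rpois(sum(has_artifact), stain$artifact_px_mean - 1)
    k <- length(present)
    if (k > 0L) {
      fn <- runif(k) < stain$false_negative_rate
      px <- draw_cell_pixels(k, stain)
      px[fn] <- 0L
    } else {
      px <- integer(0)
    }
    list(background = background,
         artifact = artifact,
         cell = data.frame(cell = present, tile = tile_idx,
                           px = as.integer(px)))
  })
}

#' Assign image-analysis weights (and ground-truth counts) to all tiles
#'
#' Emulates the automated weighting step: for every tile of every sampled
#' pair, the weight \code{z_i} is the integer number of "specific-colour"
#' pixels -- contributions from each in-slab, non-false-negative cell profile,
#' plus a background draw, plus an occasional artifact blob. The ground-truth
#' bidirectional disector count is computed alongside and stored in the
#' \code{count} column (it is what an expert would count on the presented
#' tiles; the weighting itself never uses it).
#'
#' @param tiles tile table from \code{\link{tessellate_tiles}}.
#' @param organ an \code{organ_truth}.
#' @param sectioning a \code{sectioning}.
#' @param pairs pair table from \code{\link{sample_pairs}}.
#' @param stain a \code{\link{stain_model}}.
#' @param seed integer seed; the same seed reproduces the weights exactly.
#' @return the tile table with \code{weight_px}, \code{q_forward},
#'   \code{q_backward}, \code{count} and \code{usable} columns appended.
#' @export
assign_weights <- function(tiles, organ, sectioning, pairs, stain, seed) {
  stopifnot(inherits(stain, "stain_model"))
  tiles$weight_px <- 0L
  for (k in seq_len(nrow(pairs))) {
    sel <- which(tiles$pair_id == pairs$pair_id[k])
    comp <- pair_weight_draws(tiles[sel, , drop = FALSE], organ, sectioning,
                              pairs[k, , drop = FALSE], stain, seed)
    w <- comp$background + comp$artifact
    if (nrow(comp$cell) > 0L) {
      add <- tapply(comp$cell$px, comp$cell$tile, sum)
      w[as.integer(names(add))] <- w[as.integer(names(add))] + as.integer(add)
    }
    tiles$weight_px[sel] <- as.integer(w)
  }
  tiles <- census_counts(tiles, organ, sectioning, pairs)
  tiles$usable <- 1L
  tiles
}

#' Render one tile as a binary stain raster
#'
#' Optional raster path mirroring the real workflow, where the weight is the
#' pixel count of a thresholded image: draws the same per-tile weight
#' components as \code{\link{assign_weights}} (same \code{seed}), then places
#' exactly that many positive pixels -- compact discs around each cell
#' profile, a blob for an artifact, scattered background pixels. The
#' positive-pixel count of the mask equals the tabulated \code{weight_px}.
#'
#' @param tile one row of the tile table.
#' @param organ,sectioning,pairs,stain,seed as in \code{\link{assign_weights}}.
#' @param px_per_um raster resolution (default 1 pixel per um).
#' @return an object of class \code{tile_raster}: integer 0/1 matrix
#'   \code{mask} (rows = y), \code{tile_id}, \code{weight_px}.
#' @export
render_tile_raster <- function(tile, organ, sectioning, pairs, stain, seed,
                               px_per_um = 1) {
  pair <- pairs[pairs$pair_id == tile$pair_id, , drop = FALSE]
  if (nrow(pair) != 1L) abort_config("tile's pair_id not found in pairs")
  # all tiles of this pair, in tessellation order, to replay the pair stream
  all_tiles <- tessellate_tiles(organ, pair, tile$frame_um)
  comp <- pair_weight_draws(all_tiles, organ, sectioning, pair, stain, seed)
  f <- tile$frame_um
  ix <- floor(round(tile$x_um / f, 9))
  iy <- floor(round(tile$y_um / f, 9))
  nx <- floor(organ$cross_section_w_um / f)
  this <- iy * nx + ix + 1L

  side <- as.integer(round(f * px_per_um))
  mask <- matrix(0L, nrow = side, ncol = side)
  npx <- side * side
  gx <- (col(mask) - 0.5) / px_per_um   # tile-local um coords of pixel centres
  gy <- (row(mask) - 0.5) / px_per_um

  place_nearest <- function(mask, cx, cy, k) {
    if (k <= 0) return(mask)
    d2 <- (gx - cx)^2 + (gy - cy)^2
    free <- which(mask == 0L)
    take <- free[order(d2[free])][seq_len(min(k, length(free)))]
    mask[take] <- 1L
    mask
  }

  with_seed(derive_seed(seed, "raster", pair$pair_id, this), {
    cc <- comp$cell[comp$cell$tile == this, , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      cell <- organ$cells[cc$cell[j], ]
      mask <- place_nearest(mask, cell$x_um - tile$x_um,
                            cell$y_um - tile$y_um, cc$px[j])
    }
    if (comp$artifact[this] > 0L)
      mask <- place_nearest(mask, runif(1, 0, f), runif(1, 0, f),
                            comp$artifact[this])
    bg <- comp$background[this]
    if (bg > 0L) {
      free <- which(mask == 0L)
      mask[free[sample.int(length(free), min(bg, length(free)))]] <- 1L
    }
  })
  expected <- comp$background[this] + comp$artifact[this] +
    sum(comp$cell$px[comp$cell$tile == this])
  if (expected > npx)
    warning("tile raster saturated: ", expected, " pixels requested, ",
            npx, " available")
  structure(list(mask = mask, tile_id = tile$tile_id,
                 weight_px = as.integer(sum(mask))),
            class = "tile_raster")
}

#' @export
print.tile_raster <- function(x, ...) {
  cat("tile raster ", nrow(x$mask), "x", ncol(x$mask), " px, ",
      x$weight_px, " specific pixels (tile ", x$tile_id, ")\n", sep = "")
  invisible(x)
}

#' Write / read a tile raster as an 8-bit grayscale PNG
#'
#' Lossless round trip: the positive-pixel count is preserved exactly.
#'
#' @param raster a \code{tile_raster}.
#' @param path file path.
#' @return \code{write_tile_raster} returns \code{path} invisibly;
#'   \code{read_tile_raster_mask} the 0/1 integer mask.
#' @export
write_tile_raster <- function(raster, path) {
  stopifnot(inherits(raster, "tile_raster"))
  png::writePNG(raster$mask * 1.0, path)
  invisible(path)
}

#' @rdname write_tile_raster
#' @export
read_tile_raster_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow = nrow(m))
}
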