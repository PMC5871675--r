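# Smooth arrangement of the supersection tiles and probability-proportional-
# to-weight systematic sampling.

#' Combine a weighted tile table into a supersection
#'
#' The supersection is the union of all tiles of all sampled section pairs of
#' one subject, treated as a single sampling frame. It carries the total
#' specific-pixel count \code{Z} and the combined area \code{SumA}.
#'
#' @param tiles weighted tile table (from \code{\link{assign_weights}} or
#'   \code{\link{read_tile_table}}).
#' @param tile_fraction fraction of the tessellation retained by
#'   \code{\link{subsample_tiles}} (1 = all tiles).
#' @return an object of class \code{supersection}: \code{tiles}, \code{Z},
#'   \code{SumA} (um^2), \code{n_tiles}, \code{tile_fraction}.
#' @export
build_supersection <- function(tiles, tile_fraction = 1) {
  if (is.null(tiles$weight_px))
    abort_config("tile table has no weight_px column; assign weights first")
  check_scalar_number(tile_fraction, "tile_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  structure(list(tiles = tiles,
                 Z = sum(tiles$weight_px),
                 SumA = nrow(tiles) * tiles$frame_um[1L]^2,
                 n_tiles = nrow(tiles),
                 tile_fraction = tile_fraction),
            class = "supersection")
}

#' @export
print.supersection <- function(x, ...) {
  cat("Supersection: ", x$n_tiles, " tiles, SumA = ",
      format(x$SumA, big.mark = ","), " um^2, Z = ",
      format(x$Z, big.mark = ","), " specific pixels",
      if (x$tile_fraction < 1)
        paste0(" (tile fraction ", x$tile_fraction, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Smooth (unimodal) arrangement of tiles by weight
#'
#' Sorts the tiles by increasing weight (ties broken by pair, then spatial
#' position, for determinism) and deals them into an ascending limb (odd
#' ranks) followed by a reversed descending limb (even ranks), producing a
#' smooth, symmetric, unimodal weight sequence. Arranging the sampling axis
#' this way reduces the variance of the subsequent systematic sample.
#'
#' @param tiles weighted tile table or a \code{supersection}.
#' @return an object of class \code{smooth_order}: the reordered \code{tiles},
#'   total weight \code{Z}, and the permutation \code{perm} applied.
#' @export
#' @examples
#' t3 <- data.frame(tile_id = 1:3, pair_id = 1, x_um = 0, y_um = 0,
#'                  frame_um = 200, weight_px = c(3, 1, 2))
#' smooth_order(t3)$tiles$weight_px  # 1 3 2
smooth_order <- function(tiles) {
  if (inherits(tiles, "supersection")) tiles <- tiles$tiles
  if (nrow(tiles) < 1L) abort_config("smooth_order needs at least one tile")
  if (is.null(tiles$weight_px)) abort_config("tiles have no weight_px column")
  o <- order(tiles$weight_px, tiles$pair_id, tiles$y_um, tiles$x_um)
  m <- length(o)
  ranks <- seq_len(m)
  asc <- o[ranks %% 2L == 1L]
  desc <- rev(o[ranks %% 2L == 0L])
  perm <- c(asc, desc)
  out <- tiles[perm, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(tiles = out, Z = sum(out$weight_px), perm = perm),
            class = "smooth_order")
}

#' @export
print.smooth_order <- function(x, ...) {
  cat("Smooth arrangement of", nrow(x$tiles), "tiles, Z =", x$Z,
      "specific pixels\n")
  invisible(x)
}

#' One systematic sample with probability proportional to weight
#'
#' Stacks the arranged tiles on a cumulative weight axis of total length
#' \code{Z} and draws \code{n} equidistant sampling lines at
#' `u + k * T_z, k = 0..n-1`, with \code{T_z = Z/n} and random start
#' `0 < u <= T_z`. The line falling in a tile's cumulative interval
#' `(c_i, c_i + z_i]` samples that tile; each tile is sampled with
#' probability `p_i = z_i / T_z`, so zero-weight tiles are never sampled,
#' and a tile heavier than \code{T_z} can be hit by several lines (one
#' multiplicity per line).
#'
#' @param order a \code{smooth_order}.
#' @param n number of tiles (lines) per sampling.
#' @param u explicit random start in `(0, T_z]`; mainly for oracles/replays.
#' @param seed used to draw \code{u} when it is not supplied.
#' @return an object of class \code{sampling_repetition}: data.frame
#'   \code{hits} (\code{tile_id, multiplicity, weight_px, p}), plus
#'   \code{n, Z, T_z, u, rescale}.
#' @export
pps_systematic_draw <- function(order, n, u = NULL, seed = NULL) {
  stopifnot(inherits(order, "smooth_order"))
  check_scalar_number(n, "n", lower = 1)
  if (order$Z <= 0)
    pp_stop("no specific pixels anywhere in the supersection (Z = 0)",
            class = "pp_no_signal")
  T_z <- order$Z / n
  if (is.null(u)) {
    if (is.null(seed)) abort_config("either u or seed must be supplied")
    u <- with_seed(derive_seed(seed, "u"), T_z * (1 - runif(1)))
  }
  check_scalar_number(u, "u", lower = 0, upper = T_z, strict_lower = TRUE)
  w <- order$tiles$weight_px
  pos <- which(w > 0)
  cum <- cumsum(w[pos])
  lines <- u + (seq_len(n) - 1) * T_z
  # left-open intervals (c, c + z]: index i with cum[i-1] < line <= cum[i]
  hit <- findInterval(lines, cum, left.open = TRUE) + 1L
  hit[hit > length(pos)] <- length(pos)   # guard fp overshoot at line == Z
  idx <- pos[hit]
  tab <- table(idx)
  sel <- as.integer(names(tab))
  hits <- data.frame(tile_id = order$tiles$tile_id[sel],
                     multiplicity = as.integer(tab),
                     weight_px = order$tiles$weight_px[sel],
                     p = order$tiles$weight_px[sel] / T_z)
  rownames(hits) <- NULL
  structure(list(hits = hits, n = as.integer(n), Z = order$Z, T_z = T_z,
                 u = u, rescale = 1),
            class = "sampling_repetition")
}

#' @export
print.sampling_repetition <- function(x, ...) {
  cat("PPS systematic sample: n =", x$n, "lines, T_z =", signif(x$T_z, 6),
      "px, u =", signif(x$u, 6), "->", nrow(x$hits), "distinct tiles\n")
  invisible(x)
}

#' Enumerate all integer random starts of a PPS systematic sample
#'
#' Oracle mode for exact design checks: with integer weights and \code{n}
#' dividing \code{Z} (so that \code{T_z} is an integer), the draws for
#' `u = 1, ..., T_z` enumerate the whole design; averaging any
#' Horvitz-Thompson total over them reproduces the true supersection count
#' exactly.
#'
#' @param order a \code{smooth_order} with integer weights.
#' @param n sample size; must divide \code{Z}.
#' @return list of \code{sampling_repetition}, one per integer start.
#' @export
enumerate_pps_starts <- function(order, n) {
  stopifnot(inherits(order, "smooth_order"))
  if (any(order$tiles$weight_px != round(order$tiles$weight_px)))
    abort_config("enumeration oracle requires integer weights")
  if (order$Z %% n != 0)
    abort_config("enumeration oracle requires n to divide Z (Z = ",
                 order$Z, ", n = ", n, ")")
  T_z <- order$Z / n
  lapply(seq_len(T_z), function(u) pps_systematic_draw(order, n, u = u))
}

#' The three independent samplings of the proportionator
#'
#' Draws three mutually independent systematic PPS samples (independent
#' random starts from one seeded stream) from the same smooth arrangement.
#' The union of the sampled tiles is what is presented for counting; the
#' tripartition is what makes the direct CE estimate possible.
#'
#' @param order a \code{smooth_order}.
#' @param n tiles per sampling (e.g. 22, giving 66 presented tiles).
#' @param seed integer seed.
#' @param repetitions number of independent samplings (default 3).
#' @return an object of class \code{tripartite_sample}: list
#'   \code{repetitions}, data.frame \code{presented} (one row per hit with a
#'   repetition label), \code{n, Z, T_z, us, seed}.
#' @export
tripartite_sample <- function(order, n, seed, repetitions = 3) {
  check_scalar_number(repetitions, "repetitions", lower = 2)
  if (order$Z <= 0)
    pp_stop("no specific pixels anywhere in the supersection (Z = 0)",
            class = "pp_no_signal")
  T_z <- order$Z / n
  us <- with_seed(derive_seed(seed, "tripartite"),
                  T_z * (1 - runif(repetitions)))
  reps <- lapply(us, function(u) pps_systematic_draw(order, n, u = u))
  presented <- do.call(rbind, lapply(seq_along(reps), function(r) {
    h <- reps[[r]]$hits
    h$repetition <- r
    h
  }))
  rownames(presented) <- NULL
  structure(list(repetitions = reps, presented = presented,
                 n = as.integer(n), Z = order$Z, T_z = T_z, us = us,
                 seed = seed),
            class = "tripartite_sample")
}

#' @export
print.tripartite_sample <- function(x, ...) {
  cat("Tripartite proportionator sample:", length(x$repetitions),
      "independent samplings of", x$n, "tiles =",
      sum(x$presented$multiplicity), "hits presented for counting\n")
  invisible(x)
}

#' Systematic uniform subsample of the tile tessellation
#'
#' When the number of tiles is exorbitant, a known fraction can be retained
#' before weighting; the estimator later divides by this tile sampling
#' fraction. For sparse populations the retained number of tiles should stay
#' large (a warning is issued below 10,000 when \code{sparse = TRUE}).
#'
#' @param tiles tile table.
#' @param tile_fraction fraction in (0, 1].
#' @param seed seed for the random phase.
#' @param sparse is the target population sparse? (controls the warning).
#' @return the subsampled tile table; attribute \code{tile_fraction}.
#' @export
subsample_tiles <- function(tiles, tile_fraction, seed, sparse = TRUE) {
  check_scalar_number(tile_fraction, "tile_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (tile_fraction == 1) {
    attr(tiles, "tile_fraction") <- 1
    return(tiles)
  }
  n <- nrow(tiles)
  period <- 1 / tile_fraction
  phase <- with_seed(derive_seed(seed, "tilefrac"), runif(1, 0, period))
  take <- unique(pmin(n, ceiling(seq(phase + 1e-12, n, by = period))))
  out <- tiles[take, , drop = FALSE]
  rownames(out) <- NULL
  if (sparse && nrow(out) < 10000)
    warning("only ", nrow(out), " tiles retained; for a sparse population ",
            "the sampled number of tiles should not be below 10,000")
  attr(out, "tile_fraction") <- tile_fraction
  out
}
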