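# Physical disector counting against ground truth, the unbiased counting
# frame, and the non-useable tile policy.

# half-open slab [lo, hi) of a 1-based section index
slab_bounds <- function(section, thickness_um) {
  list(lo = (section - 1) * thickness_um, hi = section * thickness_um)
}

# closed sphere [z - r, z + r] intersects half-open slab [lo, hi)
sphere_intersects_slab <- function(z, r, lo, hi) {
  (z + r) >= lo & (z - r) < hi
}

#' Unbiased counting frame rule
#'
#' The two-dimensional unbiased frame is realised on the cell profile
#' centroid with half-open intervals: a centroid is sampled by the tile at
#' `(x0, y0)` iff it lies in `[x0, x0 + f) x [y0, y0 + f)`. The left and
#' bottom edges are inclusion edges, the right and top edges exclusion
#' edges, so every point of the plane is sampled by exactly one tile of the
#' tessellation.
#'
#' @param x,y profile centroid coordinates (um); vectorised.
#' @param frame_x,frame_y lower-left corner of the frame (um).
#' @param frame_um frame side length (um).
#' @return logical vector: sampled by this frame?
#' @export
#' @examples
#' apply_unbiased_frame(0, 0, 0, 0, 200)    # TRUE: inclusion edge
#' apply_unbiased_frame(200, 0, 0, 0, 200)  # FALSE: exclusion edge
apply_unbiased_frame <- function(x, y, frame_x, frame_y, frame_um) {
  x >= frame_x & x < frame_x + frame_um &
    y >= frame_y & y < frame_y + frame_um
}

#' Bidirectional physical disector count for one tile
#'
#' Counts nucleus tops and bottoms in a disector pair: forward, a cell is
#' counted when its nucleus intersects the counting slab, is sampled by the
#' tile's unbiased frame, and does not intersect the look-up slab; backward,
#' the section roles are swapped. A nucleus spanning both slabs is counted in
#' neither direction. \code{x_i = q_forward + q_backward}.
#'
#' @param tile one row of a tile table (needs \code{x_um, y_um, frame_um}).
#' @param pair one row of a pair table (needs \code{section, lookup}).
#' @param organ an \code{organ_truth}.
#' @param sectioning a \code{sectioning} (for the slab thickness).
#' @return an object of class \code{tile_count}: \code{q_forward},
#'   \code{q_backward}, \code{x}.
#' @export
count_tile <- function(tile, pair, organ, sectioning) {
  t_um <- sectioning$thickness_um
  cells <- organ$cells
  if (nrow(cells) == 0L)
    return(structure(list(q_forward = 0L, q_backward = 0L, x = 0L),
                     class = "tile_count"))
  s1 <- slab_bounds(pair$section, t_um)
  s2 <- slab_bounds(pair$lookup, t_um)
  r <- cells$nucleus_diameter_um / 2
  in1 <- sphere_intersects_slab(cells$z_um, r, s1$lo, s1$hi)
  in2 <- sphere_intersects_slab(cells$z_um, r, s2$lo, s2$hi)
  framed <- apply_unbiased_frame(cells$x_um, cells$y_um,
                                 tile$x_um, tile$y_um, tile$frame_um)
  qf <- sum(framed & in1 & !in2)
  qb <- sum(framed & in2 & !in1)
  structure(list(q_forward = as.integer(qf), q_backward = as.integer(qb),
                 x = as.integer(qf + qb)),
            class = "tile_count")
}

#' @export
print.tile_count <- function(x, ...) {
  cat("disector count: forward", x$q_forward, "+ backward", x$q_backward,
      "=", x$x, "\n")
  invisible(x)
}

# Ground-truth disector census for a whole tile table (cell-centric, fast).
# Returns `tiles` with q_forward, q_backward and count columns appended.
census_counts <- function(tiles, organ, sectioning, pairs) {
  f <- tiles$frame_um[1L]
  t_um <- sectioning$thickness_um
  tiles$q_forward <- 0L
  tiles$q_backward <- 0L
  cells <- organ$cells
  if (nrow(cells) > 0L) {
    tkey <- paste(tiles$pair_id,
                  floor(round(tiles$x_um / f, 9)),
                  floor(round(tiles$y_um / f, 9)))
    r <- cells$nucleus_diameter_um / 2
    cix <- floor(cells$x_um / f)
    ciy <- floor(cells$y_um / f)
    for (k in seq_len(nrow(pairs))) {
      s1 <- slab_bounds(pairs$section[k], t_um)
      s2 <- slab_bounds(pairs$lookup[k], t_um)
      in1 <- sphere_intersects_slab(cells$z_um, r, s1$lo, s1$hi)
      in2 <- sphere_intersects_slab(cells$z_um, r, s2$lo, s2$hi)
      rel <- which(in1 | in2)
      if (length(rel) == 0L) next
      key <- paste(pairs$pair_id[k], cix[rel], ciy[rel])
      idx <- match(key, tkey)             # NA: centroid in a dropped edge strip
      ok <- !is.na(idx)
      fwd <- in1[rel] & !in2[rel]
      bwd <- in2[rel] & !in1[rel]
      for (j in which(ok & fwd))
        tiles$q_forward[idx[j]] <- tiles$q_forward[idx[j]] + 1L
      for (j in which(ok & bwd))
        tiles$q_backward[idx[j]] <- tiles$q_backward[idx[j]] + 1L
    }
  }
  tiles$count <- tiles$q_forward + tiles$q_backward
  tiles
}

#' Handle non-useable tiles in a sampling repetition
#'
#' Tiles with sectioning or staining artifacts that prevent counting can be
#' flagged unusable. Two substitute policies are provided (the original
#' procedure for such tiles is not part of this package's sources):
#' \describe{
#'   \item{exclude_rescale}{drop the unusable hits and rescale the repetition
#'     total by \code{n / (n - n_unusable)} (default);}
#'   \item{impute_ratio}{replace the count of each unusable hit by
#'     \code{z_i * (sum(x) / sum(z))} over the usable hits of the repetition.}
#' }
#'
#' @param repetition a \code{sampling_repetition} whose hits carry \code{x}
#'   and \code{usable} columns (see \code{\link{attach_counts}}).
#' @param policy \code{"exclude_rescale"} or \code{"impute_ratio"}.
#' @return the adjusted repetition; its \code{rescale} field and
#'   \code{policy} field record what was done.
#' @export
apply_nonusable_policy <- function(repetition,
                                   policy = c("exclude_rescale",
                                              "impute_ratio")) {
  policy <- match.arg(policy)
  stopifnot(inherits(repetition, "sampling_repetition"))
  hits <- repetition$hits
  if (is.null(hits$usable)) hits$usable <- 1L
  if (is.null(hits$x))
    abort_runtime("repetition has no counts; attach_counts() first")
  usable <- hits$usable > 0
  if (!any(usable))
    pp_stop("all hits in the repetition are unusable; estimation impossible",
            class = "pp_estimation_impossible")
  if (all(usable)) {
    repetition$policy <- policy
    return(repetition)
  }
  if (policy == "exclude_rescale") {
    n_tot <- sum(hits$multiplicity)
    n_un <- sum(hits$multiplicity[!usable])
    repetition$hits <- hits[usable, , drop = FALSE]
    repetition$rescale <- repetition$rescale * n_tot / (n_tot - n_un)
  } else {
    ratio <- sum(hits$multiplicity[usable] * hits$x[usable]) /
      sum(hits$multiplicity[usable] * hits$weight_px[usable])
    if (!is.finite(ratio))
      pp_stop("impute_ratio: usable hits have zero total weight",
              class = "pp_estimation_impossible")
    hits$x[!usable] <- hits$weight_px[!usable] * ratio
    repetition$hits <- hits
  }
  repetition$policy <- policy
  repetition
}
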