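#' Stain / image-analysis weight model
#'
#' Describes how many "specific-colour" pixels the image-analysis step
#' records per tile. Each cell profile present in a disector section
#' contributes a zero-truncated Poisson number of specific pixels (mean
#' \code{pixels_per_cell_mean}, so an in-section cell always contributes at
#' least one pixel unless it is a staining false negative). On top of that,
#' every tile receives a Poisson background of non-specific pixels, and with
#' probability \code{artifact_rate} a large spurious blob of stain-trapping
#' pixels -- the "high weight / low count" failure mode that degrades (but
#' does not bias) the estimator.
#'
#' @param pixels_per_cell_mean expected specific pixels contributed by one
#'   in-section cell profile (>= 1).
#' @param background_rate expected non-specific pixels per tile (>= 0).
#' @param artifact_rate probability a tile receives a spurious high-weight
#'   blob, in `[0, 1]`.
#' @param artifact_px_mean expected size (pixels) of an artifact blob (>= 1).
#' @param false_negative_rate probability a cell contributes zero pixels
#'   (staining misses the cell), in `[0, 1]`.
#' @param pixel_noise_dispersion extra-Poisson dispersion of the per-cell
#'   pixel draw; 0 gives a (shifted) Poisson, larger values a negative
#'   binomial with that dispersion.
#' @return an object of class \code{stain_model}.
#' @export
#' @examples
#' stain_model(pixels_per_cell_mean = 20, background_rate = 0.05)
stain_model <- function(pixels_per_cell_mean = 20,
                        background_rate = 0.05,
                        artifact_rate = 0,
                        artifact_px_mean = 300,
                        false_negative_rate = 0,
                        pixel_noise_dispersion = 0) {
  check_scalar_number(pixels_per_cell_mean, "pixels_per_cell_mean", lower = 1)
  check_scalar_number(background_rate, "background_rate", lower = 0)
  check_scalar_number(artifact_rate, "artifact_rate", lower = 0, upper = 1)
  check_scalar_number(artifact_px_mean, "artifact_px_mean", lower = 1)
  check_scalar_number(false_negative_rate, "false_negative_rate",
                      lower = 0, upper = 1)
  check_scalar_number(pixel_noise_dispersion, "pixel_noise_dispersion",
                      lower = 0)
  structure(list(pixels_per_cell_mean = pixels_per_cell_mean,
                 background_rate = background_rate,
                 artifact_rate = artifact_rate,
                 artifact_px_mean = artifact_px_mean,
                 false_negative_rate = false_negative_rate,
                 pixel_noise_dispersion = pixel_noise_dispersion),
            class = "stain_model")
}

# per-cell specific pixel draw: zero-truncated so an in-section,
# non-false-negative cell always leaves a mark (keeps HT unbiasedness exact)
draw_cell_pixels <- function(k, stain) {
  if (k == 0L) return(integer(0))
  m <- stain$pixels_per_cell_mean - 1
  if (stain$pixel_noise_dispersion > 0) {
    1L + rnbinom(k, mu = m, size = 1 / stain$pixel_noise_dispersion)
  } else {
    1L + rpois(k, m)
  }
}

#' Generate a virtual organ with a sparse, clustered cell population
#'
#' Places \code{n_cells} mononucleated cells in a rectangular organ block by a
#' Neyman-Scott-type two-layer process: Poisson cluster parents whose axial
#' position is biased towards the two end faces of the organ (emulating a
#' population concentrated near the endplates), with Gaussian offspring
#' scattered around each parent. The exact ground-truth count is recorded, and
#' every nucleus lies entirely inside the axial extent of the block so that an
#' exhaustive disector census conserves the total.
#'
#' @param height_um organ height H perpendicular to the sectioning plane (um).
#' @param width_um,depth_um rectangular cross-section dimensions (um); the
#'   cross-sectional area A = width * depth is constant along the axis.
#' @param n_cells exact number of cells to place (the ground truth N).
#' @param nucleus_diameter_um mean nucleus diameter (um); the nucleus is the
#'   unique counting feature.
#' @param nucleus_diameter_sd_um between-cell SD of the diameter (um).
#' @param parent_mean expected number of cluster parents (Poisson, min 1).
#' @param cluster_sd_um SD of the Gaussian offspring scatter around a parent.
#' @param endplate_fraction axial fraction at each end of the organ counted as
#'   the "endplate" zone (default 0.15).
#' @param endplate_weight probability that a cluster parent is placed in one
#'   of the two endplate zones rather than uniformly (clustering strength; a
#'   free parameter of the simulator).
#' @param seed integer seed; the same seed reproduces the organ exactly.
#' @return an object of class \code{organ_truth}: organ dimensions, a
#'   data.frame \code{cells} with columns \code{x_um, y_um, z_um,
#'   nucleus_diameter_um}, the ground truth \code{n_true}, and the seed.
#' @export
#' @examples
#' org <- generate_organ(n_cells = 50, seed = 1)
#' org$n_true
generate_organ <- function(height_um = 3000,
                           width_um = 3200,
                           depth_um = 3200,
                           n_cells = 50,
                           nucleus_diameter_um = 8,
                           nucleus_diameter_sd_um = 1,
                           parent_mean = 8,
                           cluster_sd_um = 150,
                           endplate_fraction = 0.15,
                           endplate_weight = 0.7,
                           seed = 1) {
  check_scalar_number(height_um, "height_um", lower = 0, strict_lower = TRUE)
  check_scalar_number(width_um, "width_um", lower = 0, strict_lower = TRUE)
  check_scalar_number(depth_um, "depth_um", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_cells, "n_cells", lower = 0)
  check_scalar_number(nucleus_diameter_um, "nucleus_diameter_um",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(endplate_fraction, "endplate_fraction",
                      lower = 0, upper = 0.5)
  check_scalar_number(endplate_weight, "endplate_weight",
                      lower = 0, upper = 1)
  if (nucleus_diameter_um >= height_um)
    abort_config("nucleus_diameter_um must be smaller than height_um")

  cells <- with_seed(seed, {
    if (n_cells == 0) {
      data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 nucleus_diameter_um = numeric(0))
    } else {
      n_par <- max(1L, rpois(1L, parent_mean))
      in_end <- runif(n_par) < endplate_weight
      ez <- endplate_fraction * height_um
      pz <- ifelse(in_end,
                   ifelse(runif(n_par) < 0.5,
                          runif(n_par, 0, ez),
                          runif(n_par, height_um - ez, height_um)),
                   runif(n_par, 0, height_um))
      px <- runif(n_par, 0, width_um)
      py <- runif(n_par, 0, depth_um)

      parent <- sample.int(n_par, n_cells, replace = TRUE)
      d <- rnorm(n_cells, nucleus_diameter_um, nucleus_diameter_sd_um)
      d <- pmin(pmax(d, nucleus_diameter_um / 2), nucleus_diameter_um * 1.5)
      r <- d / 2
      x <- px[parent] + rnorm(n_cells, 0, cluster_sd_um)
      y <- py[parent] + rnorm(n_cells, 0, cluster_sd_um)
      z <- pz[parent] + rnorm(n_cells, 0, cluster_sd_um)
      # redraw until the centroid is inside the block and the nucleus lies
      # entirely within the axial extent (exact census conservation)
      for (iter in 1:200) {
        bad <- x < 0 | x >= width_um | y < 0 | y >= depth_um |
          z < r | z > height_um - r
        if (!any(bad)) break
        k <- sum(bad)
        x[bad] <- px[parent[bad]] + rnorm(k, 0, cluster_sd_um)
        y[bad] <- py[parent[bad]] + rnorm(k, 0, cluster_sd_um)
        z[bad] <- pz[parent[bad]] + rnorm(k, 0, cluster_sd_um)
      }
      # pathological configs (huge clusters, tiny organ): clamp the stragglers
      x <- pmin(pmax(x, 0), width_um * (1 - 1e-9))
      y <- pmin(pmax(y, 0), depth_um * (1 - 1e-9))
      z <- pmin(pmax(z, r), height_um - r - 1e-9)
      data.frame(x_um = x, y_um = y, z_um = z, nucleus_diameter_um = d)
    }
  })

  structure(list(height_um = height_um,
                 cross_section_w_um = width_um,
                 cross_section_d_um = depth_um,
                 cells = cells,
                 n_true = nrow(cells),
                 seed = seed),
            class = "organ_truth")
}

#' @export
print.organ_truth <- function(x, ...) {
  cat("Virtual organ:", x$height_um, "um (H) x",
      x$cross_section_w_um, "x", x$cross_section_d_um, "um cross section\n")
  cat("  cross-sectional area A =",
      format(x$cross_section_w_um * x$cross_section_d_um, big.mark = ","),
      "um^2\n")
  cat("  ground-truth cells n_true =", x$n_true, " (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Exhaustively section an organ into serial slabs
#'
#' Cuts the organ perpendicular to its axis into \code{floor(H/t)} half-open
#' slabs `[k*t, (k+1)*t)`; a trailing remnant thinner than \code{t} is
#' discarded (and reported via a message).
#'
#' @param organ an \code{organ_truth}.
#' @param thickness_um section thickness t in um (0 < t < H).
#' @return an object of class \code{sectioning}: \code{thickness_um},
#'   \code{n_sections}, \code{remnant_um}.
#' @export
#' @examples
#' section_organ(generate_organ(seed = 1), 6)$n_sections  # 500
section_organ <- function(organ, thickness_um) {
  stopifnot(inherits(organ, "organ_truth"))
  check_scalar_number(thickness_um, "thickness_um",
                      lower = 0, strict_lower = TRUE)
  if (thickness_um >= organ$height_um)
    abort_config("section thickness (", thickness_um,
                 " um) must be smaller than the organ height (",
                 organ$height_um, " um)")
  n <- floor(organ$height_um / thickness_um)
  remnant <- organ$height_um - n * thickness_um
  if (remnant > 1e-9)
    message("section_organ: discarding a ", signif(remnant, 4),
            " um remnant thinner than one section")
  structure(list(thickness_um = thickness_um,
                 n_sections = as.integer(n),
                 remnant_um = remnant),
            class = "sectioning")
}

#' @export
print.sectioning <- function(x, ...) {
  cat("Exhaustive sectioning:", x$n_sections, "sections of",
      x$thickness_um, "um")
  if (x$remnant_um > 1e-9) cat(" (+", signif(x$remnant_um, 4), "um remnant)")
  cat("\n")
  invisible(x)
}

#' Write / read organ ground truth as JSON
#'
#' @param organ an \code{organ_truth}.
#' @param path file path.
#' @return \code{write_organ_json} returns \code{path} invisibly;
#'   \code{read_organ_json} returns an \code{organ_truth}.
#' @export
write_organ_json <- function(organ, path) {
  stopifnot(inherits(organ, "organ_truth"))
  obj <- unclass(organ)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_organ_json
#' @export
read_organ_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$cells <- as.data.frame(obj$cells)
  if (nrow(obj$cells) == 0L)
    obj$cells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                            z_um = numeric(0),
                            nucleus_diameter_um = numeric(0))
  structure(obj[c("height_um", "cross_section_w_um", "cross_section_d_um",
                  "cells", "n_true", "seed")],
            class = "organ_truth")
}
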