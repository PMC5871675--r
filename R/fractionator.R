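#' Plan a fractionator section-sampling design
#'
#' Given the organ height, section thickness and a target number of serial
#' section pairs, fixes the integer sampling interval \code{si} (every
#' si-th section starts a disector pair) and hence the known, constant
#' section sampling fraction \code{sf = 1/si}. For a 3000 um organ cut at
#' 6 um with 20 target pairs: 500 sections, si = 25, sf = 1/25.
#'
#' @param height_um organ height H (um).
#' @param thickness_um section thickness t (um).
#' @param n_pairs target number of section pairs ns.
#' @return an object of class \code{fractionator_design} with fields
#'   \code{n_sections}, \code{ns}, \code{si}, \code{sf}.
#' @export
#' @examples
#' plan_design(3000, 6, 20)$si  # 25
plan_design <- function(height_um, thickness_um, n_pairs) {
  check_scalar_number(height_um, "height_um", lower = 0, strict_lower = TRUE)
  check_scalar_number(thickness_um, "thickness_um", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(n_pairs, "n_pairs", lower = 1)
  n_sections <- floor(height_um / thickness_um)
  if (n_pairs > n_sections)
    abort_config("requested ", n_pairs, " section pairs but only ",
                 n_sections, " sections are available")
  si <- as.integer(floor(n_sections / n_pairs))
  structure(list(n_sections = as.integer(n_sections),
                 ns = as.integer(n_pairs),
                 si = si,
                 sf = 1 / si),
            class = "fractionator_design")
}

#' @export
print.fractionator_design <- function(x, ...) {
  cat("Fractionator design: ", x$n_sections, " sections, target ns = ",
      x$ns, " pairs, si = ", x$si, ", sf = 1/", x$si, "\n", sep = "")
  invisible(x)
}

#' Draw the systematic uniform random sample of section pairs
#'
#' The first counting section is taken at a random start R in the first
#' sampling period (1 <= R <= si); every further pair lies si sections later,
#' each with its consecutive section as the look-up. A pair whose look-up
#' section would fall beyond the last section is dropped (with a message).
#'
#' @param design a \code{fractionator_design}.
#' @param R explicit random start (1-based); if \code{NULL}, drawn uniformly
#'   on `{1, ..., si}` from \code{seed}.
#' @param seed seed used when \code{R} is not supplied.
#' @return data.frame with columns \code{pair_id}, \code{section} (counting
#'   section, 1-based), \code{lookup}; attribute \code{R}.
#' @export
#' @examples
#' d <- plan_design(3000, 6, 20)
#' sample_pairs(d, R = 1)$section  # 1, 26, ..., 476
sample_pairs <- function(design, R = NULL, seed = NULL) {
  stopifnot(inherits(design, "fractionator_design"))
  if (is.null(R)) {
    if (is.null(seed))
      abort_config("either R or seed must be supplied")
    R <- with_seed(derive_seed(seed, "R"), sample.int(design$si, 1L))
  }
  check_scalar_number(R, "R", lower = 1, upper = design$si)
  if (R != floor(R)) abort_config("R must be an integer")
  sections <- seq.int(R, design$n_sections, by = design$si)
  lookup <- sections + 1L
  keep <- lookup <= design$n_sections
  if (any(!keep))
    message("sample_pairs: dropping ", sum(!keep),
            " pair(s) whose look-up section falls beyond section ",
            design$n_sections)
  out <- data.frame(pair_id = seq_len(sum(keep)),
                    section = as.integer(sections[keep]),
                    lookup = as.integer(lookup[keep]))
  attr(out, "R") <- as.integer(R)
  out
}

#' Classical fractionator estimate of total number
#'
#' Under uniform sampling of a known fraction \code{sf} of the sections, the
#' estimate of the total is simply the (bidirectionally counted, already
#' halved) sample count divided by the fraction: N = count / sf.
#'
#' @param total_count total disector count over all tiles of all sampled
#'   sections, both directions, already divided by 2.
#' @param sf section sampling fraction (> 0).
#' @return the estimated total number.
#' @export
#' @examples
#' fractionator_estimate(118, 1 / 25)  # 2950
fractionator_estimate <- function(total_count, sf) {
  check_scalar_number(total_count, "total_count", lower = 0)
  check_scalar_number(sf, "sf", lower = 0, strict_lower = TRUE)
  total_count / sf
}

#' Coefficient of error of the uniform fractionator in a sparse population
#'
#' For sparse populations the sampled counts behave as independent rare
#' events, giving the well-known \code{CE = 1/sqrt(count)}.
#'
#' @param total_count total (halved) disector count; must be positive.
#' @return the coefficient of error.
#' @export
#' @examples
#' fractionator_ce(35)  # ~0.169
fractionator_ce <- function(total_count) {
  check_scalar_number(total_count, "total_count", lower = 0)
  if (total_count == 0)
    pp_stop("CE of the fractionator is undefined for a zero count",
            class = "pp_undefined_ce")
  1 / sqrt(total_count)
}
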