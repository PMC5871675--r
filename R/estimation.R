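# Horvitz-Thompson estimation, tripartite CE, group statistics and the
# PROBE design diagnostics.

#' Horvitz-Thompson contribution of one sampled tile
#'
#' A count of \code{x} cells observed in a tile that was sampled with
#' probability \code{p} contributes \code{x / p} to the total number in the
#' supersection: if a cell was sampled with probability 1/21 there must be
#' 21 such cells, on average.
#'
#' @param x disector count in the tile (>= 0).
#' @param p sampling probability of the tile (0 < p <= 1 for a single hit).
#' @return the contribution \code{X = x / p}.
#' @export
#' @examples
#' ht_contribution(2, 0.0496)  # 40.3
ht_contribution <- function(x, p) {
  if (any(x < 0)) abort_config("counts must be non-negative")
  if (any(p <= 0))
    pp_stop("sampling probability must be positive",
            class = "pp_invalid_probability")
  x / p
}

#' Attach disector counts to a sampling repetition
#'
#' @param repetition a \code{sampling_repetition}.
#' @param counts either a weighted tile table carrying \code{count} (the
#'   simulated path) or a data.frame \code{tile_id, x} and optionally
#'   \code{usable} (the user-supplied path).
#' @return the repetition with \code{x} and \code{usable} columns on its hits.
#' @export
attach_counts <- function(repetition, counts) {
  stopifnot(inherits(repetition, "sampling_repetition"))
  x_col <- if (!is.null(counts[["x"]])) counts[["x"]] else counts[["count"]]
  if (is.null(x_col) || is.null(counts[["tile_id"]]))
    abort_config("counts must provide tile_id and x (or count) columns")
  idx <- match(repetition$hits$tile_id, counts[["tile_id"]])
  if (anyNA(idx))
    pp_stop("missing counts for sampled tile(s) ",
            paste(repetition$hits$tile_id[is.na(idx)], collapse = ", "),
            "; estimation impossible", class = "pp_estimation_impossible")
  repetition$hits$x <- x_col[idx]
  repetition$hits$usable <-
    if (is.null(counts[["usable"]])) 1L
    else as.integer(counts[["usable"]][idx])
  if (anyNA(repetition$hits$x))
    pp_stop("NA counts for sampled tiles; estimation impossible",
            class = "pp_estimation_impossible")
  repetition
}

#' Horvitz-Thompson total of one sampling repetition
#'
#' Sums \code{multiplicity * x_i / p_i} over the hits (a tile hit by several
#' sampling lines contributes once per line), times any rescale factor left
#' by the non-useable-tile policy, giving one independent estimate
#' \code{X_r} of the total number of cells in the supersection.
#'
#' @param repetition a \code{sampling_repetition} with counts attached.
#' @return the repetition total \code{X_r}.
#' @export
repetition_total <- function(repetition) {
  stopifnot(inherits(repetition, "sampling_repetition"))
  h <- repetition$hits
  if (is.null(h$x))
    pp_stop("repetition has no counts; attach_counts() first",
            class = "pp_estimation_impossible")
  sum(h$multiplicity * ht_contribution(h$x, h$p)) * repetition$rescale
}

#' Per-animal estimate: total number and its coefficient of error
#'
#' Combines the independent repetition totals into the final estimate
#' \code{N = mean(X) / (2 * sf * tile_fraction) / units_per_animal}: the
#' factor 2 compensates for counting both directions of the disector, the
#' section sampling fraction \code{sf} scales the supersection up to the
#' organ, and \code{units_per_animal} divides a multi-unit specimen (e.g. 3
#' vertebrae) down to one unit. The imprecision is estimated directly from
#' the spread of the repetition totals: \code{CE = SEM(X_1..X_k)/mean(X)},
#' with the SEM using the sample SD (n-1 denominator).
#'
#' @param x_r numeric vector of repetition totals (length >= 2 for a CE).
#' @param sf section sampling fraction.
#' @param units_per_animal units pooled per specimen (default 1).
#' @param tile_fraction tile sampling fraction (default 1).
#' @return an object of class \code{animal_estimate}: \code{x_r},
#'   \code{mean_x}, \code{n_hat}, \code{ce}, \code{sf},
#'   \code{units_per_animal}, \code{tile_fraction}.
#' @export
#' @examples
#' est <- animal_estimate(c(224, 124, 214), sf = 1 / 25)
#' round(est$ce, 2)  # 0.17
animal_estimate <- function(x_r, sf, units_per_animal = 1,
                            tile_fraction = 1) {
  if (length(x_r) < 2L)
    abort_config("at least 2 repetition totals are needed for a CE")
  check_scalar_number(sf, "sf", lower = 0, strict_lower = TRUE)
  check_scalar_number(units_per_animal, "units_per_animal", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(tile_fraction, "tile_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  mean_x <- mean(x_r)
  if (mean_x == 0)
    pp_stop("mean repetition total is zero; CE undefined",
            class = "pp_undefined_ce")
  sem <- sd(x_r) / sqrt(length(x_r))
  structure(list(x_r = x_r,
                 mean_x = mean_x,
                 n_hat = mean_x / (2 * sf * tile_fraction) / units_per_animal,
                 ce = sem / mean_x,
                 sf = sf,
                 units_per_animal = units_per_animal,
                 tile_fraction = tile_fraction),
            class = "animal_estimate")
}

#' @export
print.animal_estimate <- function(x, ...) {
  cat("Proportionator estimate\n")
  cat("  repetition totals X_r:", paste(signif(x$x_r, 4), collapse = ", "),
      "\n")
  cat("  mean(X) =", signif(x$mean_x, 4), "; sf = 1/", round(1 / x$sf, 6),
      if (x$units_per_animal != 1)
        paste0("; per ", x$units_per_animal, " units"), "\n")
  cat("  N =", signif(x$n_hat, 5), "  CE =", signif(x$ce, 3), "\n")
  invisible(x)
}

#' Mean estimator imprecision of a group (root mean square CE)
#'
#' @param ce numeric vector of per-animal CEs.
#' @return \code{sqrt(mean(ce^2))}.
#' @export
#' @examples
#' round(group_mean_ce(c(0.05, 0.08, 0.12)), 3)  # 0.088
group_mean_ce <- function(ce) {
  if (length(ce) < 1L) abort_config("need at least one CE")
  sqrt(sum(ce^2) / length(ce))
}

#' Observed between-animal coefficient of variation
#'
#' @param estimates per-animal estimates (length >= 2).
#' @return sample SD (n-1 denominator) divided by the mean.
#' @export
#' @examples
#' round(group_cv(c(41, 38, 27)), 2)  # 0.21
group_cv <- function(estimates) {
  if (length(estimates) < 2L)
    abort_config("need at least two estimates for a CV")
  m <- mean(estimates)
  if (m == 0) pp_stop("mean estimate is zero; CV undefined",
                      class = "pp_undefined_cv")
  sd(estimates) / m
}

#' Biological variation: the CV with the estimator imprecision removed
#'
#' The observed variation decomposes as
#' \code{CV_obs^2 = CV_ani^2 + CE_mean^2}; solving for the biological
#' component and clamping at zero when sampling noise makes the difference
#' negative.
#'
#' @param cv_obs observed group CV.
#' @param ce_mean group mean (RMS) CE.
#' @return the biological CV; attribute \code{clamped} is TRUE when the
#'   difference was negative.
#' @export
#' @examples
#' cv_animal(0.5, 0.3)  # 0.4
cv_animal <- function(cv_obs, ce_mean) {
  check_scalar_number(cv_obs, "cv_obs", lower = 0)
  check_scalar_number(ce_mean, "ce_mean", lower = 0)
  d <- cv_obs^2 - ce_mean^2
  out <- sqrt(max(d, 0))
  attr(out, "clamped") <- d < 0
  out
}

#' PROBE: is the estimator precision balanced against biology?
#'
#' The Precision Range of an Optimally Balanced Estimator compares the
#' observed between-animal variation with the estimator imprecision:
#' \code{ratio = CV_obs^2 / CE_mean^2}. A ratio between 2 and 4 is adequate;
#' above 4 the estimator is more precise than the biology warrants (reduce
#' the workload where it is heaviest); below 2 the estimator is too
#' imprecise (sample more sections if the organ is inhomogeneous at the
#' section scale, or enlarge the frame and sample more tiles).
#'
#' @param cv_obs observed group CV.
#' @param ce_mean group mean (RMS) CE (> 0).
#' @return an object of class \code{probe_result}: \code{ratio},
#'   \code{recommendation} (one of \code{reduce_effort}, \code{adequate},
#'   \code{increase_sampling}), \code{advice}, \code{caution}.
#' @export
#' @examples
#' probe(0.21, 0.088)$ratio  # ~5.7: reduce_effort
probe <- function(cv_obs, ce_mean) {
  check_scalar_number(cv_obs, "cv_obs", lower = 0)
  check_scalar_number(ce_mean, "ce_mean", lower = 0)
  if (ce_mean == 0)
    pp_stop("PROBE undefined for a zero mean CE",
            class = "pp_undefined_probe")
  ratio <- cv_obs^2 / ce_mean^2
  if (ratio > 4) {
    rec <- "reduce_effort"
    advice <- paste("Estimator precision may be better than the purpose",
                    "requires; if convenient, reduce the workload where it",
                    "is heaviest (fewer sections or fewer sampled tiles).")
  } else if (ratio < 2) {
    rec <- "increase_sampling"
    advice <- paste("Estimator imprecision is too large: increase the",
                    "number of sections if the organ is inhomogeneous at",
                    "the section scale; otherwise enlarge the counting",
                    "frame and increase the number of sampled tiles.")
  } else {
    rec <- "adequate"
    advice <- "The precision is adequate for the purpose."
  }
  structure(list(ratio = ratio,
                 recommendation = rec,
                 advice = advice,
                 caution = paste("Change sample sizes by a proportion less",
                                 "than that of the PROBE number in relation",
                                 "to the PROBE limit.")),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat("PROBE ratio CV_obs^2 / CE_mean^2 =", signif(x$ratio, 3),
      "->", x$recommendation, "\n  ", x$advice, "\n")
  invisible(x)
}

#' Sparseness index of a population at counting magnification
#'
#' Ratio of the total number of tiles to the number of tiles bearing a
#' count: roughly how many empty tiles a uniform design must examine to
#' reach one count.
#'
#' @param n_tiles total number of tiles.
#' @param n_tiles_with_count number of tiles containing a counted cell
#'   (> 0).
#' @return the raw ratio; attribute \code{rounded} holds the integer used in
#'   reports.
#' @export
#' @examples
#' sparseness_index(1900, 35)  # ~54
sparseness_index <- function(n_tiles, n_tiles_with_count) {
  check_scalar_number(n_tiles, "n_tiles", lower = 0)
  if (n_tiles_with_count <= 0)
    pp_stop("sparseness undefined: no tiles with a count",
            class = "pp_undefined_sparseness")
  out <- n_tiles / n_tiles_with_count
  attr(out, "rounded") <- as.integer(round(out))
  out
}

#' Group summary statistics with PROBE diagnostics
#'
#' @param estimates per-animal estimates of total number.
#' @param ces per-animal CEs (same length).
#' @param sparseness optional sparseness index of the population.
#' @return an object of class \code{group_summary}: \code{mean, sd, cv_obs,
#'   ce_mean, cv_ani, probe_ratio, recommendation, sparseness}.
#' @export
#' @examples
#' group_summary(c(41, 38, 27), c(0.05, 0.08, 0.12))
group_summary <- function(estimates, ces, sparseness = NA_real_) {
  if (length(estimates) != length(ces))
    abort_config("estimates and ces must have the same length")
  cv <- group_cv(estimates)
  ce <- group_mean_ce(ces)
  pr <- probe(cv, ce)
  structure(list(estimates = estimates,
                 ces = ces,
                 mean = mean(estimates),
                 sd = sd(estimates),
                 cv_obs = cv,
                 ce_mean = ce,
                 cv_ani = as.numeric(cv_animal(cv, ce)),
                 probe_ratio = pr$ratio,
                 recommendation = pr$recommendation,
                 sparseness = sparseness),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group of", length(x$estimates), "animals\n")
  cat("  mean =", signif(x$mean, 4), " SD =", signif(x$sd, 3),
      " CV_obs =", signif(x$cv_obs, 3), "\n")
  cat("  mean CE =", signif(x$ce_mean, 3),
      " CV_ani =", signif(x$cv_ani, 3), "\n")
  cat("  PROBE =", signif(x$probe_ratio, 3), "->", x$recommendation, "\n")
  if (!is.na(x$sparseness))
    cat("  sparseness =", round(x$sparseness), "\n")
  invisible(x)
}
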