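# End-to-end pipelines: simulate one animal, estimate by proportionator and
# by the uniform fractionator baseline, and the Monte-Carlo benchmark.

#' Simulate one animal end to end (organ through weighted tiles)
#'
#' Sections the organ exhaustively, draws the systematic uniform fractionator
#' sample of disector pairs, tessellates the sampled pairs into
#' unbiased-frame tiles, and assigns image-analysis weights plus ground-truth
#' disector counts.
#'
#' @param organ an \code{organ_truth} (see \code{\link{generate_organ}}).
#' @param thickness_um section thickness t (um), default 6.
#' @param n_pairs target number of section pairs ns, default 20.
#' @param frame_um unbiased frame side (um), default 200.
#' @param stain a \code{\link{stain_model}}.
#' @param seed integer seed driving R, the weights and any subsampling.
#' @param R explicit fractionator random start (otherwise seeded).
#' @param tile_fraction optional tile sampling fraction before weighting.
#' @param sparse passed to \code{\link{subsample_tiles}}.
#' @return an object of class \code{animal_simulation}: \code{organ},
#'   \code{sectioning}, \code{design}, \code{pairs}, \code{tiles},
#'   \code{supersection}, \code{R}.
#' @export
#' @examples
#' sim <- simulate_animal(generate_organ(n_cells = 50, seed = 1), seed = 7)
#' sim$supersection
simulate_animal <- function(organ, thickness_um = 6, n_pairs = 20,
                            frame_um = 200, stain = stain_model(), seed,
                            R = NULL, tile_fraction = 1, sparse = TRUE) {
  stopifnot(inherits(organ, "organ_truth"))
  sectioning <- section_organ(organ, thickness_um)
  design <- plan_design(organ$height_um, thickness_um, n_pairs)
  pairs <- sample_pairs(design, R = R, seed = derive_seed(seed, "pairs"))
  tiles <- tessellate_tiles(organ, pairs, frame_um)
  if (tile_fraction < 1)
    tiles <- subsample_tiles(tiles, tile_fraction,
                             seed = derive_seed(seed, "tiles"),
                             sparse = sparse)
  tiles <- assign_weights(tiles, organ, sectioning, pairs, stain,
                          seed = derive_seed(seed, "stain"))
  structure(list(organ = organ,
                 sectioning = sectioning,
                 design = design,
                 pairs = pairs,
                 tiles = tiles,
                 supersection = build_supersection(tiles, tile_fraction),
                 R = attr(pairs, "R")),
            class = "animal_simulation")
}

#' @export
print.animal_simulation <- function(x, ...) {
  cat("Simulated animal: n_true =", x$organ$n_true, ", R =", x$R, "\n")
  print(x$design)
  print(x$supersection)
  invisible(x)
}

#' Proportionator estimate for one animal
#'
#' Runs the full estimation chain on a weighted supersection: smooth
#' arrangement, three (by default) independent PPS systematic samplings,
#' disector counts on the sampled tiles, the non-useable-tile policy,
#' Horvitz-Thompson repetition totals, and the final estimate with its CE.
#'
#' @param sim an \code{animal_simulation}, or a weighted tile table (then
#'   \code{sf} must be given).
#' @param n_tiles tiles per independent sampling (default 22).
#' @param seed integer seed for the random starts.
#' @param repetitions number of independent samplings (default 3).
#' @param policy non-useable-tile policy, see
#'   \code{\link{apply_nonusable_policy}}.
#' @param counts optional counts data.frame (\code{tile_id, x, usable});
#'   defaults to the simulated ground-truth counts in the tile table.
#' @param sf section sampling fraction (taken from \code{sim} if absent).
#' @param units_per_animal units pooled per specimen (default 1).
#' @param tile_fraction tile sampling fraction (taken from \code{sim}).
#' @param u optional vector of explicit random starts, one per repetition
#'   (replaces the seeded draw; for replay and worked examples).
#' @return an \code{\link{animal_estimate}} with the sampling attached as
#'   \code{$sampling}.
#' @export
proportionator_estimate <- function(sim, n_tiles = 22, seed = NULL,
                                    repetitions = 3,
                                    policy = "exclude_rescale",
                                    counts = NULL, sf = NULL,
                                    units_per_animal = 1,
                                    tile_fraction = NULL, u = NULL) {
  if (inherits(sim, "animal_simulation")) {
    tiles <- sim$tiles
    if (is.null(sf)) sf <- sim$design$sf
    if (is.null(tile_fraction)) tile_fraction <- sim$supersection$tile_fraction
  } else {
    tiles <- sim
    if (is.null(sf)) abort_config("sf must be supplied with a raw tile table")
    if (is.null(tile_fraction))
      tile_fraction <- attr(tiles, "tile_fraction") %||% 1
  }
  if (is.null(counts)) counts <- tiles
  ord <- smooth_order(tiles)
  if (!is.null(u)) {
    if (length(u) != repetitions)
      abort_config("u must supply one start per repetition")
    reps <- lapply(u, function(ui)
      pps_systematic_draw(ord, n_tiles, u = ui))
    trip <- structure(list(repetitions = reps, presented = NULL,
                           n = as.integer(n_tiles), Z = ord$Z,
                           T_z = ord$Z / n_tiles, us = u, seed = NA),
                      class = "tripartite_sample")
  } else {
    if (is.null(seed)) abort_config("either seed or u must be supplied")
    trip <- tripartite_sample(ord, n_tiles, seed, repetitions = repetitions)
  }
  x_r <- vapply(trip$repetitions, function(rep) {
    rep <- attach_counts(rep, counts)
    rep <- apply_nonusable_policy(rep, policy)
    repetition_total(rep)
  }, numeric(1))
  est <- animal_estimate(x_r, sf, units_per_animal = units_per_animal,
                         tile_fraction = tile_fraction)
  est$sampling <- trip
  est$policy <- policy
  est
}

#' Uniform fractionator baseline on the same material
#'
#' The classical estimator: examine tiles uniformly (all of them, or a
#' systematic uniform budget of \code{n_budget}), sum the bidirectional
#' disector counts, halve, and divide by the sampling fractions. Its CE in a
#' sparse population is \code{1/sqrt(count)}.
#'
#' @param sim an \code{animal_simulation} or weighted tile table with counts.
#' @param sf section sampling fraction (from \code{sim} if absent).
#' @param n_budget number of tiles to examine (default: all tiles).
#' @param seed seed for the systematic uniform tile subsample.
#' @param tile_fraction tile sampling fraction of the tessellation itself.
#' @return an object of class \code{baseline_estimate}:
#'   \code{total_count} (halved), \code{n_hat}, \code{ce} (NA when the
#'   count is zero), \code{n_examined}, \code{empty_tiles_per_count}.
#' @export
fractionator_baseline <- function(sim, sf = NULL, n_budget = NULL,
                                  seed = NULL, tile_fraction = NULL) {
  if (inherits(sim, "animal_simulation")) {
    tiles <- sim$tiles
    if (is.null(sf)) sf <- sim$design$sf
    if (is.null(tile_fraction)) tile_fraction <- sim$supersection$tile_fraction
  } else {
    tiles <- sim
    if (is.null(sf)) abort_config("sf must be supplied with a raw tile table")
    if (is.null(tile_fraction))
      tile_fraction <- attr(tiles, "tile_fraction") %||% 1
  }
  if (is.null(tiles$count))
    abort_config("tile table has no count column")
  budget_fraction <- 1
  if (!is.null(n_budget) && n_budget < nrow(tiles)) {
    if (is.null(seed)) abort_config("seed needed for a budgeted baseline")
    n_all <- nrow(tiles)
    period <- n_all / n_budget
    phase <- with_seed(derive_seed(seed, "budget"), runif(1, 0, period))
    take <- unique(pmin(n_all,
                        ceiling(phase + 1e-12 + (seq_len(n_budget) - 1) *
                                  period)))
    tiles <- tiles[take, , drop = FALSE]
    budget_fraction <- length(take) / n_all
  }
  total <- sum(tiles$count) / 2
  n_hat <- fractionator_estimate(total / budget_fraction / tile_fraction, sf)
  ce <- if (total > 0) fractionator_ce(total) else NA_real_
  n_zero <- sum(tiles$count == 0)
  n_with <- sum(tiles$count > 0)
  structure(list(total_count = total,
                 n_hat = n_hat,
                 ce = ce,
                 n_examined = nrow(tiles),
                 empty_tiles_per_count =
                   if (n_with > 0) n_zero / n_with else NA_real_),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat("Uniform fractionator baseline: count =", x$total_count,
      "over", x$n_examined, "tiles -> N =", signif(x$n_hat, 5),
      ", CE =", if (is.na(x$ce)) "undefined (zero count)"
      else signif(x$ce, 3), "\n")
  invisible(x)
}

#' Monte-Carlo benchmark: proportionator vs uniform fractionator
#'
#' Repeats the whole sampling chain on one fixed organ: each replicate draws
#' a fresh fractionator start, fresh weights, a tripartite proportionator
#' sample of \code{repetitions * n_tiles} tiles, and a uniform fractionator
#' baseline restricted to the same tiles-examined budget. Summaries report
#' bias, empirical CV, mean CE and how often the proportionator beats the
#' uniform design (a replicate where the uniform budget finds no cells at
#' all, so its CE is undefined, counts as a proportionator win).
#'
#' @param organ an \code{organ_truth}.
#' @param n_replicates number of replicates (>= 10).
#' @param seed integer seed.
#' @param thickness_um,n_pairs,frame_um,stain,n_tiles,repetitions design
#'   parameters, as in \code{\link{simulate_animal}} and
#'   \code{\link{proportionator_estimate}}.
#' @return an object of class \code{benchmark_result}: per-replicate
#'   data.frame \code{replicates} and a \code{summary} list.
#' @export
benchmark_estimators <- function(organ, n_replicates, seed,
                                 thickness_um = 6, n_pairs = 20,
                                 frame_um = 200, stain = stain_model(),
                                 n_tiles = 22, repetitions = 3) {
  check_scalar_number(n_replicates, "n_replicates", lower = 10)
  budget <- n_tiles * repetitions
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- derive_seed(seed, "benchmark", r)
    sim <- simulate_animal(organ, thickness_um = thickness_um,
                           n_pairs = n_pairs, frame_um = frame_um,
                           stain = stain, seed = s)
    # a supersection whose three samplings all count zero cells gives the
    # honest estimate 0 with an undefined CE
    prop <- tryCatch(
      proportionator_estimate(sim, n_tiles = n_tiles,
                              seed = derive_seed(s, "prop"),
                              repetitions = repetitions),
      pp_undefined_ce = function(e) list(n_hat = 0, ce = NA_real_),
      pp_no_signal = function(e) list(n_hat = 0, ce = NA_real_))
    frac_budget <- fractionator_baseline(sim, n_budget = budget,
                                         seed = derive_seed(s, "frac"))
    frac_full <- fractionator_baseline(sim)
    rows[[r]] <- data.frame(
      replicate = r,
      R = sim$R,
      prop_n_hat = prop$n_hat,
      prop_ce = prop$ce,
      frac_budget_count = frac_budget$total_count,
      frac_budget_n_hat = frac_budget$n_hat,
      frac_budget_ce = if (is.na(frac_budget$ce)) NA_real_
        else frac_budget$ce,
      frac_full_count = frac_full$total_count,
      frac_full_n_hat = frac_full$n_hat,
      frac_full_ce = if (is.na(frac_full$ce)) NA_real_ else frac_full$ce,
      empty_per_count = frac_full$empty_tiles_per_count,
      prop_wins = !is.na(prop$ce) &&
        (is.na(frac_budget$ce) || prop$ce < frac_budget$ce)
    )
  }
  reps <- do.call(rbind, rows)
  summary <- list(
    n_true = organ$n_true,
    n_replicates = n_replicates,
    tiles_budget = budget,
    prop_bias = mean(reps$prop_n_hat) - organ$n_true,
    prop_cv = sd(reps$prop_n_hat) / mean(reps$prop_n_hat),
    prop_mean_ce = group_mean_ce(reps$prop_ce[!is.na(reps$prop_ce)]),
    frac_budget_mean_ce = group_mean_ce(
      reps$frac_budget_ce[!is.na(reps$frac_budget_ce)]),
    frac_budget_undefined = mean(is.na(reps$frac_budget_ce)),
    frac_full_mean_ce = group_mean_ce(
      reps$frac_full_ce[!is.na(reps$frac_full_ce)]),
    frac_bias = mean(reps$frac_full_n_hat) - organ$n_true,
    mean_empty_per_count = mean(reps$empty_per_count, na.rm = TRUE),
    prop_win_fraction = mean(reps$prop_wins)
  )
  structure(list(replicates = reps, summary = summary),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat("Benchmark over", s$n_replicates, "replicates (n_true =", s$n_true,
      ", budget =", s$tiles_budget, "tiles examined)\n")
  cat("  proportionator: bias =", signif(s$prop_bias, 3),
      " CV =", signif(s$prop_cv, 3),
      " mean CE =", signif(s$prop_mean_ce, 3), "\n")
  cat("  fractionator (same budget): mean CE =",
      signif(s$frac_budget_mean_ce, 3), " (undefined in ",
      round(100 * s$frac_budget_undefined), "% of replicates)\n", sep = "")
  cat("  fractionator (all tiles): bias =", signif(s$frac_bias, 3),
      " mean CE =", signif(s$frac_full_mean_ce, 3),
      " empty tiles per count =", round(s$mean_empty_per_count), "\n")
  cat("  proportionator wins at equal budget in",
      round(100 * s$prop_win_fraction), "% of replicates\n")
  invisible(x)
}
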