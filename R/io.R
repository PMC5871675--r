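# Flat-file interfaces: tile tables and counts as CSV, configs as YAML/JSON,
# reports as JSON.

TILE_COLUMNS <- c("tile_id", "pair_id", "x_um", "y_um", "frame_um",
                  "weight_px", "count", "usable")

#' Write / read a tile table CSV
#'
#' One flat dialect: comma separated, header, UTF-8, '.' decimal; columns
#' \code{tile_id, pair_id, x_um, y_um, frame_um, weight_px, count, usable},
#' rows in deterministic (pair_id, y, x) order.
#'
#' @param tiles weighted tile table.
#' @param path file path.
#' @return \code{write_tile_table} returns \code{path} invisibly;
#'   \code{read_tile_table} the tile table.
#' @export
write_tile_table <- function(tiles, path) {
  missing <- setdiff(TILE_COLUMNS, names(tiles))
  if (length(missing))
    abort_config("tile table lacks column(s): ",
                 paste(missing, collapse = ", "))
  tiles <- tiles[order(tiles$pair_id, tiles$y_um, tiles$x_um), TILE_COLUMNS]
  utils::write.csv(tiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_table
#' @export
read_tile_table <- function(path) {
  tiles <- utils::read.csv(path)
  missing <- setdiff(TILE_COLUMNS, names(tiles))
  if (length(missing))
    abort_config("tile table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", "))
  tiles
}

#' Write / read a counts CSV (the real-data path)
#'
#' Columns \code{tile_id, repetition, x, usable}; one row per presented hit.
#'
#' @param counts data.frame with the columns above.
#' @param path file path.
#' @return \code{write_counts_csv} returns \code{path} invisibly;
#'   \code{read_counts_csv} the counts data.frame.
#' @export
write_counts_csv <- function(counts, path) {
  need <- c("tile_id", "repetition", "x", "usable")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    abort_config("counts lack column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(counts[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  counts <- utils::read.csv(path)
  need <- c("tile_id", "repetition", "x")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    abort_config("counts file ", path, " lacks column(s): ",
                 paste(missing, collapse = ", "))
  if (is.null(counts$usable)) counts$usable <- 1L
  counts
}

#' Read a run configuration (YAML or JSON)
#'
#' Blocks: \code{organ}, \code{stain}, \code{design}, \code{seeds}. Every
#' stochastic step takes an explicit seed; \code{design$repetitions} must be
#' at least 2 (default 3) because the tripartite CE needs independent
#' repetitions.
#'
#' @param path configuration file (.yaml/.yml or .json).
#' @return a named list of config blocks.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$design <- cfg$design %||% list()
  cfg$design$repetitions <- cfg$design$repetitions %||% 3
  if (cfg$design$repetitions < 2)
    abort_config("design$repetitions must be >= 2 (the CE needs at least ",
                 "two independent samplings)")
  cfg
}

#' Write a JSON report
#'
#' @param x a list (or package object coercible to one).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path) {
  if (!is.list(x)) abort_config("report must be a list")
  x <- c(list(schema = "proportionator/1"), x)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

# repetition report for `sample`: header + one row per hit
repetition_report <- function(trip, tile_fraction = 1) {
  list(n = trip$n,
       Z = trip$Z,
       T_z = trip$T_z,
       us = trip$us,
       tile_fraction = tile_fraction,
       seed = trip$seed,
       hits = trip$presented[, c("tile_id", "repetition", "multiplicity",
                                 "weight_px", "p")])
}
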