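# Internal helpers: classed errors, seed management, small checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

pp_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pp_error")))
}

abort_config <- function(...) pp_stop(..., class = "pp_invalid_config")

abort_runtime <- function(...) pp_stop(..., class = "pp_runtime_error")

#' @importFrom stats runif rnorm rpois rnbinom sd
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

# Deterministic derived seeds so that independent components (pairs, tiles,
# repetitions) get reproducible, non-overlapping streams from one user seed.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) {
      v <- utf8ToInt(p)
      sum(v * seq_along(v))
    } else {
      as.numeric(p)
    }
  }, numeric(1))
  x <- as.numeric(seed) %% 2147483647
  for (p in parts) x <- (x * 48271 + abs(p) + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_config(name, " must be a single number")
  if (strict_lower && x <= lower)
    abort_config(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    abort_config(name, " must be >= ", lower)
  if (x > upper)
    abort_config(name, " must be <= ", upper)
  invisible(x)
}

is_unimodal <- function(w) {
  if (length(w) <= 2L) return(TRUE)
  d <- diff(w)
  # non-decreasing then non-increasing
  up <- which(d < 0)
  if (length(up) == 0L) return(TRUE)
  all(d[seq(min(up), length(d))] <= 0)
}
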