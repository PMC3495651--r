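# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

# Trim whitespace; symbols are compared case-sensitively afterwards
# (mouse symbol case is meaningful).
trim_ws <- function(x) {
  sub("[ \t\r]+$", "", sub("^[ \t\r]+", "", x))
}

# Parse numeric cells of the TSV dialect: "", "NA", "NaN" are missing.
parse_cells <- function(x) {
  miss <- x == "" | x %in% c("NA", "NaN", "nan")
  out <- suppressWarnings(as.numeric(x))
  out[miss] <- NA_real_
  bad <- !miss & is.na(out)
  list(values = out, bad = bad)
}

# Deterministic RNG scope: runs `expr` under the given integer seed and
# restores the caller's RNG state afterwards.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
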