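#' @keywords internal
"_PACKAGE"

# Identifier discipline: all joins use the trimmed, case-folded form.
norm_id <- function(x) {
  x <- trimws(as.character(x))
  tolower(x)
}

# Evaluate `expr` under a locally seeded Mersenne-Twister stream, restoring
# any pre-existing RNG state afterwards. All package randomness flows
# through this helper so that a single integer seed fixes every draw.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Round half away from zero
#'
#' Display rounding used for integer-percent reporting (so 63.64 prints as
#' 64 and 62.5 as 63), as opposed to base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
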