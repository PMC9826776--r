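## Internal helpers: seed scoping, seed derivation, small assertions.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are untouched. A `NULL`
#' seed evaluates the code under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic expansion of one top-level seed into per-stage seeds
## (kept below 2^31 - 1; R integers are 32-bit).
derive_seeds <- function(seed, stages = c("simulate", "analyze", "chance", "null")) {
  if (is.null(seed)) return(stats::setNames(as.list(rep(list(NULL), length(stages))), stages))
  base <- as.double(seed) %% 2147483647
  out <- lapply(seq_along(stages), function(i) {
    as.integer((base * 48271 + i * 1664525) %% 2147483647)
  })
  stats::setNames(out, stages)
}

stop_gist <- function(...) stop(..., call. = FALSE)

assert_ratings <- function(x, arg = "ratings") {
  if (length(x) < 1) stop_gist("'", arg, "' must be nonempty")
  if (anyNA(x) || any(x < 0 | x > 100))
    stop_gist("'", arg, "' must lie in [0, 100] without NAs")
  invisible(x)
}

## nearest-rank percentile (no interpolation)
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

## mean +/- 1.96 SD/sqrt(n) half-width
ci95_halfwidth <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  1.96 * stats::sd(x) / sqrt(length(x))
}
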