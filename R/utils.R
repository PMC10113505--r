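# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round a fraction to a percentage with half-up tie-breaking
#'
#' Converts a proportion in \[0,1\] to a percentage rounded half-up at two
#' decimals (the convention used when reporting classification metrics).
#' Base \code{round()} rounds half-even, which disagrees on exact .005 ties.
#'
#' @param x numeric vector of proportions in \[0,1\] (NA allowed).
#' @param digits number of decimal places on the percentage scale.
#' @return numeric vector of percentages.
#' @examples
#' percent(19920 / 20304) # 98.11
#' @export
percent <- function(x, digits = 2) {
  p <- x * 100
  f <- 10^digits
  ifelse(is.na(p), NA_real_, floor(p * f + 0.5) / f)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("spasatune_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_number <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (integer && x != round(x)) {
    stop_invalid("`", name, "` must be an integer (got ", x, ")")
  }
  if (x < lo || x > hi) {
    stop_invalid("`", name, "` must be in [", lo, ", ", hi, "] (got ", x, ")")
  }
  invisible(x)
}

# Deterministic small positive integer seed derived from a string, < 2^31.
seed_from_string <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483587
  as.integer(h + 1L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's global RNG stream afterwards.  Keeps component randomness
# (training, augmentation) from desynchronizing the optimizer stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
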