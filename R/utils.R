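# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' operations do not disturb the global random stream. With `seed = NULL` the
#' code runs against the ambient RNG (used when a study function has already
#' seeded an outer scope).
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# clamp x into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Centered moving average with edge replication; w <= 1 is the identity.
moving_average <- function(x, w) {
  w <- as.integer(round(w))
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  if (n < w) return(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  sm <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(sm[(half + 1L):(half + n)])
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
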