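# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Spawn reproducible sub-seeds from a master seed
#'
#' @param seed Master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Trapezoidal integral of y over x
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Stop with a consistent invalid-argument condition
#' @keywords internal
#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("postrosc_invalid_argument", "error")))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invalid(msg)
  invisible(TRUE)
}

#' Moving average with a centered rectangular window (edge-truncated)
#' @keywords internal
#' @noRd
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  k <- rep(1 / width, width)
  as.numeric(stats::filter(x, k, sides = 2L, method = "convolution")) -> y
  # fill edge NAs by truncated means
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  idx <- which(is.na(y))
  if (length(idx)) {
    lo <- pmax(1L, idx - half)
    hi <- pmin(n, idx + (width - 1L) - half)
    y[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  y
}
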