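#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx fft lm median quantile rbinom rnorm runif runmed
#'   sd spline splinefun var predict coef
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mm <- function(..., class = "mmempathy_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ..., class = "mmempathy_error") {
  if (!isTRUE(ok)) stop_mm(..., class = class)
  invisible(TRUE)
}

#' Derive a child seed from a global seed and a stream label
#'
#' A single run-level seed fans out deterministically to independent
#' per-stream seeds (ratings, epochs, RR series, ...), so any module's
#' output can be regenerated on its own without replaying the whole run.
#'
#' @param seed integer global seed.
#' @param stream character label of the random stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## local RNG scope: evaluates expr with the given seed without disturbing
## the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

## population (divide-by-n) variance and SD; the convention used for every
## dispersion-type HRV index so that SD1 == RMSSD / sqrt(2) holds exactly
var_pop <- function(x) mean((x - mean(x))^2)
sd_pop <- function(x) sqrt(var_pop(x))
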