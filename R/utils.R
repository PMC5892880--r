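#' @import methods
#' @importFrom stats rnorm runif sd cor quantile median fft lm coef
#'   setNames ave var
#' @importFrom utils head tail read.table write.table packageVersion
#' @import data.table
NULL

## Integer encoding of a Miller index triple; |index| < 512 always holds for
## the cell sizes and resolutions this package targets.
encodeHKL <- function(h, k, l) {
  ((h + 512L) * 1024L + (k + 512L)) * 1024 + (l + 512L)
}

wrapFrac <- function(x) x - floor(x)

## Wrap fractional differences to the minimal image in [-0.5, 0.5)
wrapDelta <- function(x) x - round(x)

#' Derive a purpose-specific seed from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through this
#' function, so that independent stages have independent streams while the
#' whole pipeline stays reproducible from a single integer.
#'
#' @param seed master seed (integer).
#' @param purpose character tag naming the consumer of the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (v in utf8ToInt(as.character(purpose))) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates, and restores the caller's random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## FFT-friendly grid sizes (products of 2, 3, 5)
.goodSizes <- sort(unique(c(
  8, 9, 10, 12, 15, 16, 18, 20, 24, 25, 27, 30, 32, 36, 40, 45, 48, 50, 54,
  60, 64, 72, 75, 80, 81, 90, 96, 100, 108, 120, 125, 128, 135, 144, 150,
  160, 162, 180, 192, 200, 216, 225, 240, 243, 250, 256, 270, 288, 300, 320)))

nextGoodSize <- function(n) {
  s <- .goodSizes[.goodSizes >= n]
  if (!length(s)) stop("requested grid size too large")
  as.integer(s[1L])
}

## Spearman rank correlation (exposed via stats::cor)
spearman <- function(x, y) cor(x, y, method = "spearman")
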