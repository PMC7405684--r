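# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Bilinear interpolation of an image at continuous pixel coordinates.
# Images are numeric matrices indexed [row, col]; coordinates are 0-based
# with x along columns (rightward) and y along rows (downward), and integer
# coordinates referring to pixel centers. Points outside the image return NA.
bilinear_sample <- function(image, x, y) {
  h <- nrow(image)
  w <- ncol(image)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  if (!any(ok)) return(out)
  xo <- x[ok]
  yo <- y[ok]
  x0 <- pmin(floor(xo), w - 2)
  y0 <- pmin(floor(yo), h - 2)
  x0 <- pmax(x0, 0)
  y0 <- pmax(y0, 0)
  fx <- xo - x0
  fy <- yo - y0
  i00 <- y0 + 1 + x0 * h
  v <- image[i00] * (1 - fx) * (1 - fy) +
    image[i00 + h] * fx * (1 - fy) +
    image[i00 + 1] * (1 - fx) * fy +
    image[i00 + h + 1] * fx * fy
  out[ok] <- v
  out
}

# Arc length of a polyline given as an n x 2 matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
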