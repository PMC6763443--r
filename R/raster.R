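#' Lightweight in-memory rasters
#'
#' Rasters in this package are plain numeric matrices with a `res` attribute
#' (pixel size in metres). Rows run north-to-south from the top-left origin,
#' columns west-to-east; values are sampled at pixel centres, so the centre of
#' cell `[r, c]` (1-based) lies at `x = (c - 0.5) * res`,
#' `y = (r - 0.5) * res` with `y` increasing southward.
#'
#' @param nrow,ncol raster dimensions in pixels.
#' @param res pixel size in metres.
#' @param fill initial value.
#' @return a numeric matrix with attribute `res`.
#' @export
tm_raster <- function(nrow, ncol, res, fill = 0) {
  stopifnot(res > 0, nrow >= 1, ncol >= 1)
  m <- matrix(fill, nrow = nrow, ncol = ncol)
  attr(m, "res") <- res
  m
}

#' @rdname tm_raster
#' @param r a raster matrix.
#' @export
tm_res <- function(r) {
  res <- attr(r, "res")
  if (is.null(res)) stop("raster has no 'res' attribute")
  res
}

# pixel-centre coordinates (m) for 1-based row/col
tm_cell_xy <- function(row, col, res) {
  list(x = (col - 0.5) * res, y = (row - 0.5) * res)
}

# nearest-pixel (1-based) indices for map coordinates, clamped to the grid
tm_xy_cell <- function(x, y, r) {
  res <- tm_res(r)
  row <- pmin(pmax(ceiling(y / res), 1L), nrow(r))
  col <- pmin(pmax(ceiling(x / res), 1L), ncol(r))
  list(row = as.integer(row), col = as.integer(col))
}

#' Sample a raster at map coordinates (nearest pixel centre)
#'
#' @param r raster matrix with `res` attribute.
#' @param x,y coordinate vectors in metres.
#' @return numeric vector of sampled values.
#' @export
tm_sample <- function(r, x, y) {
  idx <- tm_xy_cell(x, y, r)
  r[cbind(idx$row, idx$col)]
}

# smooth standardized Gaussian random field: white noise convolved with a
# separable Gaussian kernel, then empirically centred and scaled to unit sd
smooth_field <- function(nrow, ncol, range_px) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (range_px >= 1) {
    half <- max(1L, ceiling(2 * range_px))
    k <- stats::dnorm(seq(-half, half), sd = range_px)
    k <- k / sum(k)
    pad <- function(m, n) { # reflect-pad rows
      m[c(pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m))), , drop = FALSE]
    }
    conv_rows <- function(m) {
      mp <- pad(m, half)
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
      out
    }
    z <- conv_rows(z)
    z <- t(conv_rows(t(z)))
  }
  s <- stats::sd(z)
  if (s == 0) return(z * 0)
  (z - mean(z)) / s
}
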