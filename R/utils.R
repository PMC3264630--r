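# Shared low-level helpers: error conditions, raster primitives, rectangles.

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slidecache_invalid_argument", "slidecache_error")))
}

stop_not_found <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slidecache_not_found", "slidecache_error")))
}

stop_state <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slidecache_state_error", "slidecache_error")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("slidecache_parse_error", "slidecache_error")))
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_scalar_num <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

#' Nearest-neighbor source indices for a resampled axis
#'
#' Output pixel `i` (0-based) samples source index
#' `floor((i + 0.5) * n_src / n_out)`, the half-pixel-centre convention.
#' Returned indices are 1-based for R subsetting.
#'
#' @param n_out number of output pixels along the axis.
#' @param n_src number of source pixels along the axis.
#' @return integer vector of length `n_out` with values in `1:n_src`.
#' @export
nn_index <- function(n_out, n_src) {
  i <- seq_len(n_out) - 1
  idx <- floor((i + 0.5) * n_src / n_out)
  as.integer(pmin(pmax(idx, 0), n_src - 1)) + 1L
}

#' Nearest-neighbor resampling of an RGB raster
#'
#' Resamples a `height x width x 3` integer raster to `out_h x out_w` by
#' nearest-neighbor lookup under the half-pixel-centre convention of
#' [nn_index()]. When the output size equals the input size the result is
#' bit-identical to the input.
#'
#' @param pixels integer array of dimension `c(h, w, 3)`.
#' @param out_h,out_w output dimensions in pixels (>= 1).
#' @return integer array of dimension `c(out_h, out_w, 3)`.
#' @export
resample_nn <- function(pixels, out_h, out_w) {
  if (!is_count(out_h) || !is_count(out_w)) {
    stop_invalid("output dimensions must be positive integers")
  }
  d <- dim(pixels)
  pixels[nn_index(out_h, d[1]), nn_index(out_w, d[2]), , drop = FALSE]
}

# White (255) raster, the fill colour for regions outside the slide.
blank_raster <- function(h, w, value = 255L) {
  array(as.integer(value), dim = c(h, w, 3L))
}

assert_raster <- function(x, what = "raster") {
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3) {
    stop_invalid("%s must be an h x w x 3 array", what)
  }
  invisible(x)
}

# --- axis-aligned rectangles, half-open [x0, x1) x [y0, y1) ---------------

rect <- function(x0, y0, x1, y1) {
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

rect_empty <- function(r) r$x1 <= r$x0 || r$y1 <= r$y0

rect_intersect <- function(a, b) {
  rect(max(a$x0, b$x0), max(a$y0, b$y0), min(a$x1, b$x1), min(a$y1, b$y1))
}

rect_contains <- function(outer, inner) {
  outer$x0 <= inner$x0 && inner$x1 <= outer$x1 &&
    outer$y0 <= inner$y0 && inner$y1 <= outer$y1
}

# a \ b as a list of up to 4 disjoint rectangles (top, bottom, left, right).
rect_diff <- function(a, b) {
  if (rect_empty(a)) return(list())
  b <- rect_intersect(a, b)
  if (rect_empty(b)) return(list(a))
  out <- list()
  if (b$y0 > a$y0) out <- c(out, list(rect(a$x0, a$y0, a$x1, b$y0)))
  if (b$y1 < a$y1) out <- c(out, list(rect(a$x0, b$y1, a$x1, a$y1)))
  if (b$x0 > a$x0) out <- c(out, list(rect(a$x0, b$y0, b$x0, b$y1)))
  if (b$x1 < a$x1) out <- c(out, list(rect(b$x1, b$y0, a$x1, b$y1)))
  out
}

# Map an axis-aligned rectangle through a translation + positive uniform
# scaling transform (the only transforms the engine composes).
rect_transform <- function(r, m) {
  p0 <- m %*% c(r$x0, r$y0, 1)
  p1 <- m %*% c(r$x1, r$y1, 1)
  rect(min(p0[1], p1[1]), min(p0[2], p1[2]), max(p0[1], p1[1]), max(p0[2], p1[2]))
}
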