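# Region-on-demand instruction set: the viewer<->image-store contract.

#' Construct a region request
#'
#' The instruction carries the region origin `(x, y)`, its extent
#' `(width, height)` in pixels, and a `zoom` divisor in `[1, Inf)` where
#' zoom 1 is the highest scanned magnification. Coordinates are expressed in
#' the requested-zoom pixel frame, so the response is exactly
#' `width x height` pixels.
#'
#' @param x,y region origin (integers, may be negative).
#' @param width,height region extent in pixels, >= 1.
#' @param zoom magnification divisor, >= 1.
#' @return a `region_request`.
#' @export
region_request <- function(x, y, width, height, zoom = 1) {
  if (!is_scalar_num(x) || !is_scalar_num(y) || x != round(x) || y != round(y)) {
    stop_invalid("x and y must be integers")
  }
  if (!is_count(width) || !is_count(height)) {
    stop_invalid("width and height must be positive integers")
  }
  if (!is_scalar_num(zoom) || zoom < 1) {
    stop_invalid("zoom must be >= 1 (zoom 1 is the highest magnification)")
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height),
                 zoom = zoom),
            class = "region_request")
}

#' Serve a region request from a pyramid
#'
#' The effective magnification is `base_magnification / zoom`; the region is
#' synthesized by [region_at_magnification()] in that pixel frame. The
#' response raster is always exactly `width x height`, white-filled where the
#' request extends beyond the slide.
#'
#' @param pyramid a `tile_pyramid`.
#' @param request a `region_request` (or arguments to build one via `...`).
#' @return a `region_response`: list with `raster`, `magnification`
#'   (effective), and `source_level` (magnification of the stored level used).
#' @export
handle_request <- function(pyramid, request) {
  if (!inherits(request, "region_request")) {
    stop_invalid("request must be a region_request")
  }
  magnification <- pyramid$base_magnification / request$zoom
  src <- source_level_magnification(pyramid, magnification)
  raster <- region_at_magnification(pyramid, magnification,
                                    request$x, request$y,
                                    request$width, request$height)
  structure(list(raster = raster, magnification = magnification,
                 source_level = src, request = request),
            class = "region_response")
}

#' @export
print.region_response <- function(x, ...) {
  cat(sprintf("<region_response> %d x %d px at %gx (served from %gx level)\n",
              x$request$width, x$request$height, x$magnification, x$source_level))
  invisible(x)
}
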