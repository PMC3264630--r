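# Deterministic generator of histology-like test rasters.

#' Generate a synthetic histology-like slide
#'
#' Produces a deterministic RGB raster with multi-scale structure emulating an
#' H&E-stained tissue scan: a low-frequency eosin-pink background wash,
#' mid-frequency clusters of dark nucleus-like ellipses, and per-pixel noise.
#' The three scales guarantee that full-resolution and down-sampled renderings
#' of the same region differ measurably, which is what the cache-blur and
#' pyramid tests rely on.
#'
#' @param width_px,height_px slide dimensions in pixels, both >= 64.
#' @param base_magnification nominal objective power of the scan (e.g. 40).
#' @param seed integer seed; identical arguments give pixel-identical output.
#' @return a `slide_image`: list with `pixels` (integer array
#'   `height_px x width_px x 3`, values in 0..255), `width_px`, `height_px`
#'   and `base_magnification`.
#' @examples
#' s <- generate_slide(128, 96, base_magnification = 40, seed = 1)
#' dim(s$pixels)
#' @export
generate_slide <- function(width_px, height_px, base_magnification = 40, seed = 1L) {
  if (!is_count(width_px, 64) || !is_count(height_px, 64)) {
    stop_invalid("width_px and height_px must be integers >= 64")
  }
  if (!is_scalar_num(base_magnification) || base_magnification <= 0) {
    stop_invalid("base_magnification must be a positive number")
  }
  w <- as.integer(width_px)
  h <- as.integer(height_px)

  pixels <- withr::with_seed(as.integer(seed), {
    xs <- seq_len(w)
    ys <- seq_len(h)

    # Low-frequency wash: a few long-wavelength sinusoids modulating intensity.
    wash <- matrix(0, h, w)
    for (k in 1:3) {
      fx <- stats::runif(1, 0.3, 1.5) / w
      fy <- stats::runif(1, 0.3, 1.5) / h
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 6, 14)
      wash <- wash + amp * sin(outer(2 * pi * fy * ys, 2 * pi * fx * xs, "+") + phase)
    }

    # Eosin-like background with wash modulation.
    bg <- c(234, 205, 215)
    red <- matrix(bg[1], h, w) + wash
    green <- matrix(bg[2], h, w) + wash
    blue <- matrix(bg[3], h, w) + 0.5 * wash

    # Nucleus-like dark ellipses, grouped into clusters (~1 cluster / 0.3 Mpx,
    # ~20 nuclei each, radii 4-16 px: plausible nucleus sizes at 40x).
    # Blobs accumulate into one opacity mask, blended into all channels at
    # the end (single-pass arithmetic keeps the per-blob cost local).
    nucleus <- c(92, 58, 128)
    mask <- matrix(0, h, w)
    n_clusters <- max(2L, as.integer(round(w * h / 3e5)))
    cx_all <- stats::runif(n_clusters, 1, w)
    cy_all <- stats::runif(n_clusters, 1, h)
    for (ci in seq_len(n_clusters)) {
      n_blob <- stats::rpois(1, 20) + 3L
      spread <- stats::runif(1, 30, 120)
      bx <- stats::rnorm(n_blob, cx_all[ci], spread)
      by <- stats::rnorm(n_blob, cy_all[ci], spread)
      rx <- stats::runif(n_blob, 4, 16)
      ry <- stats::runif(n_blob, 4, 16)
      ang <- stats::runif(n_blob, 0, pi)
      strength <- stats::runif(n_blob, 0.6, 0.95)
      for (bi in seq_len(n_blob)) {
        rmax <- max(rx[bi], ry[bi])
        x0 <- max(1L, as.integer(floor(bx[bi] - rmax)))
        x1 <- min(w, as.integer(ceiling(bx[bi] + rmax)))
        y0 <- max(1L, as.integer(floor(by[bi] - rmax)))
        y1 <- min(h, as.integer(ceiling(by[bi] + rmax)))
        if (x0 > x1 || y0 > y1) next
        dx <- (x0:x1) - bx[bi]
        dy <- (y0:y1) - by[bi]
        u <- outer(dy * sin(ang[bi]), dx * cos(ang[bi]), "+") / rx[bi]
        v <- outer(dy * cos(ang[bi]), -dx * sin(ang[bi]), "+") / ry[bi]
        inside <- (u^2 + v^2) <= 1
        if (!any(inside)) next
        sub <- mask[y0:y1, x0:x1, drop = FALSE]
        sub[inside] <- pmax(sub[inside], strength[bi])
        mask[y0:y1, x0:x1] <- sub
      }
    }
    red <- red * (1 - mask) + nucleus[1] * mask
    green <- green * (1 - mask) + nucleus[2] * mask
    blue <- blue * (1 - mask) + nucleus[3] * mask

    # Per-pixel noise so that no two resolution levels are trivially equal.
    out <- array(0L, dim = c(h, w, 3L))
    out[, , 1] <- as.integer(pmin(pmax(round(red + stats::runif(h * w, -8, 8)), 0), 255))
    out[, , 2] <- as.integer(pmin(pmax(round(green + stats::runif(h * w, -8, 8)), 0), 255))
    out[, , 3] <- as.integer(pmin(pmax(round(blue + stats::runif(h * w, -8, 8)), 0), 255))
    out
  })

  structure(
    list(pixels = pixels, width_px = w, height_px = h,
         base_magnification = base_magnification),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %d x %d px at %gx base magnification\n",
              x$width_px, x$height_px, x$base_magnification))
  invisible(x)
}

#' Write a slide raster to a PNG or TIFF file
#'
#' @param slide a `slide_image` (or a bare integer raster array).
#' @param path output path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  pixels <- if (inherits(slide, "slide_image")) slide$pixels else slide
  assert_raster(pixels, "slide")
  arr <- pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path)
  } else {
    stop_invalid("unsupported output format '%s' (use .png or .tif)", ext)
  }
  invisible(path)
}

#' Read a raster file as a slide
#'
#' @param path a PNG or TIFF file.
#' @param base_magnification nominal magnification to attach to the raster.
#' @return a `slide_image`.
#' @export
read_slide <- function(path, base_magnification = 40) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop_invalid("unsupported input format '%s' (use .png or .tif)", ext)
  }
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  pixels <- array(as.integer(round(arr * 255)), dim = dim(arr))
  structure(
    list(pixels = pixels, width_px = dim(arr)[2], height_px = dim(arr)[1],
         base_magnification = base_magnification),
    class = "slide_image"
  )
}
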