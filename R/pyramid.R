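# Multi-resolution tile pyramid: build, tile access, arbitrary-magnification
# region synthesis, and the DZI-like on-disk layout.

#' Build a tile pyramid from a slide
#'
#' Stores the slide at each requested magnification, highest first. Each level
#' raster is the base raster nearest-neighbor resampled by
#' `magnification / base_magnification` (the base level is the slide itself)
#' and cut into `tile_size` x `tile_size` tiles; right/bottom edge tiles may
#' be smaller. Level dimensions follow
#' `ceil(base_dim * magnification / base_magnification)`.
#'
#' @param slide a `slide_image`.
#' @param magnifications positive magnifications to store; the maximum must
#'   equal the slide's base magnification (the scan itself is the top level).
#' @param tile_size tile side in pixels, >= 16. Default 256.
#' @param slide_id identifier recorded in the pyramid metadata.
#' @return a `tile_pyramid`.
#' @export
build_pyramid <- function(slide, magnifications = c(40, 10, 1), tile_size = 256L,
                          slide_id = "slide") {
  if (!inherits(slide, "slide_image")) stop_invalid("slide must be a slide_image")
  if (!is_count(tile_size, 16)) stop_invalid("tile_size must be an integer >= 16")
  if (length(magnifications) < 1 || any(!is.finite(magnifications)) ||
      any(magnifications <= 0)) {
    stop_invalid("magnifications must be positive numbers")
  }
  if (anyDuplicated(magnifications)) stop_invalid("magnifications must be unique")
  if (max(magnifications) > slide$base_magnification + 1e-9) {
    stop_invalid("requested magnification %g exceeds base magnification %g",
                 max(magnifications), slide$base_magnification)
  }
  if (abs(max(magnifications) - slide$base_magnification) > 1e-9) {
    stop_invalid("the highest stored magnification must equal the base magnification (%g)",
                 slide$base_magnification)
  }
  mags <- sort(magnifications, decreasing = TRUE)
  tile_size <- as.integer(tile_size)

  levels <- lapply(mags, function(m) {
    f <- m / slide$base_magnification
    lw <- as.integer(ceiling(slide$width_px * f))
    lh <- as.integer(ceiling(slide$height_px * f))
    raster <- if (abs(f - 1) < 1e-12) slide$pixels else resample_nn(slide$pixels, lh, lw)
    structure(
      list(magnification = m, width_px = lw, height_px = lh,
           tile_size = tile_size, tiles = split_tiles(raster, tile_size)),
      class = "pyramid_level"
    )
  })
  names(levels) <- format_mag(mags)

  structure(
    list(slide_id = slide_id,
         base_width = slide$width_px, base_height = slide$height_px,
         base_magnification = slide$base_magnification,
         tile_size = tile_size, magnifications = mags, levels = levels),
    class = "tile_pyramid"
  )
}

format_mag <- function(m) sprintf("%g", m)

split_tiles <- function(raster, ts) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  n_tr <- ceiling(h / ts); n_tc <- ceiling(w / ts)
  lapply(seq_len(n_tr), function(tr) {
    r0 <- (tr - 1L) * ts + 1L; r1 <- min(tr * ts, h)
    lapply(seq_len(n_tc), function(tc) {
      c0 <- (tc - 1L) * ts + 1L; c1 <- min(tc * ts, w)
      raster[r0:r1, c0:c1, , drop = FALSE]
    })
  })
}

#' Reassemble a pyramid level from its tiles
#'
#' @param level a `pyramid_level`.
#' @return the level raster, bit-identical to the pre-tiling raster.
#' @export
stitch_level <- function(level) {
  out <- blank_raster(level$height_px, level$width_px, 0L)
  ts <- level$tile_size
  for (tr in seq_along(level$tiles)) {
    for (tc in seq_along(level$tiles[[tr]])) {
      tile <- level$tiles[[tr]][[tc]]
      r0 <- (tr - 1L) * ts
      c0 <- (tc - 1L) * ts
      out[r0 + seq_len(dim(tile)[1]), c0 + seq_len(dim(tile)[2]), ] <- tile
    }
  }
  out
}

find_level <- function(pyramid, magnification) {
  i <- which(abs(pyramid$magnifications - magnification) < 1e-9)
  if (length(i) != 1) {
    stop_not_found("magnification %g is not a stored pyramid level (stored: %s)",
                   magnification, paste(format_mag(pyramid$magnifications), collapse = ", "))
  }
  pyramid$levels[[i]]
}

#' Magnification of the stored level a request is served from
#'
#' The source level for a requested magnification is the stored level with the
#' smallest magnification that is still >= the request, so synthesis only ever
#' reduces (never enlarges) stored pixels.
#'
#' @param pyramid a `tile_pyramid`.
#' @param magnification requested magnification, in `(0, base]`.
#' @return the source level's magnification.
#' @export
source_level_magnification <- function(pyramid, magnification) {
  if (!is_scalar_num(magnification) || magnification <= 0) {
    stop_invalid("magnification must be a positive number")
  }
  if (magnification > pyramid$base_magnification + 1e-9) {
    stop_invalid("magnification %g exceeds the highest scanned magnification (%g)",
                 magnification, pyramid$base_magnification)
  }
  cand <- pyramid$magnifications[pyramid$magnifications >= magnification - 1e-9]
  min(cand)
}

# Copy the half-open in-bounds region [x0,x1) x [y0,y1) (0-based, level frame)
# out of the tile grid.
extract_from_tiles <- function(level, x0, y0, x1, y1) {
  ts <- level$tile_size
  out <- blank_raster(y1 - y0, x1 - x0, 0L)
  for (tr in (y0 %/% ts):((y1 - 1L) %/% ts)) {
    tile_r0 <- tr * ts
    for (tc in (x0 %/% ts):((x1 - 1L) %/% ts)) {
      tile_c0 <- tc * ts
      tile <- level$tiles[[tr + 1L]][[tc + 1L]]
      ry0 <- max(y0, tile_r0); ry1 <- min(y1, tile_r0 + dim(tile)[1])
      rx0 <- max(x0, tile_c0); rx1 <- min(x1, tile_c0 + dim(tile)[2])
      out[(ry0 - y0 + 1L):(ry1 - y0), (rx0 - x0 + 1L):(rx1 - x0), ] <-
        tile[(ry0 - tile_r0 + 1L):(ry1 - tile_r0),
             (rx0 - tile_c0 + 1L):(rx1 - tile_c0), , drop = FALSE]
    }
  }
  out
}

#' Read a region of a stored pyramid level
#'
#' Coordinates are 0-based, top-left origin, half-open `[x, x+w)`; pixels
#' outside the level bounds are white (255,255,255), pixels inside are
#' bit-identical to the stored level raster.
#'
#' @param pyramid a `tile_pyramid`.
#' @param magnification a stored level magnification.
#' @param x,y region origin in level-frame pixels (may be negative).
#' @param w,h region extent in pixels, >= 1.
#' @return an integer raster of dimension `c(h, w, 3)`.
#' @export
read_level_region <- function(pyramid, magnification, x, y, w, h) {
  level <- find_level(pyramid, magnification)
  if (!is_count(w) || !is_count(h)) stop_invalid("w and h must be positive integers")
  x <- as.integer(x); y <- as.integer(y); w <- as.integer(w); h <- as.integer(h)
  out <- blank_raster(h, w)
  x0 <- max(x, 0L); x1 <- min(x + w, level$width_px)
  y0 <- max(y, 0L); y1 <- min(y + h, level$height_px)
  if (x0 < x1 && y0 < y1) {
    out[(y0 - y + 1L):(y1 - y), (x0 - x + 1L):(x1 - x), ] <-
      extract_from_tiles(level, x0, y0, x1, y1)
  }
  out
}

#' Serve a region at an arbitrary magnification
#'
#' Any magnification in `(0, base]` can be requested; non-stored
#' magnifications are synthesized by nearest-neighbor reduction of the
#' immediate higher stored level (e.g. a 5.4x request over stored
#' {40x, 10x, 1x} reduces the 10x level by a factor 0.54). Coordinates are in
#' the target-magnification pixel frame. At a stored magnification the output
#' is bit-identical to [read_level_region()].
#'
#' @inheritParams read_level_region
#' @param magnification requested magnification, in `(0, base]`.
#' @return an integer raster of dimension `c(h, w, 3)`; white outside bounds.
#' @export
region_at_magnification <- function(pyramid, magnification, x, y, w, h) {
  src_mag <- source_level_magnification(pyramid, magnification)
  level <- find_level(pyramid, src_mag)
  if (!is_count(w) || !is_count(h)) stop_invalid("w and h must be positive integers")
  x <- as.integer(x); y <- as.integer(y); w <- as.integer(w); h <- as.integer(h)

  f <- magnification / pyramid$base_magnification
  tw <- as.integer(ceiling(pyramid$base_width * f))
  th <- as.integer(ceiling(pyramid$base_height * f))

  out <- blank_raster(h, w)
  x0 <- max(x, 0L); x1 <- min(x + w, tw)
  y0 <- max(y, 0L); y1 <- min(y + h, th)
  if (x0 >= x1 || y0 >= y1) return(out)

  # Source index (0-based) of each in-bounds target pixel, half-pixel-centre.
  sx <- pmin(pmax(floor((seq.int(x0, x1 - 1L) + 0.5) * level$width_px / tw), 0),
             level$width_px - 1L)
  sy <- pmin(pmax(floor((seq.int(y0, y1 - 1L) + 0.5) * level$height_px / th), 0),
             level$height_px - 1L)
  block <- extract_from_tiles(level, as.integer(min(sx)), as.integer(min(sy)),
                              as.integer(max(sx)) + 1L, as.integer(max(sy)) + 1L)
  out[(y0 - y + 1L):(y1 - y), (x0 - x + 1L):(x1 - x), ] <-
    block[as.integer(sy - min(sy)) + 1L, as.integer(sx - min(sx)) + 1L, , drop = FALSE]
  out
}

#' @export
print.tile_pyramid <- function(x, ...) {
  cat(sprintf("<tile_pyramid> '%s' %d x %d px, tile %d, levels: %s\n",
              x$slide_id, x$base_width, x$base_height, x$tile_size,
              paste0(format_mag(x$magnifications), "x", collapse = " ")))
  invisible(x)
}

# --- on-disk layout: DZI-like directory of PNG tiles + pyramid.json --------

#' Write a pyramid to a directory
#'
#' Layout: `pyramid.json` metadata plus one `level_<mag>` directory per level
#' holding `{row}_{col}.png` tiles (0-based indices).
#'
#' @param pyramid a `tile_pyramid`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyramid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(slide_id = pyramid$slide_id,
               base_width = pyramid$base_width,
               base_height = pyramid$base_height,
               base_magnification = pyramid$base_magnification,
               tile_size = pyramid$tile_size,
               magnifications = pyramid$magnifications)
  jsonlite::write_json(meta, file.path(dir, "pyramid.json"), auto_unbox = TRUE, digits = NA)
  for (level in pyramid$levels) {
    ldir <- file.path(dir, paste0("level_", format_mag(level$magnification)))
    dir.create(ldir, showWarnings = FALSE)
    for (tr in seq_along(level$tiles)) {
      for (tc in seq_along(level$tiles[[tr]])) {
        png::writePNG(level$tiles[[tr]][[tc]] / 255,
                      file.path(ldir, sprintf("%d_%d.png", tr - 1L, tc - 1L)))
      }
    }
  }
  invisible(dir)
}

#' Read a pyramid written by [write_pyramid()]
#'
#' @param dir directory containing `pyramid.json` and level tile directories.
#' @return a `tile_pyramid`.
#' @export
read_pyramid <- function(dir) {
  meta_path <- file.path(dir, "pyramid.json")
  if (!file.exists(meta_path)) stop_not_found("no pyramid.json under '%s'", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ts <- as.integer(meta$tile_size)
  mags <- sort(as.numeric(meta$magnifications), decreasing = TRUE)
  levels <- lapply(mags, function(m) {
    f <- m / meta$base_magnification
    lw <- as.integer(ceiling(meta$base_width * f))
    lh <- as.integer(ceiling(meta$base_height * f))
    ldir <- file.path(dir, paste0("level_", format_mag(m)))
    n_tr <- ceiling(lh / ts); n_tc <- ceiling(lw / ts)
    tiles <- lapply(seq_len(n_tr), function(tr) {
      lapply(seq_len(n_tc), function(tc) {
        arr <- png::readPNG(file.path(ldir, sprintf("%d_%d.png", tr - 1L, tc - 1L)))
        array(as.integer(round(arr * 255)), dim = dim(arr))
      })
    })
    structure(list(magnification = m, width_px = lw, height_px = lh,
                   tile_size = ts, tiles = tiles),
              class = "pyramid_level")
  })
  names(levels) <- format_mag(mags)
  structure(
    list(slide_id = meta$slide_id, base_width = as.integer(meta$base_width),
         base_height = as.integer(meta$base_height),
         base_magnification = as.numeric(meta$base_magnification),
         tile_size = ts, magnifications = mags, levels = levels),
    class = "tile_pyramid"
  )
}
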