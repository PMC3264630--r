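# Multi-resolution prefetch cache: a 9x12 grid of 256x256 cells around the
# viewport, the centre 3x4 block at full resolution, graded down-sampling
# towards the periphery, promotion of cells entering the screen, and grid
# re-anchoring when the screen escapes the grid.

#' The default per-cell resolution pattern
#'
#' A 9 x 12 matrix of pixel-area fractions: the central 3x4 block (rows 4-6,
#' columns 5-8) is full resolution (1.00), surrounded by rings at 0.25, 0.125
#' and 0.0625. The fractions are non-increasing away from the centre, so the
#' further a cached cell sits from the screen the blurrier it is.
#'
#' @return a 9 x 12 numeric matrix of fractions in (0, 1].
#' @export
default_resolution_pattern <- function() {
  p <- matrix(12.5, 9, 12)
  p[, c(1, 12)] <- 6.25
  p[3:7, 3:10] <- 25
  p[4:6, 5:8] <- 100
  p / 100
}

#' Resolution fraction of a cache-grid cell
#'
#' @param row,col 1-based cell indices.
#' @param pattern fraction matrix; default [default_resolution_pattern()].
#' @return the pixel-area fraction loaded for that cell, in (0, 1].
#' @export
resolution_fraction <- function(row, col, pattern = default_resolution_pattern()) {
  if (!is_count(row) || row > nrow(pattern) || !is_count(col) || col > ncol(pattern)) {
    stop_invalid("cell (%s, %s) is outside the %d x %d grid",
                 toString(row), toString(col), nrow(pattern), ncol(pattern))
  }
  pattern[row, col]
}

#' An empty cache-grid stats record
#'
#' Counters: `pixels_loaded` (nominal pixels fetched), `pixels_naive_equivalent`
#' (what full-resolution loads of the same cells would cost), `cells_loaded`,
#' `promotions`, `grid_reloads`.
#'
#' @return a `cache_stats` list of zeroed counters.
#' @export
new_cache_stats <- function() {
  structure(list(pixels_loaded = 0, pixels_naive_equivalent = 0,
                 cells_loaded = 0, promotions = 0, grid_reloads = 0),
            class = "cache_stats")
}

#' Add two stats records
#'
#' @param a,b `cache_stats`.
#' @return their field-wise sum.
#' @export
add_stats <- function(a, b) {
  structure(Map(`+`, a, b), class = "cache_stats")
}

#' @export
print.cache_stats <- function(x, ...) {
  cat(sprintf(paste0("<cache_stats> loaded %.0f px (naive %.0f px, %.2f%% saved), ",
                     "%d cells, %d promotions, %d reloads\n"),
              x$pixels_loaded, x$pixels_naive_equivalent,
              if (x$pixels_naive_equivalent > 0)
                100 * (1 - x$pixels_loaded / x$pixels_naive_equivalent) else 0,
              x$cells_loaded, x$promotions, x$grid_reloads))
  invisible(x)
}

#' Construct an (unfilled) cache grid
#'
#' The grid lives in the pixel frame of its `magnification`: cell `(1, 1)`
#' has its top-left corner at `(anchor_x, anchor_y)` and each cell covers
#' `cell_px x cell_px` pixels. With the defaults the grid spans
#' 3072 x 2304 px, three screens wide and tall around a 1024 x 768 display.
#'
#' @param anchor_x,anchor_y slide-frame coordinates (at `magnification`) of
#'   cell (1,1)'s top-left corner.
#' @param magnification effective magnification of the grid contents.
#' @param rows,cols grid shape (default 9 x 12).
#' @param cell_px cell side in pixels (default 256).
#' @param pattern per-cell resolution-fraction matrix, `rows x cols`.
#' @return a `cache_grid` with all cells empty.
#' @export
cache_grid <- function(anchor_x, anchor_y, magnification,
                       rows = 9L, cols = 12L, cell_px = 256L,
                       pattern = default_resolution_pattern()) {
  if (!is_count(rows) || !is_count(cols) || !is_count(cell_px)) {
    stop_invalid("rows, cols and cell_px must be positive integers")
  }
  if (!is.matrix(pattern) || nrow(pattern) != rows || ncol(pattern) != cols) {
    stop_invalid("pattern must be a %d x %d matrix", rows, cols)
  }
  if (any(pattern <= 0) || any(pattern > 1)) {
    stop_invalid("pattern fractions must lie in (0, 1]")
  }
  if (!is_scalar_num(magnification) || magnification <= 0) {
    stop_invalid("magnification must be a positive number")
  }
  cells <- lapply(seq_len(rows), function(r) {
    lapply(seq_len(cols), function(c) {
      list(raster = NULL, fraction = pattern[r, c], state = "empty")
    })
  })
  # Central on-screen block: a centred rows/3 x cols/3 sub-grid (3x4 for the
  # defaults, matching a 1024x768 screen of 256 px cells).
  rc <- max(1L, as.integer(ceiling(rows / 3)))
  cc <- max(1L, as.integer(ceiling(cols / 3)))
  r0 <- as.integer((rows - rc) %/% 2) + 1L
  c0 <- as.integer((cols - cc) %/% 2) + 1L
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_px = as.integer(cell_px),
         anchor_x = anchor_x, anchor_y = anchor_y,
         magnification = magnification, pattern = pattern,
         central_rows = r0:(r0 + rc - 1L), central_cols = c0:(c0 + cc - 1L),
         cells = cells),
    class = "cache_grid"
  )
}

#' @export
print.cache_grid <- function(x, ...) {
  states <- vapply(unlist(x$cells, recursive = FALSE), function(c) c$state, "")
  cat(sprintf("<cache_grid> %d x %d cells of %d px at %gx, anchor (%g, %g); %d loaded\n",
              x$rows, x$cols, x$cell_px, x$magnification,
              x$anchor_x, x$anchor_y, sum(states == "loaded")))
  invisible(x)
}

# Grid footprint in its magnification frame, half-open.
grid_rect <- function(grid) {
  rect(grid$anchor_x, grid$anchor_y,
       grid$anchor_x + grid$cols * grid$cell_px,
       grid$anchor_y + grid$rows * grid$cell_px)
}

# Ring distance of a cell from the central block (0 inside it).
ring_distance <- function(grid, row, col) {
  dr <- max(0, min(grid$central_rows) - row, row - max(grid$central_rows))
  dc <- max(0, min(grid$central_cols) - col, col - max(grid$central_cols))
  max(dr, dc)
}

#' Deterministic load order of the grid cells
#'
#' Central (on-screen) cells dequeue first, then rings outward; ties break by
#' row then column. This is the priority order in which cells become
#' displayable, modelling asynchronous per-block display reproducibly.
#'
#' @param grid a `cache_grid`.
#' @return a data frame with columns `row`, `col`, `ring` in dequeue order.
#' @export
load_queue_order <- function(grid) {
  idx <- expand.grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  ring <- mapply(function(r, c) ring_distance(grid, r, c), idx$row, idx$col)
  ord <- order(ring, idx$row, idx$col)
  data.frame(row = idx$row[ord], col = idx$col[ord], ring = ring[ord])
}

# Fetch one cell at a given fraction via the region server and return the
# display raster plus the request log entry.
load_cell_raster <- function(grid, pyramid, row, col, fraction) {
  cp <- grid$cell_px
  side <- if (fraction >= 1) cp else max(1L, as.integer(round(cp * sqrt(fraction))))
  m_req <- grid$magnification * side / cp
  zoom <- pyramid$base_magnification / m_req
  ox <- grid$anchor_x + (col - 1L) * cp
  oy <- grid$anchor_y + (row - 1L) * cp
  x <- as.integer(round(ox * side / cp))
  y <- as.integer(round(oy * side / cp))
  resp <- handle_request(pyramid, region_request(x, y, side, side, zoom))
  raster <- if (side < cp) resample_nn(resp$raster, cp, cp) else resp$raster
  list(raster = raster,
       log = data.frame(row = row, col = col, fraction = fraction,
                        source_px = side, magnification = m_req, zoom = zoom))
}

#' Fill every empty cell of the grid
#'
#' Cells load in [load_queue_order()] (centre first). A cell at fraction `f`
#' fetches a source block of `round(cell_px * sqrt(f))` px per side at the
#' correspondingly reduced magnification, then enlarges it to the cell by
#' nearest neighbor — e.g. a 0.25 cell on a 40x grid loads a 128 x 128 block
#' at 20x. Savings are accounted at the nominal fraction: each load adds
#' `f * cell_px^2` to `pixels_loaded` and `cell_px^2` to the naive
#' equivalent. Cells beyond the slide come back white and are counted at
#' their nominal fraction like any other cell.
#'
#' @param grid a `cache_grid`.
#' @param pyramid a `tile_pyramid` with base magnification >= the grid's.
#' @return list with the filled `grid`, a `stats` delta, and a `loads` data
#'   frame logging each request (row, col, fraction, source_px,
#'   magnification, zoom).
#' @export
fill_grid <- function(grid, pyramid) {
  if (grid$magnification > pyramid$base_magnification + 1e-9) {
    stop_invalid("grid magnification %g exceeds base magnification %g",
                 grid$magnification, pyramid$base_magnification)
  }
  stats <- new_cache_stats()
  logs <- list()
  queue <- load_queue_order(grid)
  cp2 <- as.numeric(grid$cell_px)^2
  for (k in seq_len(nrow(queue))) {
    r <- queue$row[k]; c <- queue$col[k]
    cell <- grid$cells[[r]][[c]]
    if (cell$state != "empty") next
    got <- load_cell_raster(grid, pyramid, r, c, cell$fraction)
    grid$cells[[r]][[c]] <- list(raster = got$raster, fraction = cell$fraction,
                                 state = "loaded")
    stats$pixels_loaded <- stats$pixels_loaded + cell$fraction * cp2
    stats$pixels_naive_equivalent <- stats$pixels_naive_equivalent + cp2
    stats$cells_loaded <- stats$cells_loaded + 1
    logs[[length(logs) + 1L]] <- got$log
  }
  list(grid = grid, stats = stats,
       loads = if (length(logs)) do.call(rbind, logs) else
         data.frame(row = integer(), col = integer(), fraction = numeric(),
                    source_px = integer(), magnification = numeric(),
                    zoom = numeric()))
}

#' Cells whose screen projection intersects the display
#'
#' @param grid a `cache_grid`.
#' @param viewport a `viewport_state` mapping the grid's magnification frame
#'   to the screen.
#' @return data frame with columns `row`, `col` (possibly zero rows).
#' @export
visible_cells <- function(grid, viewport) {
  screen <- rect(0, 0, viewport$screen_width, viewport$screen_height)
  cp <- grid$cell_px
  out_r <- integer(); out_c <- integer()
  for (r in seq_len(grid$rows)) {
    for (c in seq_len(grid$cols)) {
      cell_rect <- rect(grid$anchor_x + (c - 1L) * cp, grid$anchor_y + (r - 1L) * cp,
                        grid$anchor_x + c * cp, grid$anchor_y + r * cp)
      if (!rect_empty(rect_intersect(rect_transform(cell_rect, viewport$cumulative$matrix),
                                     screen))) {
        out_r <- c(out_r, r); out_c <- c(out_c, c)
      }
    }
  }
  data.frame(row = out_r, col = out_c)
}

#' Promote visible cells to full resolution
#'
#' Every cell intersecting the screen that is not already at full resolution
#' is re-fetched at fraction 1 and replaces its blurred version; cells off
#' screen stay untouched. Promotion order follows [load_queue_order()].
#' Idempotent: a second call performs zero promotions.
#'
#' @inheritParams visible_cells
#' @param pyramid a `tile_pyramid`.
#' @return list with the updated `grid`, a `stats` delta, and `promoted`
#'   (data frame of promoted cells in order).
#' @export
promote_visible <- function(grid, viewport, pyramid) {
  vis <- visible_cells(grid, viewport)
  key <- paste(vis$row, vis$col)
  stats <- new_cache_stats()
  cp2 <- as.numeric(grid$cell_px)^2
  promoted <- list()
  queue <- load_queue_order(grid)
  for (k in seq_len(nrow(queue))) {
    r <- queue$row[k]; c <- queue$col[k]
    if (!(paste(r, c) %in% key)) next
    cell <- grid$cells[[r]][[c]]
    if (cell$state == "loaded" && cell$fraction >= 1) next
    got <- load_cell_raster(grid, pyramid, r, c, 1)
    grid$cells[[r]][[c]] <- list(raster = got$raster, fraction = 1, state = "loaded")
    stats$pixels_loaded <- stats$pixels_loaded + cp2
    stats$pixels_naive_equivalent <- stats$pixels_naive_equivalent + cp2
    stats$promotions <- stats$promotions + 1
    promoted[[length(promoted) + 1L]] <- data.frame(row = r, col = c)
  }
  list(grid = grid, stats = stats,
       promoted = if (length(promoted)) do.call(rbind, promoted) else
         data.frame(row = integer(), col = integer()))
}

#' Re-anchor the grid if the screen has escaped it
#'
#' The grid only reloads when part of the screen is no longer covered by the
#' grid footprint (a cumulative pan beyond the one-screen margin, or a
#' zoom-out shrinking the footprint inside the screen) — never after each
#' single transform. On reload a fresh grid is anchored centred on the
#' current viewport, at magnification `min(base, base * viewport scale)`
#' relative to the base frame, and filled with its pattern.
#'
#' @inheritParams promote_visible
#' @return list with `grid`, `stats` delta, `reloaded` flag, and `loads` (the
#'   fill log when a reload happened).
#' @export
maybe_reanchor <- function(grid, viewport, pyramid) {
  inv <- solve(viewport$cumulative$matrix)
  screen_in_grid <- rect_transform(rect(0, 0, viewport$screen_width,
                                        viewport$screen_height), inv)
  if (rect_contains(grid_rect(grid), screen_in_grid)) {
    return(list(grid = grid, stats = new_cache_stats(), reloaded = FALSE,
                loads = NULL))
  }
  base <- pyramid$base_magnification
  scale_base <- viewport_scale(viewport) * grid$magnification / base
  new_mag <- min(base, base * scale_base)
  # Screen centre in the new magnification frame.
  centre_cur <- (inv %*% c(viewport$screen_width / 2, viewport$screen_height / 2, 1))[1:2]
  centre_new <- centre_cur * new_mag / grid$magnification
  half_w <- grid$cols * grid$cell_px / 2
  half_h <- grid$rows * grid$cell_px / 2
  fresh <- cache_grid(round(centre_new[1] - half_w), round(centre_new[2] - half_h),
                      new_mag, grid$rows, grid$cols, grid$cell_px, grid$pattern)
  filled <- fill_grid(fresh, pyramid)
  stats <- filled$stats
  stats$grid_reloads <- stats$grid_reloads + 1
  list(grid = filled$grid, stats = stats, reloaded = TRUE, loads = filled$loads)
}

#' Assemble the loaded grid content under a viewport rectangle
#'
#' Stitches the cell rasters covering the screen into one `screen_height x
#' screen_width` raster (white where no loaded cell covers a pixel). Only
#' valid for viewports whose mag-frame scale is 1 (screen pixels map 1:1 to
#' grid pixels), which is how the session uses the grid.
#'
#' @inheritParams visible_cells
#' @return an integer raster `screen_height x screen_width x 3`.
#' @export
render_screen <- function(grid, viewport) {
  m <- viewport$cumulative$matrix
  if (abs(m[1, 1] - 1) > 1e-9) {
    stop_invalid("render_screen requires a unit-scale mag-frame viewport")
  }
  out <- blank_raster(viewport$screen_height, viewport$screen_width)
  cp <- grid$cell_px
  vis <- visible_cells(grid, viewport)
  for (k in seq_len(nrow(vis))) {
    r <- vis$row[k]; c <- vis$col[k]
    cell <- grid$cells[[r]][[c]]
    if (cell$state != "loaded") next
    # Cell origin on screen (integral for unit-scale session viewports).
    sx <- as.integer(round(grid$anchor_x + (c - 1L) * cp + m[1, 3]))
    sy <- as.integer(round(grid$anchor_y + (r - 1L) * cp + m[2, 3]))
    x0 <- max(0, sx); x1 <- min(viewport$screen_width, sx + cp)
    y0 <- max(0, sy); y1 <- min(viewport$screen_height, sy + cp)
    if (x0 >= x1 || y0 >= y1) next
    out[(y0 + 1):y1, (x0 + 1):x1, ] <-
      cell$raster[(y0 - sy + 1):(y1 - sy), (x0 - sx + 1):(x1 - sx), , drop = FALSE]
  }
  out
}

#' Is every visible screen pixel backed by a loaded cell?
#'
#' Coverage safety: the screen rectangle must lie inside the grid footprint
#' and every cell it touches must be loaded — i.e. no white background can
#' appear from cache misses.
#'
#' @inheritParams visible_cells
#' @return TRUE/FALSE.
#' @export
screen_fully_cached <- function(grid, viewport) {
  inv <- solve(viewport$cumulative$matrix)
  screen_in_grid <- rect_transform(rect(0, 0, viewport$screen_width,
                                        viewport$screen_height), inv)
  if (!rect_contains(grid_rect(grid), screen_in_grid)) return(FALSE)
  vis <- visible_cells(grid, viewport)
  all(vapply(seq_len(nrow(vis)), function(k) {
    grid$cells[[vis$row[k]]][[vis$col[k]]]$state == "loaded"
  }, logical(1)))
}
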