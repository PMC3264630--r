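# Session orchestration: configuration, manipulation traces, trace replay
# against the full stack, and the smart-vs-naive caching comparison.

#' Engine configuration
#'
#' Defaults are the reference device and grid: 1024 x 768 screen, 9 x 12 grid
#' of 256 px cells with the graded resolution pattern, stored magnifications
#' {40, 10, 1}, 256 px tiles.
#'
#' @param screen_width,screen_height display size in pixels.
#' @param grid_rows,grid_cols cache-grid shape.
#' @param cell_px cache-cell side in pixels.
#' @param pattern resolution-fraction matrix (`grid_rows x grid_cols`).
#' @param magnifications stored pyramid magnifications.
#' @param tile_size pyramid tile side in pixels.
#' @return a `slidecache_config`.
#' @export
slidecache_config <- function(screen_width = 1024L, screen_height = 768L,
                              grid_rows = 9L, grid_cols = 12L, cell_px = 256L,
                              pattern = default_resolution_pattern(),
                              magnifications = c(40, 10, 1),
                              tile_size = 256L) {
  check <- function(ok, field, what) {
    if (!ok) stop_invalid("config field '%s' is invalid: %s", field, what)
  }
  check(is_count(screen_width), "screen_width", "must be a positive integer")
  check(is_count(screen_height), "screen_height", "must be a positive integer")
  check(is_count(grid_rows), "grid_rows", "must be a positive integer")
  check(is_count(grid_cols), "grid_cols", "must be a positive integer")
  check(is_count(cell_px), "cell_px", "must be a positive integer")
  check(is.matrix(pattern) && nrow(pattern) == grid_rows &&
          ncol(pattern) == grid_cols, "pattern",
        sprintf("must be a %d x %d matrix", grid_rows, grid_cols))
  check(all(pattern > 0) && all(pattern <= 1), "pattern",
        "fractions must lie in (0, 1]")
  check(is.numeric(magnifications) && length(magnifications) >= 1 &&
          all(magnifications > 0) && !anyDuplicated(magnifications),
        "magnifications", "must be unique positive numbers")
  check(is_count(tile_size, 16), "tile_size", "must be an integer >= 16")
  structure(list(screen_width = as.integer(screen_width),
                 screen_height = as.integer(screen_height),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_px = as.integer(cell_px), pattern = pattern,
                 magnifications = as.numeric(magnifications),
                 tile_size = as.integer(tile_size)),
            class = "slidecache_config")
}

#' Read a configuration from a JSON file
#'
#' Missing fields take their defaults; a malformed field raises an
#' invalid-argument error naming it.
#'
#' @param path JSON file with any subset of the [slidecache_config()] fields.
#' @return a `slidecache_config`.
#' @export
read_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_parse("cannot parse config '%s': %s",
                                                 path, conditionMessage(e)))
  args <- list()
  for (f in c("screen_width", "screen_height", "grid_rows", "grid_cols",
              "cell_px", "magnifications", "tile_size")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$pattern)) args$pattern <- as.matrix(raw$pattern)
  do.call(slidecache_config, args)
}

# --- manipulation traces (JSON lines) --------------------------------------

#' Read a session trace
#'
#' One JSON object per line. Manipulation events:
#' `{"type":"pan","dx":..,"dy":..}`,
#' `{"type":"zoom","scale":..,"focal_x":..,"focal_y":..}`,
#' `{"type":"pan_zoom", ...both...}`. Annotation directives:
#' `{"type":"begin_annotation","kind":"circle"|"rectangle"}`,
#' `{"type":"edit_annotation","dx":..,"dy":..,"dw":..,"dh":..}`,
#' `{"type":"commit_annotation","label":".."}`.
#'
#' @param path a JSON-lines trace file.
#' @return list of trace items (each a parsed record with a `type`).
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_parse("trace line %d: %s", i,
                                                   conditionMessage(e)))
    if (is.null(rec$type)) stop_parse("trace line %d: missing 'type'", i)
    rec
  })
}

#' Write a session trace
#'
#' @param trace list of trace items as returned by [read_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  lines <- vapply(trace, function(rec) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

num_or <- function(x, default = 0) if (is.null(x)) default else as.numeric(x)

trace_item_event <- function(rec) {
  switch(rec$type,
         pan = manipulation_event("pan", dx = num_or(rec$dx), dy = num_or(rec$dy)),
         zoom = manipulation_event("zoom", scale = num_or(rec$scale, 1),
                                   focal_x = num_or(rec$focal_x),
                                   focal_y = num_or(rec$focal_y)),
         pan_zoom = manipulation_event("pan_and_zoom",
                                       dx = num_or(rec$dx), dy = num_or(rec$dy),
                                       scale = num_or(rec$scale, 1),
                                       focal_x = num_or(rec$focal_x),
                                       focal_y = num_or(rec$focal_y)),
         NULL)
}

# Mag-frame viewport (grid frame -> screen) derived from the base viewport.
mag_viewport <- function(viewport_base, grid_mag, base_mag) {
  viewport_state(affine_compose(list(affine_scale(base_mag / grid_mag),
                                     viewport_base$cumulative)),
                 viewport_base$screen_width, viewport_base$screen_height)
}

#' Replay a manipulation trace against the full stack
#'
#' Starts centred on the slide at base magnification, fills the cache grid,
#' then for each trace item: applies the manipulation to the viewport
#' (ignored while an annotation is being edited), re-anchors the grid if the
#' screen escaped it, and promotes newly visible cells to full resolution.
#' Annotation directives drive the editing state machine; a directive that
#' violates it (e.g. `begin` while already editing) raises a state error
#' naming the offending trace line.
#'
#' @param pyramid a `tile_pyramid`.
#' @param trace list of trace items ([read_trace()]), possibly empty.
#' @param config a `slidecache_config`.
#' @return list with `stats` (aggregate `cache_stats`), `viewport` (final
#'   base-frame `viewport_state`), `grid` (final `cache_grid`),
#'   `annotations` (final `annotation_session`), and `log` (per-event data
#'   frame of stats deltas).
#' @export
run_session <- function(pyramid, trace = list(), config = slidecache_config()) {
  base <- pyramid$base_magnification
  vp <- viewport_state(
    affine_translate(config$screen_width / 2 - pyramid$base_width / 2,
                     config$screen_height / 2 - pyramid$base_height / 2),
    config$screen_width, config$screen_height)
  grid_mag <- base
  mvp <- mag_viewport(vp, grid_mag, base)
  centre <- screen_to_slide(mvp, c(config$screen_width / 2, config$screen_height / 2))
  grid <- cache_grid(round(centre[1] - config$grid_cols * config$cell_px / 2),
                     round(centre[2] - config$grid_rows * config$cell_px / 2),
                     grid_mag, config$grid_rows, config$grid_cols,
                     config$cell_px, config$pattern)
  filled <- fill_grid(grid, pyramid)
  grid <- filled$grid
  stats <- filled$stats
  session <- annotation_session()
  log <- list(data.frame(line = 0L, type = "initial_fill",
                         pixels_loaded = filled$stats$pixels_loaded,
                         pixels_naive_equivalent = filled$stats$pixels_naive_equivalent,
                         promotions = 0, grid_reloads = 0))

  for (i in seq_along(trace)) {
    rec <- trace[[i]]
    delta <- new_cache_stats()
    ev <- trace_item_event(rec)
    if (!is.null(ev)) {
      if (session_allows_manipulation(session)) {
        vp <- apply_event(vp, ev)
        mvp <- mag_viewport(vp, grid$magnification, base)
        re <- maybe_reanchor(grid, mvp, pyramid)
        grid <- re$grid
        delta <- add_stats(delta, re$stats)
        if (re$reloaded) mvp <- mag_viewport(vp, grid$magnification, base)
        pr <- promote_visible(grid, mvp, pyramid)
        grid <- pr$grid
        delta <- add_stats(delta, pr$stats)
      }
    } else if (rec$type == "begin_annotation") {
      session <- with_trace_line(i, begin_annotation(session, rec$kind, vp))
    } else if (rec$type == "edit_annotation") {
      session <- with_trace_line(i, edit_annotation(session,
                                                    num_or(rec$dx), num_or(rec$dy),
                                                    num_or(rec$dw), num_or(rec$dh),
                                                    vp))
    } else if (rec$type == "commit_annotation") {
      session <- with_trace_line(i, commit_annotation(session,
                                                      num_or_chr(rec$label)))
    } else {
      stop_parse("trace line %d: unknown type '%s'", i, rec$type)
    }
    stats <- add_stats(stats, delta)
    log[[length(log) + 1L]] <-
      data.frame(line = i, type = rec$type,
                 pixels_loaded = delta$pixels_loaded,
                 pixels_naive_equivalent = delta$pixels_naive_equivalent,
                 promotions = delta$promotions, grid_reloads = delta$grid_reloads)
  }

  list(stats = stats, viewport = vp, grid = grid, annotations = session,
       log = do.call(rbind, log))
}

num_or_chr <- function(x, default = "") if (is.null(x)) default else as.character(x)

with_trace_line <- function(line, expr) {
  tryCatch(
    expr,
    slidecache_state_error = function(e) {
      stop_state("trace line %d: %s", line, conditionMessage(e))
    }
  )
}

#' Compare smart caching against naive full-resolution caching
#'
#' Replays the trace twice — once with the configured graded resolution
#' pattern and once with every cell at full resolution — and reports total
#' pixels loaded by each strategy and the percentage reduction. With an
#' empty trace this is the single-grid-fill comparison: the graded pattern
#' loads 75.58% less data than loading all 108 cells at full resolution.
#'
#' @param pyramid a `tile_pyramid`.
#' @param trace list of trace items.
#' @param config a `slidecache_config`.
#' @return list with `smart_pixels`, `naive_pixels`, `reduction_percent`,
#'   and the per-event logs `smart_log`, `naive_log`.
#' @export
compare_strategies <- function(pyramid, trace = list(),
                               config = slidecache_config()) {
  smart <- run_session(pyramid, trace, config)
  naive_config <- config
  naive_config$pattern <- matrix(1, config$grid_rows, config$grid_cols)
  naive <- run_session(pyramid, trace, naive_config)
  list(smart_pixels = smart$stats$pixels_loaded,
       naive_pixels = naive$stats$pixels_loaded,
       reduction_percent = 100 * (1 - smart$stats$pixels_loaded /
                                    naive$stats$pixels_loaded),
       smart_log = smart$log, naive_log = naive$log)
}
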