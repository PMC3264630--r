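test_that("the default resolution pattern matches the printed table", {
  printed <- printed_resolution_table()
  expect_equal(default_resolution_pattern(), unname(printed / 100))
  expect_identical(resolution_fraction(4, 5), 1)
  expect_identical(resolution_fraction(1, 1), 0.0625)
  expect_identical(resolution_fraction(3, 3), 0.25)
  expect_error(resolution_fraction(0, 1), class = "slidecache_invalid_argument")
  expect_error(resolution_fraction(4, 13), class = "slidecache_invalid_argument")
  # summed cell-equivalents of the printed table
  expect_equal(sum(default_resolution_pattern()), sum(printed) / 100)
  expect_equal(sum(printed) / 100, 26.375)
  # blur is monotone away from the central block along every row and column
  p <- default_resolution_pattern()
  for (r in 1:9) {
    expect_true(all(diff(p[r, 1:5]) >= 0))   # approaching the centre
    expect_true(all(diff(p[r, 8:12]) <= 0))  # leaving the centre
  }
  for (cc in 1:12) {
    expect_true(all(diff(p[1:4, cc]) >= 0))
    expect_true(all(diff(p[6:9, cc]) <= 0))
  }
})

test_that("the default grid has the reference geometry", {
  g <- cache_grid(0, 0, 40)
  expect_identical(c(g$rows, g$cols, g$cell_px), c(9L, 12L, 256L))
  expect_identical(c(g$cols * g$cell_px, g$rows * g$cell_px), c(3072L, 2304L))
  expect_identical(g$central_rows, 4:6)
  expect_identical(g$central_cols, 5:8)
  expect_identical(length(g$central_rows) * length(g$central_cols), 12L)
  expect_identical(g$rows * g$cols - 12L, 96L)
  expect_error(cache_grid(0, 0, 40, pattern = matrix(1, 2, 2)),
               class = "slidecache_invalid_argument")
  expect_error(cache_grid(0, 0, 40, pattern = matrix(2, 9, 12)),
               class = "slidecache_invalid_argument")
})

test_that("cells dequeue centre-first in deterministic ring order", {
  g <- cache_grid(0, 0, 40)
  q <- load_queue_order(g)
  expect_identical(nrow(q), 108L)
  first12 <- q[1:12, ]
  expect_true(all(first12$row %in% 4:6 & first12$col %in% 5:8))
  expect_true(all(diff(q$ring) >= 0))
  # deterministic: identical on recomputation
  expect_identical(q, load_queue_order(g))
})

test_that("filling the grid loads the graded fractions and books the savings", {
  p <- med_pyramid()
  g <- cache_grid(-1024, -768, 40)
  filled <- fill_grid(g, p)
  expect_identical(filled$stats$cells_loaded, 108)
  expect_equal(filled$stats$pixels_loaded / filled$stats$pixels_naive_equivalent,
               26.375 / 108, tolerance = 1e-12)
  expect_true(all(vapply(unlist(filled$grid$cells, recursive = FALSE),
                         function(cell) cell$state == "loaded", logical(1))))
  # a 0.25-fraction cell at 40x requested a 128 px block at 20x (zoom 2)
  log25 <- filled$loads[filled$loads$fraction == 0.25, ][1, ]
  expect_identical(log25$source_px, 128L)
  expect_identical(log25$magnification, 20)
  expect_identical(log25$zoom, 2)
  # 12.5% and 6.25% cells use round(256 * sqrt(f)) px source blocks
  expect_identical(unique(filled$loads$source_px[filled$loads$fraction == 0.125]), 91L)
  expect_identical(unique(filled$loads$source_px[filled$loads$fraction == 0.0625]), 64L)
  # an all-full-resolution pattern degenerates to the naive ratio 1
  naive <- fill_grid(cache_grid(-1024, -768, 40, pattern = matrix(1, 9, 12)), p)
  expect_equal(naive$stats$pixels_loaded, naive$stats$pixels_naive_equivalent)
})

test_that("visible cells are the central 3x4 block for a centred grid", {
  g <- cache_grid(-1024, -768, 40)
  vp <- centred_grid_viewport(g)
  vis <- visible_cells(g, vp)
  expect_identical(nrow(vis), 12L)
  expect_true(all(vis$row %in% 4:6 & vis$col %in% 5:8))
  # a full-screen-width pan keeps the screen inside the 9x12 grid
  panned <- apply_event(vp, manipulation_event("pan", dx = -1024))
  vis2 <- visible_cells(g, panned)
  expect_gt(nrow(vis2), 0)
  expect_true(all(vis2$col <= 12))
  # viewport far outside the grid sees nothing
  gone <- apply_event(vp, manipulation_event("pan", dx = -10000))
  expect_identical(nrow(visible_cells(g, gone)), 0L)
})

test_that("promotion sharpens exactly the visible cells and is idempotent", {
  p <- med_pyramid()
  g <- cache_grid(-1024, -768, 40)
  vp <- centred_grid_viewport(g)
  filled <- fill_grid(g, p)
  pr <- promote_visible(filled$grid, vp, p)
  # centre was already full resolution: no promotions on a fresh centred grid
  expect_identical(pr$stats$promotions, 0)
  # the on-screen mosaic equals a direct full-resolution request bit-exactly
  mosaic <- render_screen(pr$grid, vp)
  direct <- handle_request(p, region_request(-1024 + 4 * 256, -768 + 3 * 256,
                                             1024, 768, zoom = 1))$raster
  expect_identical(mosaic, direct)
  # pan one cell to the right: exactly the entering column is promoted
  panned <- apply_event(vp, manipulation_event("pan", dx = -256))
  pr2 <- promote_visible(pr$grid, panned, p)
  expect_identical(pr2$stats$promotions, 3)
  expect_true(all(pr2$promoted$col == 9L))
  expect_identical(sort(pr2$promoted$row), 4:6)
  # promoted mosaic again matches the direct request
  expect_identical(render_screen(pr2$grid, panned),
                   handle_request(p, region_request(4 * 256 - 1024 + 256,
                                                    3 * 256 - 768,
                                                    1024, 768, zoom = 1))$raster)
  # idempotent
  pr3 <- promote_visible(pr2$grid, panned, p)
  expect_identical(pr3$stats$promotions, 0)
})

test_that("the grid reloads only when the screen escapes it", {
  p <- med_pyramid()
  g <- fill_grid(cache_grid(-1024, -768, 40), p)$grid
  vp <- centred_grid_viewport(g)
  # single pans up to one screen width/height: no reload
  for (d in list(c(-1024, 0), c(1024, 0), c(0, -768), c(0, 768), c(-1024, 768))) {
    moved <- apply_event(vp, manipulation_event("pan", dx = d[1], dy = d[2]))
    re <- maybe_reanchor(g, moved, p)
    expect_false(re$reloaded)
  }
  # a cumulative 2000 px pan exceeds the 1024 px margin: reload
  far <- apply_event(vp, manipulation_event("pan", dx = -2000))
  re <- maybe_reanchor(g, far, p)
  expect_true(re$reloaded)
  expect_identical(re$stats$grid_reloads, 1)
  expect_true(screen_fully_cached(re$grid, centred_grid_viewport(re$grid)))
  # zoom-in: footprint grows, no reload
  zin <- apply_event(vp, manipulation_event("zoom", scale = 2,
                                            focal_x = 512, focal_y = 384))
  expect_false(maybe_reanchor(g, zin, p)$reloaded)
  # strong zoom-out: footprint shrinks inside the screen, reload
  zout <- apply_event(vp, manipulation_event("zoom", scale = 0.2,
                                             focal_x = 512, focal_y = 384))
  re2 <- maybe_reanchor(g, zout, p)
  expect_true(re2$reloaded)
  # the reloaded grid drops to the matching lower magnification
  expect_equal(re2$grid$magnification, 40 * 0.2)
})
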