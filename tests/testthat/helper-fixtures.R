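# Shared fixtures (memoised: built once per test run) and independent
# oracles used by the DERIVED-value tests.

fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# 256 x 192 slide, 64 px tiles: fast unit-test pyramid.
small_slide <- function() memo_fixture("small_slide", function() {
  generate_slide(256, 192, base_magnification = 40, seed = 11)
})
small_pyramid <- function() memo_fixture("small_pyramid", function() {
  build_pyramid(small_slide(), c(40, 10, 1), tile_size = 64)
})

# 1024 x 768 slide, 256 px tiles: one-screen pyramid.
med_slide <- function() memo_fixture("med_slide", function() {
  generate_slide(1024, 768, base_magnification = 40, seed = 1)
})
med_pyramid <- function() memo_fixture("med_pyramid", function() {
  build_pyramid(med_slide(), c(40, 10, 1), tile_size = 256)
})

# 4096 x 3072 reference slide: large enough for a full 9x12 grid of 256 px
# cells at base magnification.
ref_pyramid <- function() memo_fixture("ref_pyramid", function() {
  build_pyramid(generate_slide(4096, 3072, base_magnification = 40, seed = 42),
                c(40, 10, 1), tile_size = 256)
})

# Independent nearest-neighbor oracle: plain double loop over the stated
# index formula floor((i + 0.5) * n_src / n_out), 0-based.
oracle_resample_nn <- function(src, out_h, out_w) {
  out <- array(0L, dim = c(out_h, out_w, 3L))
  src_h <- dim(src)[1]; src_w <- dim(src)[2]
  for (i in seq_len(out_h)) {
    si <- floor((i - 1 + 0.5) * src_h / out_h)
    for (j in seq_len(out_w)) {
      sj <- floor((j - 1 + 0.5) * src_w / out_w)
      out[i, j, ] <- src[si + 1, sj + 1, ]
    }
  }
  out
}

# Independent transcription of the printed per-cell resolution percentages,
# row by row as tabulated (9 rows x 12 columns).
printed_resolution_table <- function() {
  r_outer <- c(6.25, rep(12.5, 10), 6.25)
  r_mid <- c(6.25, 12.5, rep(25, 8), 12.5, 6.25)
  r_core <- c(6.25, 12.5, 25, 25, 100, 100, 100, 100, 25, 25, 12.5, 6.25)
  matrix(c(r_outer, r_outer, r_mid, r_core, r_core, r_core, r_mid,
           r_outer, r_outer),
         nrow = 9, byrow = TRUE)
}

# Centred mag-frame viewport over a grid: screen pixels map 1:1 onto grid
# pixels and the screen centre coincides with the grid centre, leaving the
# grid's margin on every side.
centred_grid_viewport <- function(grid, screen_width = 1024L, screen_height = 768L) {
  gw <- grid$cols * grid$cell_px
  gh <- grid$rows * grid$cell_px
  viewport_state(
    affine_translate(screen_width / 2 - (grid$anchor_x + gw / 2),
                     screen_height / 2 - (grid$anchor_y + gh / 2)),
    screen_width, screen_height)
}
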