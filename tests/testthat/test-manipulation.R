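# Inline 3x3 matrices built directly from the textbook forms serve as the
# independent oracle throughout.
oracle_translate <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
oracle_scale <- function(s) diag(c(s, s, 1))

test_that("translation and focal-point scaling match their matrix forms", {
  expect_equal(affine_translate(0, 0)$matrix, diag(3))
  expect_equal(apply_affine(affine_translate(10, 5), c(0, 0)), c(10, 5))
  expect_equal(affine_compose(list(affine_translate(3, 4),
                                   affine_translate(-3, -4)))$matrix, diag(3))
  expect_equal(affine_scale_about(1, 123, -45)$matrix, diag(3))
  expect_equal(apply_affine(affine_scale_about(2, 0, 0), c(1, 1)), c(2, 2))
  # hand-multiplied: T(512,384) S(2) T(-512,-384)
  m <- oracle_translate(512, 384) %*% oracle_scale(2) %*% oracle_translate(-512, -384)
  expect_equal(affine_scale_about(2, 512, 384)$matrix, m, tolerance = 1e-12)
  expect_equal(apply_affine(affine_scale_about(2, 512, 384), c(512, 384)),
               c(512, 384))
  expect_equal(apply_affine(affine_scale_about(2, 512, 384), c(0, 0)),
               c(-512, -384))
  expect_error(affine_scale_about(0, 0, 0), class = "slidecache_invalid_argument")
  expect_error(affine_scale(-1), class = "slidecache_invalid_argument")
})

test_that("focal-point scaling decomposes into translate-scale-translate", {
  withr::with_seed(101, {
    for (k in 1:25) {
      s <- runif(1, 0.2, 5)
      p <- runif(2, -1000, 1000)
      dec <- affine_compose(list(affine_translate(-p[1], -p[2]), affine_scale(s),
                                 affine_translate(p[1], p[2])))
      expect_equal(affine_scale_about(s, p[1], p[2])$matrix, dec$matrix,
                   tolerance = 1e-12)
      # fixed-point law
      expect_equal(apply_affine(affine_scale_about(s, p[1], p[2]), p), p,
                   tolerance = 1e-9)
    }
  })
})

random_transform_list <- function(n) {
  lapply(seq_len(n), function(i) {
    if (runif(1) < 0.5) {
      affine_translate(runif(1, -500, 500), runif(1, -500, 500))
    } else {
      affine_scale_about(runif(1, 0.3, 3), runif(1, 0, 1024), runif(1, 0, 768))
    }
  })
}

test_that("composition equals sequential application and prefixes are consistent", {
  expect_equal(affine_compose(list())$matrix, diag(3))
  expect_equal(affine_compose(list(affine_translate(10, 0),
                                   affine_translate(0, 5)))$matrix,
               affine_translate(10, 5)$matrix)
  withr::with_seed(202, {
    for (k in 1:10) {
      ts <- random_transform_list(5)
      pt <- runif(2, -200, 200)
      # oracle: apply each transform to the point in sequence
      step <- pt
      for (t in ts) step <- apply_affine(t, step)
      expect_equal(apply_affine(affine_compose(ts), pt), step, tolerance = 1e-9)
      # prefix products (intermediate states shown during a gesture)
      expect_equal(intermediate_state(ts, 0)$matrix, diag(3))
      expect_equal(intermediate_state(ts, 5)$matrix, affine_compose(ts)$matrix,
                   tolerance = 1e-12)
      oracle3 <- ts[[3]]$matrix %*% ts[[2]]$matrix %*% ts[[1]]$matrix
      expect_equal(intermediate_state(ts, 3)$matrix, oracle3, tolerance = 1e-12)
      for (j in 1:5) {
        expect_equal(intermediate_state(ts, j)$matrix,
                     (ts[[j]]$matrix %*% intermediate_state(ts, j - 1)$matrix),
                     tolerance = 1e-9)
      }
    }
  })
  expect_error(intermediate_state(list(), 1), class = "slidecache_invalid_argument")
  expect_error(intermediate_state(random_transform_list(2), -1),
               class = "slidecache_invalid_argument")
})

test_that("events act on the viewport as composed screen-space transforms", {
  vp <- viewport_state()
  expect_equal(apply_event(vp, manipulation_event("pan"))$cumulative$matrix, diag(3))
  pan <- apply_event(vp, manipulation_event("pan", dx = -300))
  expect_equal(slide_to_screen(pan, c(700, 100)), c(400, 100))
  # combined pan+zoom equals applying the two factors in sequence
  ev <- manipulation_event("pan_and_zoom", dx = 40, dy = -20, scale = 1.5,
                           focal_x = 512, focal_y = 384)
  two_step <- apply_event(apply_event(vp, manipulation_event("zoom", scale = 1.5,
                                                             focal_x = 512,
                                                             focal_y = 384)),
                          manipulation_event("pan", dx = 40, dy = -20))
  expect_equal(apply_event(vp, ev)$cumulative$matrix, two_step$cumulative$matrix,
               tolerance = 1e-12)
  # group action: folding events equals composing their transforms
  withr::with_seed(303, {
    for (k in 1:10) {
      e1 <- manipulation_event("pan_and_zoom", dx = runif(1, -300, 300),
                               dy = runif(1, -300, 300), scale = runif(1, 0.5, 2),
                               focal_x = runif(1, 0, 1024), focal_y = runif(1, 0, 768))
      e2 <- manipulation_event("pan_and_zoom", dx = runif(1, -300, 300),
                               dy = runif(1, -300, 300), scale = runif(1, 0.5, 2),
                               focal_x = runif(1, 0, 1024), focal_y = runif(1, 0, 768))
      folded <- apply_event(apply_event(vp, e1), e2)
      oracle <- slidecache:::event_transform(e2)$matrix %*%
        slidecache:::event_transform(e1)$matrix
      expect_equal(folded$cumulative$matrix, oracle, tolerance = 1e-9)
    }
  })
  expect_error(manipulation_event("pan", scale = 2),
               class = "slidecache_invalid_argument")
  expect_error(manipulation_event("zoom", dx = 1),
               class = "slidecache_invalid_argument")
})

test_that("screen and slide coordinates are mutually inverse", {
  vp <- viewport_state()
  expect_equal(screen_to_slide(vp, c(17, 23)), c(17, 23))
  withr::with_seed(404, {
    v <- vp
    for (k in 1:8) {
      v <- apply_event(v, manipulation_event("pan_and_zoom",
                                             dx = runif(1, -300, 300),
                                             dy = runif(1, -300, 300),
                                             scale = runif(1, 0.5, 2),
                                             focal_x = runif(1, 0, 1024),
                                             focal_y = runif(1, 0, 768)))
      pt <- runif(2, -2000, 2000)
      expect_equal(screen_to_slide(v, slide_to_screen(v, pt)), pt,
                   tolerance = 1e-9)
      expect_equal(slide_to_screen(v, pt),
                   (v$cumulative$matrix %*% c(pt, 1))[1:2], tolerance = 1e-9)
    }
  })
})

test_that("uncovered screen regions match the pan/zoom geometry", {
  big_slide <- c(100000, 100000)
  vp <- viewport_state(affine_translate(-40000, -40000))
  # identity: nothing uncovered
  expect_length(uncovered_screen_region(vp, vp, big_slide), 0)
  # pan content left by 300: a 300 px white strip appears on the right
  after <- apply_event(vp, manipulation_event("pan", dx = -300))
  unc <- uncovered_screen_region(vp, after, big_slide)
  expect_length(unc, 1)
  expect_equal(unlist(unc[[1]]), c(x0 = 724, y0 = 0, x1 = 1024, y1 = 768))
  # zoom in about the screen centre: content expands outward, nothing uncovered
  zoomed <- apply_event(vp, manipulation_event("zoom", scale = 2,
                                               focal_x = 512, focal_y = 384))
  expect_length(uncovered_screen_region(vp, zoomed, big_slide), 0)
  # diagonal pan: membership agrees with a point-sampling oracle
  after2 <- apply_event(vp, manipulation_event("pan", dx = -200, dy = 120))
  unc2 <- uncovered_screen_region(vp, after2, big_slide)
  in_rects <- function(x, y, rects) {
    any(vapply(rects, function(r) x >= r$x0 && x < r$x1 && y >= r$y0 && y < r$y1,
               logical(1)))
  }
  for (x in seq(4, 1020, by = 64)) {
    for (y in seq(4, 764, by = 64)) {
      # uncovered iff the point maps outside the previously shown screen rect
      prev <- solve(slidecache:::event_transform(
        manipulation_event("pan", dx = -200, dy = 120))$matrix) %*% c(x, y, 1)
      expected <- prev[1] < 0 || prev[1] >= 1024 || prev[2] < 0 || prev[2] >= 768
      expect_identical(in_rects(x, y, unc2), expected)
    }
  }
})
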