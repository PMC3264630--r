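# Affine pan/zoom manipulation: 3x3 homogeneous transforms, cumulative
# composition, viewport state, and uncovered-screen geometry.

#' Affine transform from a 3x3 homogeneous matrix
#'
#' The engine only composes translations and positive uniform scalings, so
#' every transform has the form `[[s,0,tx],[0,s,ty],[0,0,1]]` with `s > 0`.
#'
#' @param m a 3x3 numeric matrix with last row `(0, 0, 1)`.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !is.numeric(m)) {
    stop_invalid("m must be a 3x3 numeric matrix")
  }
  if (any(abs(m[3, ] - c(0, 0, 1)) > 1e-12)) {
    stop_invalid("last row must be (0, 0, 1)")
  }
  if (abs(det(m)) < 1e-15) stop_invalid("transform must be invertible")
  structure(list(matrix = m), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(diag(3))

#' Translation transform
#'
#' Maps `(x, y)` to `(x + dx, y + dy)`.
#'
#' @param dx,dy translation in pixels.
#' @return an `affine_transform`.
#' @export
affine_translate <- function(dx, dy) {
  m <- diag(3); m[1, 3] <- dx; m[2, 3] <- dy
  affine_transform(m)
}

#' Uniform scaling about the origin
#'
#' @param s scale factor, > 0.
#' @return an `affine_transform`.
#' @export
affine_scale <- function(s) {
  if (!is_scalar_num(s) || s <= 0) stop_invalid("scale factor must be > 0")
  m <- diag(c(s, s, 1))
  affine_transform(m)
}

#' Uniform scaling about an arbitrary focal point
#'
#' Decomposes as translate(px, py) then scale(s) then translate(-px, -py) in
#' matrix order, so `(px, py)` is a fixed point: zooming about a finger
#' position leaves that position stationary on screen.
#'
#' @param s scale factor, > 0.
#' @param px,py focal point coordinates.
#' @return an `affine_transform`.
#' @export
affine_scale_about <- function(s, px, py) {
  if (!is_scalar_num(s) || s <= 0) stop_invalid("scale factor must be > 0")
  affine_compose(list(affine_translate(-px, -py), affine_scale(s),
                      affine_translate(px, py)))
}

#' Compose an ordered list of transforms
#'
#' `transforms` is in application order (first applied first); the result is
#' the right-to-left matrix product. The empty list composes to the identity.
#'
#' @param transforms list of `affine_transform`.
#' @return an `affine_transform`.
#' @export
affine_compose <- function(transforms) {
  m <- diag(3)
  for (t in transforms) {
    if (!inherits(t, "affine_transform")) stop_invalid("all elements must be affine_transform")
    m <- t$matrix %*% m
  }
  affine_transform(m)
}

#' Intermediate (prefix) transform of a manipulation sequence
#'
#' The product of the first `j` transforms, displayed between `j = 0`
#' (identity, before any transform) and `j = n` (the full composition), so a
#' sequence of manipulations can be rendered continuously while it runs.
#'
#' @param transforms list of `affine_transform` in application order.
#' @param j prefix length, `0 <= j <= length(transforms)`.
#' @return an `affine_transform`.
#' @export
intermediate_state <- function(transforms, j) {
  n <- length(transforms)
  if (!is_count(j, 0) || j > n) {
    stop_invalid("j must be an integer in [0, %d]", n)
  }
  affine_compose(transforms[seq_len(j)])
}

#' Apply a transform to points
#'
#' @param transform an `affine_transform`.
#' @param points numeric vector `c(x, y)` or an n x 2 matrix.
#' @return same shape as `points`.
#' @export
apply_affine <- function(transform, points) {
  m <- transform$matrix
  if (is.matrix(points)) {
    out <- cbind(points, 1) %*% t(m)
    out[, 1:2, drop = FALSE]
  } else {
    (m %*% c(points[1], points[2], 1))[1:2]
  }
}

#' Viewport state: the cumulative slide-to-screen mapping
#'
#' @param cumulative an `affine_transform` mapping slide coordinates to screen
#'   coordinates.
#' @param screen_width,screen_height display size in pixels (default
#'   1024 x 768).
#' @return a `viewport_state`.
#' @export
viewport_state <- function(cumulative = affine_identity(),
                           screen_width = 1024L, screen_height = 768L) {
  if (!inherits(cumulative, "affine_transform")) {
    stop_invalid("cumulative must be an affine_transform")
  }
  if (!is_count(screen_width) || !is_count(screen_height)) {
    stop_invalid("screen dimensions must be positive integers")
  }
  structure(list(cumulative = cumulative,
                 screen_width = as.integer(screen_width),
                 screen_height = as.integer(screen_height)),
            class = "viewport_state")
}

# Uniform scale factor of a viewport's cumulative transform.
viewport_scale <- function(viewport) viewport$cumulative$matrix[1, 1]

#' A pan/zoom manipulation event
#'
#' Events stand in for touch gestures: a pure pan carries `(dx, dy)` with
#' `scale = 1`; a pure zoom carries `scale` about `(focal_x, focal_y)` with
#' `(dx, dy) = (0, 0)`; `pan_and_zoom` combines both. All quantities are in
#' screen pixels.
#'
#' @param kind one of `"pan"`, `"zoom"`, `"pan_and_zoom"`.
#' @param dx,dy screen-pixel translation.
#' @param scale scale factor, > 0.
#' @param focal_x,focal_y screen-pixel focal point of the scaling.
#' @return a `manipulation_event`.
#' @export
manipulation_event <- function(kind = c("pan", "zoom", "pan_and_zoom"),
                               dx = 0, dy = 0, scale = 1,
                               focal_x = 0, focal_y = 0) {
  kind <- match.arg(kind)
  if (!is_scalar_num(scale) || scale <= 0) stop_invalid("scale must be > 0")
  if (kind == "pan" && scale != 1) stop_invalid("a pure pan must have scale = 1")
  if (kind == "zoom" && (dx != 0 || dy != 0)) {
    stop_invalid("a pure zoom must have dx = dy = 0")
  }
  structure(list(kind = kind, dx = dx, dy = dy, scale = scale,
                 focal_x = focal_x, focal_y = focal_y),
            class = "manipulation_event")
}

# The screen-frame transform an event induces: scale about the focal point,
# then translate.
event_transform <- function(event) {
  affine_compose(list(affine_scale_about(event$scale, event$focal_x, event$focal_y),
                      affine_translate(event$dx, event$dy)))
}

#' Apply a manipulation event to a viewport
#'
#' The new cumulative transform is
#' `translate(dx, dy) %*% scale_about(scale, focal) %*% old`, i.e. the event
#' acts in screen space on top of everything applied so far.
#'
#' @param viewport a `viewport_state`.
#' @param event a `manipulation_event`.
#' @return the updated `viewport_state`.
#' @export
apply_event <- function(viewport, event) {
  if (!inherits(event, "manipulation_event")) {
    stop_invalid("event must be a manipulation_event")
  }
  new_cum <- affine_compose(list(viewport$cumulative, event_transform(event)))
  viewport_state(new_cum, viewport$screen_width, viewport$screen_height)
}

#' Map screen coordinates to slide coordinates (and back)
#'
#' Mutually inverse mappings through the cumulative transform and its inverse.
#'
#' @param viewport a `viewport_state`.
#' @param point numeric `c(x, y)` or an n x 2 matrix.
#' @return transformed point(s), same shape as the input.
#' @export
screen_to_slide <- function(viewport, point) {
  apply_affine(affine_transform(solve(viewport$cumulative$matrix)), point)
}

#' @rdname screen_to_slide
#' @export
slide_to_screen <- function(viewport, point) {
  apply_affine(viewport$cumulative, point)
}

#' Screen regions uncovered by a viewport change
#'
#' After a pan or zoom, parts of the screen may no longer be covered by
#' previously loaded content and appear white until refilled from the server
#' (panning left, for instance, exposes a white strip on the right). Returns
#' those screen-space rectangles: the screen area that lies over the slide
#' under the new viewport but outside the image of the previously displayed
#' screen content.
#'
#' @param before,after `viewport_state`s sharing screen dimensions.
#' @param slide_extent numeric `c(width, height)` of the slide in the frame
#'   the viewports map from.
#' @return list of rectangles, each `list(x0, y0, x1, y1)` half-open; empty
#'   when content still covers the screen.
#' @export
uncovered_screen_region <- function(before, after, slide_extent) {
  if (before$screen_width != after$screen_width ||
      before$screen_height != after$screen_height) {
    stop_invalid("viewports must share screen dimensions")
  }
  screen <- rect(0, 0, after$screen_width, after$screen_height)
  slide_after <- rect_transform(rect(0, 0, slide_extent[1], slide_extent[2]),
                                after$cumulative$matrix)
  delta <- after$cumulative$matrix %*% solve(before$cumulative$matrix)
  carried <- rect_transform(screen, delta)
  res <- rect_diff(rect_intersect(screen, slide_after), carried)
  Filter(function(r) !rect_empty(r), res)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(x$matrix)
  invisible(x)
}

#' @export
print.viewport_state <- function(x, ...) {
  m <- x$cumulative$matrix
  cat(sprintf("<viewport_state> screen %d x %d, scale %g, offset (%g, %g)\n",
              x$screen_width, x$screen_height, m[1, 1], m[1, 3], m[2, 3]))
  invisible(x)
}
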