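# Slide-anchored annotations: circles and rectangles with text labels, fixed
# in base-slide coordinates so they pan and zoom in lockstep with the slide,
# plus the editing state machine that halts navigation while drawing.

#' Construct an annotation
#'
#' Geometry is stored in base-slide pixel coordinates and never changes under
#' viewport manipulation — anchoring is by coordinates, not screen pixels.
#' Circles carry a centre and radius; rectangles a top-left corner and
#' extent.
#'
#' @param kind `"circle"` or `"rectangle"`.
#' @param x,y circle centre, or rectangle top-left corner.
#' @param r circle radius (> 0); circles only.
#' @param w,h rectangle extent (> 0); rectangles only.
#' @param label text label (drawn below the shape by a renderer).
#' @param colour display colour.
#' @param id unique identifier string.
#' @return an `annotation`.
#' @export
annotation <- function(kind = c("circle", "rectangle"), x, y, r = NULL,
                       w = NULL, h = NULL, label = "", colour = "#FFD700",
                       id = "a1") {
  kind <- match.arg(kind)
  if (!is_scalar_num(x) || !is_scalar_num(y)) stop_invalid("x and y must be numbers")
  if (kind == "circle") {
    if (!is_scalar_num(r) || r <= 0) stop_invalid("circle radius must be > 0")
    geom <- list(x = as.numeric(x), y = as.numeric(y), r = as.numeric(r))
  } else {
    if (!is_scalar_num(w) || w <= 0 || !is_scalar_num(h) || h <= 0) {
      stop_invalid("rectangle extent must be > 0")
    }
    geom <- list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h))
  }
  structure(c(list(kind = kind), geom,
              list(label = as.character(label), colour = colour,
                   id = as.character(id))),
            class = "annotation")
}

annotation_centroid <- function(a) {
  if (a$kind == "circle") c(a$x, a$y) else c(a$x + a$w / 2, a$y + a$h / 2)
}

#' Start an annotation session
#'
#' A session is either navigating (viewport manipulation allowed) or editing
#' exactly one annotation (manipulation halted until the edit commits).
#'
#' @param store optional list of `annotation`s to start from.
#' @return an `annotation_session` in navigate mode.
#' @export
annotation_session <- function(store = list()) {
  ids <- vapply(store, function(a) a$id, "")
  if (anyDuplicated(ids)) stop_invalid("annotation ids must be unique")
  structure(list(mode = "navigate", editing_id = NULL, store = store,
                 next_id = length(store) + 1L),
            class = "annotation_session")
}

#' May the viewport be manipulated right now?
#'
#' FALSE while an annotation is being edited: gesture control of the slide is
#' halted between [begin_annotation()] and [commit_annotation()].
#'
#' @param session an `annotation_session`.
#' @return TRUE/FALSE.
#' @export
session_allows_manipulation <- function(session) {
  session$mode == "navigate"
}

#' Begin editing a new annotation
#'
#' Creates a default-geometry annotation anchored at the screen centre
#' (mapped to slide coordinates through the viewport) and switches the
#' session to editing mode.
#'
#' @param session an `annotation_session` in navigate mode.
#' @param kind `"circle"` or `"rectangle"`.
#' @param viewport the current `viewport_state`, used to place the default
#'   geometry under the screen centre at a screen size of ~128 px.
#' @return the session in editing mode, with the new annotation in its store.
#' @export
begin_annotation <- function(session, kind = c("circle", "rectangle"),
                             viewport = viewport_state()) {
  kind <- match.arg(kind)
  if (session$mode != "navigate") {
    stop_state("already editing annotation '%s'; commit it first", session$editing_id)
  }
  centre <- screen_to_slide(viewport, c(viewport$screen_width / 2,
                                        viewport$screen_height / 2))
  s <- viewport_scale(viewport)
  id <- paste0("a", session$next_id)
  a <- if (kind == "circle") {
    annotation("circle", centre[1], centre[2], r = 64 / s, id = id)
  } else {
    annotation("rectangle", centre[1] - 64 / s, centre[2] - 48 / s,
               w = 128 / s, h = 96 / s, id = id)
  }
  session$store[[length(session$store) + 1L]] <- a
  session$mode <- "editing"
  session$editing_id <- id
  session$next_id <- session$next_id + 1L
  session
}

#' Move or resize the annotation being edited
#'
#' Deltas are given in screen pixels and mapped through the inverse viewport,
#' so a 100 px screen drag moves the annotation 50 slide px under a 2x zoom.
#' Resizing below the minimum extent (1 base px) clamps rather than errors.
#'
#' @param session an `annotation_session` in editing mode.
#' @param dx,dy move delta in screen pixels.
#' @param dw,dh resize delta in screen pixels (for circles `dw` adjusts the
#'   radius; `dh` is ignored).
#' @param viewport the current `viewport_state`.
#' @return the updated session.
#' @export
edit_annotation <- function(session, dx = 0, dy = 0, dw = 0, dh = 0,
                            viewport = viewport_state()) {
  if (session$mode != "editing") stop_state("no annotation is being edited")
  s <- viewport_scale(viewport)
  i <- which(vapply(session$store, function(a) a$id, "") == session$editing_id)
  a <- session$store[[i]]
  a$x <- a$x + dx / s
  a$y <- a$y + dy / s
  if (a$kind == "circle") {
    a$r <- max(1, a$r + dw / s)
  } else {
    a$w <- max(1, a$w + dw / s)
    a$h <- max(1, a$h + dh / s)
  }
  session$store[[i]] <- a
  session
}

#' Commit the annotation being edited
#'
#' Stores the label, leaves editing mode, and restores slide manipulation.
#' Empty labels are allowed.
#'
#' @param session an `annotation_session` in editing mode.
#' @param label the text label to attach.
#' @return the session back in navigate mode.
#' @export
commit_annotation <- function(session, label = "") {
  if (session$mode != "editing") stop_state("no annotation is being edited")
  i <- which(vapply(session$store, function(a) a$id, "") == session$editing_id)
  session$store[[i]]$label <- as.character(label)
  session$mode <- "navigate"
  session$editing_id <- NULL
  session
}

#' Project annotations into the screen frame
#'
#' Maps every annotation's geometry through the viewport: centres through
#' `slide_to_screen`, radii and extents multiplied by the viewport scale
#' (uniform scaling keeps circles circular). All annotations transform
#' identically with the slide, so visually they stay bonded to the tissue.
#' `label_x`/`label_y` give the label anchor at the shape's bottom edge.
#'
#' @param store list of `annotation`s (or an `annotation_session`).
#' @param viewport a `viewport_state` mapping base-slide to screen.
#' @return a data frame with one row per annotation: `id`, `kind`, screen
#'   `x`, `y` (centre), `r` or `w`,`h` (NA where not applicable), `label`,
#'   `colour`, `label_x`, `label_y`.
#' @export
project_annotations <- function(store, viewport) {
  if (inherits(store, "annotation_session")) store <- store$store
  s <- viewport_scale(viewport)
  rows <- lapply(store, function(a) {
    ctr <- slide_to_screen(viewport, annotation_centroid(a))
    if (a$kind == "circle") {
      data.frame(id = a$id, kind = a$kind, x = ctr[1], y = ctr[2],
                 r = a$r * s, w = NA_real_, h = NA_real_,
                 label = a$label, colour = a$colour,
                 label_x = ctr[1], label_y = ctr[2] + a$r * s)
    } else {
      data.frame(id = a$id, kind = a$kind, x = ctr[1], y = ctr[2],
                 r = NA_real_, w = a$w * s, h = a$h * s,
                 label = a$label, colour = a$colour,
                 label_x = ctr[1], label_y = ctr[2] + a$h * s / 2)
    }
  })
  if (!length(rows)) {
    return(data.frame(id = character(), kind = character(), x = numeric(),
                      y = numeric(), r = numeric(), w = numeric(),
                      h = numeric(), label = character(), colour = character(),
                      label_x = numeric(), label_y = numeric()))
  }
  do.call(rbind, rows)
}

#' Save annotations to a JSON file
#'
#' Records are written ordered by id; the round trip through
#' [load_annotations()] is lossless.
#'
#' @param store list of `annotation`s (or an `annotation_session`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(store, path) {
  if (inherits(store, "annotation_session")) store <- store$store
  ids <- vapply(store, function(a) a$id, "")
  recs <- lapply(store[order(ids)], unclass)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load annotations from a JSON file
#'
#' @param path a file written by [save_annotations()].
#' @return a list of `annotation`s ordered by id.
#' @export
load_annotations <- function(path) {
  recs <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop_parse("cannot parse '%s': %s",
                                                  path, conditionMessage(e)))
  store <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    need <- c("kind", "x", "y", "id")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop_parse("record %d: missing field(s) %s", i, toString(miss))
    }
    tryCatch(
      annotation(rec$kind, rec$x, rec$y, r = rec$r, w = rec$w, h = rec$h,
                 label = if (is.null(rec$label)) "" else rec$label,
                 colour = if (is.null(rec$colour)) "#FFD700" else rec$colour,
                 id = rec$id),
      error = function(e) stop_parse("record %d: %s", i, conditionMessage(e))
    )
  })
  ids <- vapply(store, function(a) a$id, "")
  if (anyDuplicated(ids)) {
    stop_parse("duplicate annotation id '%s'", ids[duplicated(ids)][1])
  }
  store[order(ids)]
}
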