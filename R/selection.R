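#' Focus+context selection state
#'
#' A selection combines three ingredients, applied in this order:
#' attribute-range filters and cutting planes decide per-vertex
#' *visibility* (all combined by AND; intervals closed on both ends;
#' points exactly on a cutting plane pass), and an ordered list of
#' progressively refinable spatial ROI steps builds the *focus* set
#' (starting empty; each step unions, intersects or subtracts the
#' vertices -- or whole tracks -- hit by its shape). Visible vertices
#' outside the focus form the de-emphasized context.
#'
#' @param filters list of [attribute_filter()].
#' @param planes list of [cut_plane()].
#' @param roi_steps ordered list of [roi_step()].
#' @param granularity `"track"` (a track is hit when any of its vertices
#'   is inside a shape; default, matching hemisphere-style selections) or
#'   `"vertex"`.
#' @return An object of class `selection_state`.
#' @export
selection_state <- function(filters = list(), planes = list(),
                            roi_steps = list(),
                            granularity = c("track", "vertex")) {
  granularity <- match.arg(granularity)
  for (f in filters) stopifnot(inherits(f, "attribute_filter"))
  for (p in planes) stopifnot(inherits(p, "cut_plane"))
  for (s in roi_steps) stopifnot(inherits(s, "roi_step"))
  structure(list(filters = filters, planes = planes, roi_steps = roi_steps,
                 granularity = granularity),
            class = "selection_state")
}

#' Closed-interval attribute filter
#' @param attribute attribute name.
#' @param lo,hi interval bounds, `lo <= hi`; boundary values pass.
#' @return An object of class `attribute_filter`.
#' @export
attribute_filter <- function(attribute, lo, hi) {
  if (lo > hi) stopf("filter on '%s': lo (%g) > hi (%g)", attribute, lo, hi)
  structure(list(attribute = attribute, lo = as.double(lo),
                 hi = as.double(hi)),
            class = "attribute_filter")
}

#' Cutting plane keeping one half-space
#' @param plane a [plane_spec()].
#' @param keep_side `+1` keeps the half-space the normal points into,
#'   `-1` the other; points exactly on the plane always pass.
#' @return An object of class `cut_plane`.
#' @export
cut_plane <- function(plane, keep_side = 1) {
  stopifnot(inherits(plane, "plane_spec"))
  if (!keep_side %in% c(-1, 1)) stopf("keep_side must be +1 or -1")
  structure(list(plane = plane, keep_side = keep_side), class = "cut_plane")
}

#' One refinement step of a spatial ROI selection
#' @param shape a [roi_sphere()] or [roi_box()].
#' @param op how the shape's hits update the focus set: `"add"` (union),
#'   `"intersect"`, or `"subtract"`.
#' @return An object of class `roi_step`.
#' @export
roi_step <- function(shape, op = c("add", "intersect", "subtract")) {
  op <- match.arg(op)
  stopifnot(inherits(shape, "roi_shape"))
  structure(list(shape = shape, op = op), class = "roi_step")
}

#' Spherical / box ROI shapes
#' @param center length-3 sphere center.
#' @param radius sphere radius > 0.
#' @return An object of classes `roi_sphere`/`roi_box` and `roi_shape`.
#' @export
roi_sphere <- function(center, radius) {
  if (!is_number(radius) || radius <= 0) stopf("radius must be > 0")
  structure(list(center = as.double(center), radius = radius),
            class = c("roi_sphere", "roi_shape"))
}

#' @rdname roi_sphere
#' @param min,max length-3 box corners, componentwise `min <= max`.
#' @export
roi_box <- function(min, max) {
  min <- as.double(min); max <- as.double(max)
  if (any(min > max)) stopf("box min must be <= max componentwise")
  structure(list(min = min, max = max), class = c("roi_box", "roi_shape"))
}

#' Per-vertex containment in an ROI shape (boundary inclusive)
#' @noRd
shape_contains <- function(shape, p) {
  if (inherits(shape, "roi_sphere")) {
    d2 <- colSums((t(p) - shape$center)^2)
    d2 <= shape$radius^2
  } else {
    ok <- rep(TRUE, nrow(p))
    for (k in 1:3) ok <- ok & p[, k] >= shape$min[k] & p[, k] <= shape$max[k]
    ok
  }
}

#' Per-vertex visibility under filters and cutting planes
#'
#' A vertex passes iff, for every filter, `lo <= value <= hi` (closed
#' interval) and it lies on the kept side of every cutting plane (points
#' exactly on a plane pass). Filters combine by conjunction, so the
#' result is independent of filter order.
#'
#' @param ts a [trajectory_set()].
#' @param sel a [selection_state()] (its `roi_steps` are ignored here).
#' @param state state name or index whose coordinates the planes test
#'   against (default the original).
#' @return Logical vector of length `n_vertices(ts)`.
#' @export
vertex_passes_filters <- function(ts, sel, state = 1L) {
  n <- n_vertices(ts)
  ok <- rep(TRUE, n)
  for (f in sel$filters) {
    v <- get_attribute(ts, f$attribute)
    ok <- ok & v >= f$lo & v <= f$hi
  }
  p <- ts$states[[state]]
  for (cp in sel$planes) {
    d <- as.vector((p - matrix(cp$plane$origin, n, 3, byrow = TRUE)) %*%
                     cp$plane$normal)
    ok <- ok & (cp$keep_side * d >= 0)
  }
  ok
}

#' Evaluate the ROI steps into a focus flag
#'
#' Starting from an empty focus, each step updates membership with its
#' shape's hits: `add` = union, `intersect`, `subtract`. At
#' `granularity = "track"` a track is hit by a shape iff at least one of
#' its vertices is inside, and the returned flags are per track (in
#' first-appearance track order); at `"vertex"` flags are per vertex.
#'
#' @param ts a [trajectory_set()].
#' @param sel a [selection_state()].
#' @param state state name or index for the containment tests.
#' @return Logical vector: per track (`granularity = "track"`) or per
#'   vertex.
#' @export
roi_select <- function(ts, sel, state = 1L) {
  p <- ts$states[[state]]
  tracks <- unique(ts$track)
  per_track <- sel$granularity == "track"
  focus <- rep(FALSE, if (per_track) length(tracks) else n_vertices(ts))
  for (st in sel$roi_steps) {
    hit_v <- shape_contains(st$shape, p)
    hit <- if (per_track)
      as.vector(rowsum(as.integer(hit_v),
                       factor(ts$track, levels = tracks)) > 0)
    else hit_v
    focus <- switch(st$op,
                    add = focus | hit,
                    intersect = focus & hit,
                    subtract = focus & !hit)
  }
  focus
}

#' Per-vertex visibility and focus/context style assignment
#'
#' Vertices failing the filters or cutting planes are invisible.
#' Remaining vertices get `style_focus` when they belong to the focus set
#' (their track, at track granularity) and `style_context` otherwise. A
#' segment is drawn iff both its endpoints are visible.
#'
#' @param ts a [trajectory_set()].
#' @param sel a [selection_state()].
#' @param style_focus,style_context arbitrary style objects (e.g.
#'   [visual_style()]); returned unchanged in the `styles` slot.
#' @param state state name or index for plane/ROI geometry tests.
#' @return List with `visible` (logical per vertex), `style_id` (integer
#'   per vertex: 1 = focus, 2 = context, `NA` = invisible), `styles`
#'   (list of the two styles) and `segment_visible` (logical per
#'   segment).
#' @export
effective_visibility <- function(ts, sel, style_focus, style_context,
                                 state = 1L) {
  visible <- vertex_passes_filters(ts, sel, state = state)
  focus <- roi_select(ts, sel, state = state)
  focus_v <- if (sel$granularity == "track")
    focus[match(ts$track, unique(ts$track))] else focus
  style_id <- ifelse(visible, ifelse(focus_v, 1L, 2L), NA_integer_)
  seg_vis <- if (n_segments(ts) > 0)
    visible[ts$segments[, 1]] & visible[ts$segments[, 2]]
  else logical()
  list(visible = visible, style_id = style_id,
       styles = list(focus = style_focus, context = style_context),
       segment_visible = seg_vis)
}
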