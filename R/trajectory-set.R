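#' Trajectory sets: vertices, attributes, segments and geometry states
#'
#' A `trajectory_set` is the in-memory model shared by every other part of
#' the package. It mirrors the flat buffer layout a WebGL viewer consumes:
#' a vertex coordinate list, per-vertex attribute columns in vertex order,
#' a segment index list (pairs of vertex indices), and one or more named
#' geometry states -- alternative coordinates (bundled, projected) for the
#' same topology. State 1 is always the original geometry.
#'
#' Indices are 1-based inside R; [build_packet()] emits 0-based indices for
#' viewer consumption.
#'
#' @param positions numeric N x 3 matrix (or flat length-3N vector,
#'   x/y/z interleaved) of vertex coordinates, arbitrary spatial units.
#' @param track length-N vector (character or numeric) assigning each
#'   vertex to a track; vertex order within a track is the row order.
#' @param segments M x 2 integer matrix of 1-based vertex index pairs, or
#'   `NULL` to derive chains per track via [segments_from_tracks()].
#' @param attributes named list of numeric length-N vectors, or a list of
#'   [attribute_column()] objects.
#' @return An object of class `trajectory_set` with elements `positions`,
#'   `track`, `segments`, `attributes` (list of `attribute_column`) and
#'   `states` (named list of N x 3 matrices; first is `"original"`).
#' @examples
#' ts <- trajectory_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
#'                      track = c("a", "a", "a"),
#'                      attributes = list(signal = c(5, 6, 7)))
#' n_vertices(ts)
#' n_segments(ts)
#' @export
trajectory_set <- function(positions, track, segments = NULL,
                           attributes = list()) {
  positions <- as_xyz_matrix(positions)
  n <- nrow(positions)
  if (length(track) != n)
    stopf("track has length %d but there are %d vertices", length(track), n)
  track <- as.character(track)
  if (is.null(segments)) {
    segments <- segments_from_tracks(track)
  } else {
    segments <- as_segment_matrix(segments)
  }
  attributes <- normalize_attribute_list(attributes, n)
  ts <- structure(
    list(positions = positions,
         track = track,
         segments = segments,
         attributes = attributes,
         states = list(original = positions)),
    class = "trajectory_set")
  rep <- validate_trajectory_set(ts)
  if (length(rep) > 0)
    stopf("invalid trajectory set:\n  %s", paste(rep, collapse = "\n  "))
  ts
}

as_segment_matrix <- function(segments) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    if (length(segments) %% 2L != 0L)
      stopf("flat segment index list must have even length")
    segments <- matrix(as.integer(segments), ncol = 2L, byrow = TRUE)
  }
  segments <- as.matrix(segments)
  if (ncol(segments) != 2L) stopf("segments must be an M x 2 index matrix")
  storage.mode(segments) <- "integer"
  dimnames(segments) <- NULL
  segments
}

#' Construct a named per-vertex attribute column
#'
#' Min/max are recorded at construction (the UI schema needs slider ranges
#' without rescanning the data); `vmin`/`vmax` may be widened to a fixed
#' shared range across datasets or states.
#'
#' @param name attribute name, unique within a trajectory set.
#' @param values numeric vector, one value per vertex.
#' @param vmin,vmax recorded range; default the data range. Must cover the
#'   data (`vmin <= min(values)`, `vmax >= max(values)`).
#' @param shared logical; whether the range is fixed across geometry states.
#' @return An object of class `attribute_column`.
#' @export
attribute_column <- function(name, values, vmin = NULL, vmax = NULL,
                             shared = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("attribute name must be a non-empty string")
  values <- as.double(values)
  rng <- if (length(values) > 0 && any(is.finite(values)))
    range(values, finite = TRUE) else c(0, 0)
  if (is.null(vmin)) vmin <- rng[1]
  if (is.null(vmax)) vmax <- rng[2]
  if (length(values) > 0 && (vmin > rng[1] || vmax < rng[2]))
    stopf("attribute '%s': [vmin, vmax] = [%g, %g] does not cover data range [%g, %g]",
          name, vmin, vmax, rng[1], rng[2])
  structure(list(name = name, values = values,
                 vmin = as.double(vmin), vmax = as.double(vmax),
                 shared = isTRUE(shared)),
            class = "attribute_column")
}

normalize_attribute_list <- function(attributes, n) {
  if (length(attributes) == 0) return(list())
  out <- vector("list", length(attributes))
  nm <- names(attributes)
  for (i in seq_along(attributes)) {
    a <- attributes[[i]]
    if (inherits(a, "attribute_column")) {
      out[[i]] <- a
    } else {
      if (is.null(nm) || !nzchar(nm[i]))
        stopf("plain attribute vectors must be named")
      out[[i]] <- attribute_column(nm[i], a)
    }
  }
  names(out) <- vapply(out, `[[`, "", "name")
  for (a in out)
    if (length(a$values) != n)
      stopf("attribute '%s' has %d values but there are %d vertices",
            a$name, length(a$values), n)
  if (anyDuplicated(names(out)))
    stopf("duplicate attribute name(s): %s",
          paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Number of vertices / segments / states in a trajectory set
#' @param ts a [trajectory_set()].
#' @return Integer count.
#' @export
n_vertices <- function(ts) nrow(ts$positions)

#' @rdname n_vertices
#' @export
n_segments <- function(ts) nrow(ts$segments)

#' @rdname n_vertices
#' @export
n_states <- function(ts) length(ts$states)

#' Attribute access
#'
#' `get_attribute()` returns the values of a named attribute (error if
#' absent); `has_attribute()` tests for presence; `set_attribute()` adds or
#' replaces a column and returns the modified set.
#' @param ts a [trajectory_set()].
#' @param name attribute name.
#' @return `get_attribute()`: numeric vector of length `n_vertices(ts)`.
#' @export
get_attribute <- function(ts, name) {
  a <- ts$attributes[[name]]
  if (is.null(a)) stopf("unknown attribute '%s' (available: %s)", name,
                        paste(names(ts$attributes), collapse = ", "))
  a$values
}

#' @rdname get_attribute
#' @export
has_attribute <- function(ts, name) !is.null(ts$attributes[[name]])

#' @rdname get_attribute
#' @param column an [attribute_column()], or a numeric vector.
#' @export
set_attribute <- function(ts, name, column) {
  if (!inherits(column, "attribute_column"))
    column <- attribute_column(name, column)
  if (length(column$values) != n_vertices(ts))
    stopf("attribute '%s' has %d values but there are %d vertices",
          name, length(column$values), n_vertices(ts))
  ts$attributes[[name]] <- column
  ts
}

#' Add a named geometry state
#'
#' A geometry state stores alternative coordinates (e.g. an edge-bundled
#' copy or a projection) for the same vertices and topology; a viewer can
#' blend between states.
#'
#' @param ts a [trajectory_set()].
#' @param name state name (unique; replacing an existing name is an error).
#' @param positions N x 3 matrix (or flat 3N vector) of alternative
#'   coordinates; must match the original vertex count.
#' @return The modified trajectory set.
#' @export
add_state <- function(ts, name, positions) {
  positions <- as_xyz_matrix(positions, what = sprintf("state '%s'", name))
  if (nrow(positions) != n_vertices(ts))
    stopf("state '%s' has %d vertices, expected %d",
          name, nrow(positions), n_vertices(ts))
  if (name %in% names(ts$states)) stopf("state '%s' already exists", name)
  ts$states[[name]] <- positions
  ts
}

#' Validate a trajectory set against its structural invariants
#'
#' Checks, without throwing: every attribute column has one value per
#' vertex; every segment index is a valid vertex index; every geometry
#' state has the same number of coordinates as the original; segments
#' connect vertices of the same track.
#'
#' @param ts a `trajectory_set` (possibly hand-modified).
#' @return Character vector of human-readable violations; empty when all
#'   invariants hold.
#' @export
validate_trajectory_set <- function(ts) {
  out <- character()
  n <- nrow(ts$positions)
  if (length(ts$track) != n)
    out <- c(out, sprintf("track map length %d != vertex count %d",
                          length(ts$track), n))
  for (a in ts$attributes)
    if (length(a$values) != n)
      out <- c(out, sprintf("attribute '%s' length %d != vertex count %d",
                            a$name, length(a$values), n))
  if (anyDuplicated(names(ts$attributes)))
    out <- c(out, "duplicate attribute names")
  seg <- ts$segments
  if (nrow(seg) > 0) {
    bad <- seg < 1L | seg > n
    if (any(bad))
      out <- c(out, sprintf("segment index out of range [1, %d]: %s", n,
                            paste(utils::head(seg[bad], 5), collapse = ", ")))
    ok <- !bad[, 1] & !bad[, 2]
    if (any(ok) && length(ts$track) == n) {
      cross <- ts$track[seg[ok, 1]] != ts$track[seg[ok, 2]]
      if (any(cross))
        out <- c(out, sprintf("%d segment(s) connect vertices of different tracks",
                              sum(cross)))
    }
  }
  for (nm in names(ts$states)) {
    st <- ts$states[[nm]]
    if (!is.matrix(st) || nrow(st) != n || ncol(st) != 3L)
      out <- c(out, sprintf("state '%s' length mismatch: %d coordinates, expected %d",
                            nm, length(st), 3L * n))
  }
  out
}

#' Derive chain segments from a track map
#'
#' For each track, consecutive vertices (by `order_key`, or by input order
#' when `order_key` is `NULL`) are connected by one segment, so a track
#' with k vertices yields k - 1 segments and the total segment count is
#' N minus the number of tracks. Single-vertex tracks produce no segment
#' but the vertex is retained.
#'
#' @param track length-N track identifier per vertex.
#' @param order_key optional length-N numeric sort key (e.g. time) ordering
#'   vertices within each track; ties within a track are an error.
#' @return M x 2 integer matrix of 1-based vertex index pairs.
#' @examples
#' segments_from_tracks(c("a", "a", "a", "b", "b"))
#' @export
segments_from_tracks <- function(track, order_key = NULL) {
  track <- as.character(track)
  n <- length(track)
  if (!is.null(order_key) && length(order_key) != n)
    stopf("order_key length %d != track length %d", length(order_key), n)
  idx_by_track <- split(seq_len(n), factor(track, levels = unique(track)))
  pairs <- vector("list", length(idx_by_track))
  for (i in seq_along(idx_by_track)) {
    idx <- idx_by_track[[i]]
    if (!is.null(order_key)) {
      key <- order_key[idx]
      if (anyDuplicated(key))
        stopf("duplicate order_key value(s) within track '%s'",
              names(idx_by_track)[i])
      idx <- idx[order(key)]
    }
    k <- length(idx)
    pairs[[i]] <- if (k < 2L) matrix(integer(), ncol = 2L)
                  else cbind(idx[-k], idx[-1L])
  }
  seg <- if (length(pairs) == 0) matrix(integer(), ncol = 2L)
         else do.call(rbind, pairs)
  storage.mode(seg) <- "integer"
  dimnames(seg) <- NULL
  seg
}

#' Axis-aligned bounding box of the original geometry
#'
#' @param ts a [trajectory_set()] with at least one vertex.
#' @param state state name or index to measure (default the original).
#' @return List with numeric length-3 `min` and `max`.
#' @export
bounding_box <- function(ts, state = 1L) {
  p <- ts$states[[state]]
  if (is.null(p)) stopf("unknown state '%s'", state)
  if (nrow(p) == 0) stopf("bounding box of an empty trajectory set")
  list(min = apply(p, 2, min), max = apply(p, 2, max))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d vertices, %d segments, %d tracks\n",
              n_vertices(x), n_segments(x), length(unique(x$track))))
  cat(sprintf("  states: %s\n", paste(names(x$states), collapse = ", ")))
  if (length(x$attributes))
    cat(sprintf("  attributes: %s\n", paste(vapply(x$attributes, function(a)
      sprintf("%s [%g, %g]", a$name, a$vmin, a$vmax), ""), collapse = ", ")))
  invisible(x)
}

#' @export
print.attribute_column <- function(x, ...) {
  cat(sprintf("<attribute_column> '%s', %d values, range [%g, %g]%s\n",
              x$name, length(x$values), x$vmin, x$vmax,
              if (x$shared) ", shared" else ""))
  invisible(x)
}

#' Per-track vertex indices, in segment (chain) order
#' @noRd
track_vertex_indices <- function(ts) {
  split(seq_len(n_vertices(ts)),
        factor(ts$track, levels = unique(ts$track)))
}
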