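#' Oblique plane specification
#'
#' A plane given by an origin point and a unit normal, used for planar
#' projection states and cutting planes.
#'
#' @param origin length-3 point on the plane.
#' @param normal length-3 normal; normalized internally (zero normal is an
#'   error).
#' @return An object of class `plane_spec` with unit `normal`.
#' @export
plane_spec <- function(origin = c(0, 0, 0), normal = c(0, 0, 1)) {
  origin <- as.double(origin); normal <- as.double(normal)
  if (length(origin) != 3 || length(normal) != 3)
    stopf("origin and normal must have length 3")
  nl <- sqrt(sum(normal^2))
  if (nl == 0) stopf("plane normal must be non-zero")
  structure(list(origin = origin, normal = normal / nl),
            class = "plane_spec")
}

#' Project points orthogonally onto a plane
#'
#' Each point p maps to p - ((p - q) . n) n for plane origin q and unit
#' normal n. Idempotent: points already on the plane are unchanged.
#'
#' @param p N x 3 coordinate matrix.
#' @param plane a [plane_spec()].
#' @return N x 3 matrix of projected coordinates.
#' @export
project_plane_points <- function(p, plane) {
  stopifnot(inherits(plane, "plane_spec"))
  p <- as_xyz_matrix(p)
  d <- as.vector((p - matrix(plane$origin, nrow(p), 3, byrow = TRUE)) %*%
                   plane$normal)
  p - outer(d, plane$normal)
}

#' Add a planar-projection geometry state
#'
#' @param ts a [trajectory_set()].
#' @param plane a [plane_spec()].
#' @param name state name; the default records the plane parameters.
#' @return The trajectory set with the extra state.
#' @export
add_plane_state <- function(ts, plane, name = NULL) {
  if (is.null(name))
    name <- sprintf("planar(q=%g,%g,%g n=%g,%g,%g)",
                    plane$origin[1], plane$origin[2], plane$origin[3],
                    plane$normal[1], plane$normal[2], plane$normal[3])
  add_state(ts, name, project_plane_points(ts$positions, plane))
}

#' Mercator projection parameters
#'
#' Spherical Mercator about a configurable center: each point is read in
#' spherical coordinates about `center` (longitude from atan2 of the y/x
#' offsets, latitude from the z offset), then mapped conformally to the
#' plane. Radius information is discarded, so the projection is invariant
#' to the distance from the center.
#'
#' @param center length-3 projection center; no data point may coincide
#'   with it.
#' @param scale map scale R0 > 0 (map x spans `scale * 2 * pi` over the
#'   full longitude range).
#' @param lon0 reference longitude in radians (maps to x = 0).
#' @param lat_clamp latitude clamp in radians, in (0, pi/2); default 85
#'   degrees, avoiding the pole singularity of the Mercator formula.
#' @return An object of class `mercator_params`.
#' @export
mercator_params <- function(center = c(0, 0, 0), scale = 1, lon0 = 0,
                            lat_clamp = 85 * pi / 180) {
  if (!is_number(scale) || scale <= 0) stopf("scale must be > 0")
  if (!is_number(lat_clamp) || lat_clamp <= 0 || lat_clamp >= pi / 2)
    stopf("lat_clamp must lie in (0, pi/2)")
  structure(list(center = as.double(center), scale = scale,
                 lon0 = lon0, lat_clamp = lat_clamp),
            class = "mercator_params")
}

#' Wrap angles into (-pi, pi]
#' @noRd
wrap_longitude <- function(lam) {
  out <- (lam + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi  # boundary convention: (-pi, pi]
  out
}

#' Apply the Mercator map to points
#'
#' Maps each point to `(scale * wrap(lambda - lon0),
#' scale * log(tan(pi/4 + phi/2)), 0)` with longitude lambda, latitude phi
#' (clamped to +/- `lat_clamp`) about the center. Output is embedded in 3D
#' with z = 0 so viewers can blend a map state with 3D states by plain
#' componentwise interpolation.
#'
#' @param p N x 3 coordinate matrix.
#' @param params a [mercator_params()].
#' @return N x 3 matrix of map coordinates (z = 0).
#' @export
project_mercator_points <- function(p, params) {
  stopifnot(inherits(params, "mercator_params"))
  p <- as_xyz_matrix(p)
  v <- p - matrix(params$center, nrow(p), 3, byrow = TRUE)
  rad <- row_norms(v)
  if (any(rad == 0))
    stopf("vertex %d coincides with the projection center",
          which(rad == 0)[1])
  lam <- atan2(v[, 2], v[, 1])
  phi <- asin(pmin(1, pmax(-1, v[, 3] / rad)))
  phi <- pmin(params$lat_clamp, pmax(-params$lat_clamp, phi))
  cbind(x = params$scale * wrap_longitude(lam - params$lon0),
        y = params$scale * log(tan(pi / 4 + phi / 2)),
        z = 0)
}

#' Add a Mercator geometry state
#'
#' Besides the new state, segments that cross the longitude seam (wrapped
#' endpoint longitudes differing by more than pi) are flagged in a
#' per-vertex attribute `"seam"` (1 on both endpoints of a crossing
#' segment, else 0) so a renderer can suppress the spurious lines that
#' would otherwise span the map.
#'
#' @param ts a [trajectory_set()].
#' @param params a [mercator_params()].
#' @param name state name (default `"mercator"`).
#' @return The trajectory set with the extra state and `"seam"` attribute.
#' @export
add_mercator_state <- function(ts, params = mercator_params(),
                               name = "mercator") {
  proj <- project_mercator_points(ts$positions, params)
  seam <- rep(0, n_vertices(ts))
  if (n_segments(ts) > 0) {
    xa <- proj[ts$segments[, 1], 1] / params$scale
    xb <- proj[ts$segments[, 2], 1] / params$scale
    crossing <- abs(xa - xb) > pi
    seam[ts$segments[crossing, ]] <- 1
  }
  ts <- add_state(ts, name, proj)
  set_attribute(ts, "seam",
                attribute_column("seam", seam, vmin = 0, vmax = 1))
}

#' Automatic bounding-box axes
#'
#' Builds three axis polylines along the bounding-box edges emanating
#' from the box minimum corner, with `tick_count` evenly spaced ticks per
#' axis labelled from the data ranges. A zero-extent dimension gets a
#' single tick.
#'
#' @param ts a [trajectory_set()] with at least one vertex.
#' @param tick_count ticks per axis (>= 2).
#' @return An object of class `axes_spec`: list with `polylines` (named
#'   list of K x 3 matrices), `ticks` (per-axis positions along the axis,
#'   in data units) and `labels` (per-axis tick label strings).
#' @export
auto_axes <- function(ts, tick_count = 5L) {
  if (tick_count < 2) stopf("tick_count must be >= 2")
  bb <- bounding_box(ts)
  lo <- unname(bb$min); hi <- unname(bb$max)
  axes <- list(); ticks <- list(); labels <- list()
  dirs <- diag(3)
  names_ <- c("x", "y", "z")
  for (k in 1:3) {
    span <- hi[k] - lo[k]
    tk <- if (span == 0) lo[k]
          else seq(lo[k], hi[k], length.out = tick_count)
    # degenerate axis keeps >= 2 (coincident) polyline vertices
    endpoint <- lo + dirs[k, ] * span
    axes[[names_[k]]] <- as_xyz_matrix(rbind(lo, endpoint),
                                       what = "axis polyline")
    ticks[[names_[k]]] <- tk
    labels[[names_[k]]] <- formatC(tk, format = "g", digits = 6)
  }
  structure(list(polylines = axes, ticks = ticks, labels = labels),
            class = "axes_spec")
}

#' Custom axes from polylines
#'
#' Wraps user-provided polylines (e.g. continent outlines for geographic
#' data) as an axes specification that transforms along with the data.
#'
#' @param polylines named list of K x 3 matrices (K >= 2 each).
#' @param ticks,labels optional per-axis tick positions and labels.
#' @return An `axes_spec`.
#' @export
axes_spec <- function(polylines, ticks = NULL, labels = NULL) {
  if (!is.list(polylines) || length(polylines) == 0)
    stopf("polylines must be a non-empty list")
  polylines <- lapply(polylines, as_xyz_matrix, what = "axis polyline")
  for (pl in polylines)
    if (nrow(pl) < 2) stopf("each axis polyline needs >= 2 vertices")
  if (is.null(names(polylines)))
    names(polylines) <- sprintf("axis%d", seq_along(polylines))
  structure(list(polylines = polylines,
                 ticks = ticks %||% lapply(polylines, function(x) numeric()),
                 labels = labels %||% lapply(polylines, function(x) character())),
            class = "axes_spec")
}

#' Transform axes with the same mapping as a geometry state
#'
#' Applies a point transform (e.g. `function(p) project_mercator_points(p,
#' params)`) vertex-wise to every axis polyline, so axes adapt to
#' projections exactly as the data does.
#'
#' @param axes an `axes_spec` ([auto_axes()] or [axes_spec()]).
#' @param state_transform function mapping an N x 3 matrix to an N x 3
#'   matrix.
#' @return The transformed `axes_spec`.
#' @export
transform_axes <- function(axes, state_transform) {
  stopifnot(inherits(axes, "axes_spec"), is.function(state_transform))
  axes$polylines <- lapply(axes$polylines, function(pl)
    as_xyz_matrix(state_transform(pl), what = "transformed axis polyline"))
  axes
}
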