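#' Derived per-vertex attributes
#'
#' Trajectory data often arrives as bare coordinates; these helpers derive
#' the generic attributes most visualisations need: a timestamp, the local
#' turning angle of each trajectory, and the local movement direction
#' (used by the orientation-XYZ colour mode). All are idempotent: running
#' an enrichment twice equals running it once.
#'
#' @name enrichment
NULL

#' Add (or normalize) a per-vertex time attribute
#'
#' When the set has no `"time"` attribute, each vertex gets its rank along
#' its own track (0, 1, 2, ...). Normalization modes: `"raw"` keeps the
#' values verbatim, `"zero"` shifts each track to start at 0, `"unit"`
#' rescales each track to the unit interval \[0, 1\] (single-vertex or
#' zero-duration tracks map to 0).
#'
#' @param ts a [trajectory_set()].
#' @param normalization `"raw"`, `"zero"` or `"unit"`.
#' @return The trajectory set with attribute `"time"`.
#' @export
add_time_attribute <- function(ts, normalization = c("raw", "zero", "unit")) {
  normalization <- match.arg(normalization)
  idx <- track_vertex_indices(ts)
  tm <- if (has_attribute(ts, "time")) get_attribute(ts, "time")
        else {
          v <- numeric(n_vertices(ts))
          for (ix in idx) v[ix] <- seq_along(ix) - 1
          v
        }
  if (normalization != "raw") {
    for (ix in idx) {
      tv <- tm[ix] - min(tm[ix])
      if (normalization == "unit") {
        span <- max(tv)
        tv <- if (span > 0) tv / span else tv * 0
      }
      tm[ix] <- tv
    }
  }
  set_attribute(ts, "time", tm)
}

#' Add the local turning angle attribute
#'
#' At each interior vertex of a track, the angle (in degrees, in 3D)
#' between the incoming segment direction and the outgoing segment
#' direction: 0 for a straight continuation, up to 180 for a reversal.
#' Track endpoints get `endpoint_value`; a zero-length incident segment
#' yields angle 0 at that vertex.
#'
#' @param ts a [trajectory_set()].
#' @param endpoint_value angle assigned at track endpoints (default 0, so
#'   straight tracks are uniformly 0).
#' @return The trajectory set with attribute `"angle"`.
#' @export
add_local_angle <- function(ts, endpoint_value = 0) {
  p <- ts$positions
  ang <- rep(as.double(endpoint_value), n_vertices(ts))
  for (ix in track_vertex_indices(ts)) {
    k <- length(ix)
    if (k < 3) next
    a <- p[ix[1:(k - 2)], , drop = FALSE]
    b <- p[ix[2:(k - 1)], , drop = FALSE]
    c_ <- p[ix[3:k], , drop = FALSE]
    u <- b - a
    v <- c_ - b
    nu <- row_norms(u); nv <- row_norms(v)
    cosang <- rowSums(u * v) / (nu * nv)
    cosang[nu == 0 | nv == 0] <- 1  # zero-length segment => angle 0
    cosang <- pmin(1, pmax(-1, cosang))
    ang[ix[2:(k - 1)]] <- acos(cosang) * 180 / pi
  }
  set_attribute(ts, "angle", ang)
}

#' Add unit movement-direction attributes
#'
#' Stores, per vertex, the normalized direction of its outgoing segment
#' (for the last vertex of a track, the incoming one) as three attributes
#' `"dir_x"`, `"dir_y"`, `"dir_z"` in \[-1, 1\]. Zero-length segments and
#' single-vertex tracks yield (0, 0, 0). The orientation-XYZ colour mode
#' maps these components to RGB.
#'
#' @param ts a [trajectory_set()].
#' @return The trajectory set with attributes `"dir_x"`, `"dir_y"`,
#'   `"dir_z"`.
#' @export
add_orientation <- function(ts) {
  p <- ts$positions
  d <- matrix(0, n_vertices(ts), 3)
  for (ix in track_vertex_indices(ts)) {
    k <- length(ix)
    if (k < 2) next
    seg <- p[ix[-1], , drop = FALSE] - p[ix[-k], , drop = FALSE]
    seg <- normalize_rows(seg)
    d[ix[-k], ] <- seg       # outgoing direction
    d[ix[k], ] <- seg[k - 1, ]  # last vertex: incoming
  }
  ts <- set_attribute(ts, "dir_x",
                      attribute_column("dir_x", d[, 1], vmin = -1, vmax = 1))
  ts <- set_attribute(ts, "dir_y",
                      attribute_column("dir_y", d[, 2], vmin = -1, vmax = 1))
  set_attribute(ts, "dir_z",
                attribute_column("dir_z", d[, 3], vmin = -1, vmax = 1))
}
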