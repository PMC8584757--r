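#' Edge-bundling parameters
#'
#' Controls the kernel-based bundling transform of [add_bundled_state()].
#' Bundling pulls spatially proximate trajectory portions together so the
#' dominant shared routes ("highways") emerge from dense line data.
#'
#' @param radius neighbourhood radius as a fraction of the bounding-box
#'   diagonal (default 0.05). Must be > 0.
#' @param iterations number of attraction iterations (>= 0, default 10);
#'   0 iterations (with 0 smoothing passes) leaves the data untouched.
#' @param strength step size in \[0, 1\] towards the neighbourhood
#'   centroid per iteration (default 0.5); 0 is the identity.
#' @param anchor_endpoints keep the first and last vertex of every track
#'   fixed (default `TRUE`), preserving the tracks' endpoints.
#' @param smoothing_passes per-track Laplacian smoothing passes after each
#'   iteration (default 1).
#' @return An object of class `bundle_params`.
#' @export
bundle_params <- function(radius = 0.05, iterations = 10L, strength = 0.5,
                          anchor_endpoints = TRUE, smoothing_passes = 1L) {
  if (!is_number(radius) || radius <= 0) stopf("radius must be > 0")
  if (!is_number(strength) || strength < 0 || strength > 1)
    stopf("strength must be in [0, 1]")
  if (iterations < 0 || smoothing_passes < 0)
    stopf("iterations and smoothing_passes must be >= 0")
  structure(list(radius = radius, iterations = as.integer(iterations),
                 strength = strength,
                 anchor_endpoints = isTRUE(anchor_endpoints),
                 smoothing_passes = as.integer(smoothing_passes)),
            class = "bundle_params")
}

#' Compute an edge-bundled geometry state
#'
#' Iterative kernel-density-style bundling: per iteration, every
#' non-anchored vertex moves by `strength` times the offset from itself to
#' the Gaussian-weighted centroid of all vertices within `radius`
#' (Gaussian sigma = radius / 2; the vertex itself participates with
#' weight 1), then each track polyline is smoothed by `smoothing_passes`
#' Laplacian passes (vertex pulled half-way to the mean of its polyline
#' neighbours). Track endpoints stay fixed when `anchor_endpoints`. All
#' updates within an iteration are synchronous. Coincident geometry is a
#' fixed point, and `strength = 0` or `iterations = 0` (with 0 smoothing)
#' reproduce the input exactly.
#'
#' The neighbourhood query uses a uniform-grid spatial index;
#' `method = "brute"` forces the quadratic reference search (used as a
#' cross-check oracle in the test suite).
#'
#' @param ts a [trajectory_set()].
#' @param params a [bundle_params()] (radius interpreted as a fraction of
#'   the bounding-box diagonal of the original state).
#' @param name name of the new geometry state (default `"bundled"`).
#' @param method `"grid"` (spatial index) or `"brute"` (reference).
#' @return `add_bundled_state()`: the trajectory set with the extra state;
#'   `bundle_positions()`: the bundled N x 3 coordinate matrix.
#' @export
add_bundled_state <- function(ts, params = bundle_params(),
                              name = "bundled", method = c("grid", "brute")) {
  add_state(ts, name, bundle_positions(ts, params, method = method))
}

#' @rdname add_bundled_state
#' @export
bundle_positions <- function(ts, params = bundle_params(),
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "bundle_params"))
  p <- ts$positions
  n <- nrow(p)
  if (n == 0) return(p)
  bb <- bounding_box(ts)
  diag_len <- sqrt(sum((bb$max - bb$min)^2))
  r <- params$radius * if (diag_len > 0) diag_len else 1
  sigma <- r / 2

  idx <- track_vertex_indices(ts)
  anchored <- rep(FALSE, n)
  if (params$anchor_endpoints)
    for (ix in idx) anchored[c(ix[1], ix[length(ix)])] <- TRUE

  for (it in seq_len(params$iterations)) {
    cent <- if (method == "grid") gaussian_centroids_grid(p, r, sigma)
            else gaussian_centroids_brute(p, r, sigma)
    move <- !anchored
    p[move, ] <- p[move, , drop = FALSE] +
      params$strength * (cent[move, , drop = FALSE] - p[move, , drop = FALSE])
    for (pass in seq_len(params$smoothing_passes))
      p <- laplacian_smooth(p, idx, anchored)
  }
  dimnames(p) <- list(NULL, c("x", "y", "z"))
  p
}

#' Gaussian-weighted neighbourhood centroids, quadratic reference
#' @noRd
gaussian_centroids_brute <- function(p, r, sigma) {
  n <- nrow(p)
  out <- p
  for (i in seq_len(n)) {
    d2 <- colSums((t(p) - p[i, ])^2)
    nb <- which(d2 <= r * r)
    w <- exp(-d2[nb] / (2 * sigma^2))
    out[i, ] <- colSums(p[nb, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' Same centroids via a uniform grid of cell size r (27-cell stencil)
#' @noRd
gaussian_centroids_grid <- function(p, r, sigma) {
  n <- nrow(p)
  lo <- apply(p, 2, min)
  cell <- ceiling(sweep(p, 2, lo) / r + 1e-12) # 1-based cells
  cell[cell < 1] <- 1
  # pack 3D cell coords into one key
  dims <- apply(cell, 2, max)
  key <- (cell[, 1] - 1) + dims[1] * ((cell[, 2] - 1) + dims[2] * (cell[, 3] - 1))
  bucket <- split(seq_len(n), key)
  out <- p
  r2 <- r * r
  for (i in seq_len(n)) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      cx <- cell[i, 1] + dx; cy <- cell[i, 2] + dy; cz <- cell[i, 3] + dz
      if (cx < 1 || cy < 1 || cz < 1 || cx > dims[1] || cy > dims[2] || cz > dims[3])
        next
      k <- as.character((cx - 1) + dims[1] * ((cy - 1) + dims[2] * (cz - 1)))
      b <- bucket[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- colSums((t(p[cand, , drop = FALSE]) - p[i, ])^2)
    nb <- cand[d2 <= r2]
    w <- exp(-d2[d2 <= r2] / (2 * sigma^2))
    out[i, ] <- colSums(p[nb, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' One synchronous Laplacian pass along each track polyline
#' @noRd
laplacian_smooth <- function(p, idx, anchored) {
  out <- p
  for (ix in idx) {
    k <- length(ix)
    if (k < 2) next
    for (j in seq_len(k)) {
      v <- ix[j]
      if (anchored[v]) next
      nbr <- ix[c(j - 1, j + 1)[c(j - 1, j + 1) >= 1 & c(j - 1, j + 1) <= k]]
      mean_nbr <- colMeans(p[nbr, , drop = FALSE])
      out[v, ] <- 0.5 * p[v, ] + 0.5 * mean_nbr
    }
  }
  out
}
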