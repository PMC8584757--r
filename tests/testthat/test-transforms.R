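# two isolated parallel lines whose only in-radius neighbour is the
# directly opposite vertex: spacing s along x > radius, separation d < radius
parallel_lines_ts <- function(k = 10, s = 2, d = 0.3) {
  xs <- (seq_len(k) - 1) * s
  pos <- rbind(cbind(xs, 0, 0), cbind(xs, d, 0))
  trajectory_set(pos, track = rep(c("a", "b"), each = k))
}

test_that("bundling: coincident straight lines are an exact fixed point", {
  xs <- seq(0, 10, by = 2.5)
  pos <- rbind(cbind(xs, 0, 0), cbind(xs, 0, 0))
  ts <- trajectory_set(pos, track = rep(c("a", "b"), each = length(xs)))
  # radius (0.05 * diag = 0.5) below the 2.5 vertex spacing: each vertex
  # only sees its coincident twin
  out <- bundle_positions(ts, bundle_params(iterations = 3))
  expect_equal(out, ts$positions)
})

test_that("bundling: strength 0 and zero iterations are the identity; endpoints anchored", {
  ts <- make_fixture("parallel_bundles", n_tracks = 6, vertices_per_track = 10,
                     seed = 3)
  expect_equal(bundle_positions(ts, bundle_params(strength = 0,
                                                  smoothing_passes = 0)),
               ts$positions)
  expect_equal(bundle_positions(ts, bundle_params(iterations = 0,
                                                  smoothing_passes = 0)),
               ts$positions)
  out <- bundle_positions(ts, bundle_params(iterations = 4))
  ends <- unlist(lapply(split(seq_len(n_vertices(ts)),
                              factor(ts$track, levels = unique(ts$track))),
                        function(ix) c(ix[1], ix[length(ix)])))
  expect_equal(out[ends, ], ts$positions[ends, ])
})

test_that("bundling pulls two parallel lines together as the hand-computed centroid predicts", {
  k <- 10; s <- 2; d <- 0.3
  ts <- parallel_lines_ts(k, s, d)
  diag_len <- sqrt(sum((bounding_box(ts)$max - bounding_box(ts)$min)^2))
  r <- 1.0
  params <- bundle_params(radius = r / diag_len, iterations = 1, strength = 1,
                          smoothing_passes = 0)
  out <- bundle_positions(ts, params)
  # oracle: neighbourhood of an interior vertex = {self (w=1), opposite
  # (w = exp(-d^2 / (2 sigma^2)))}, sigma = r/2; strength-1 step lands on
  # the weighted centroid
  w <- exp(-d^2 / (2 * (r / 2)^2))
  y_lower <- d * w / (1 + w)
  y_upper <- d - y_lower
  interior <- 2:(k - 1)
  expect_equal(out[interior, 2], rep(y_lower, k - 2), tolerance = 1e-12)
  expect_equal(out[k + interior, 2], rep(y_upper, k - 2), tolerance = 1e-12)
  # both lines end up near the midline (exactly there in the small-d limit)
  expect_true(all(abs(out[c(interior, k + interior), 2] - d / 2) < 0.05 * d))
  # x coordinates untouched (neighbourhood is symmetric in x)
  expect_equal(out[, 1], ts$positions[, 1])
})

test_that("grid spatial index reproduces the brute-force neighbourhood search", {
  ts <- make_fixture("parallel_bundles", n_tracks = 10, vertices_per_track = 20,
                     seed = 1)
  for (p in list(bundle_params(iterations = 2),
                 bundle_params(radius = 0.2, iterations = 1,
                               smoothing_passes = 0))) {
    a <- bundle_positions(ts, p, method = "grid")
    b <- bundle_positions(ts, p, method = "brute")
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("bundling contracts within-bundle spread monotonically on the two-bundle fixture", {
  ts <- make_fixture("parallel_bundles", n_tracks = 10, vertices_per_track = 20,
                     seed = 1)
  params <- bundle_params(iterations = 1)
  d_prev <- mean_bundle_nn_distance(ts$positions, ts)
  dists <- d_prev
  pos <- ts$positions
  work <- ts
  for (it in 1:5) {
    work$positions <- pos
    work$states$original <- pos
    pos <- bundle_positions(work, params)
    dists <- c(dists, mean_bundle_nn_distance(pos, ts))
  }
  expect_lt(dists[2], dists[1])          # strictly decreases at iteration 1
  expect_true(all(diff(dists) <= 1e-12)) # non-increasing thereafter
})

test_that("planar projection satisfies the closed form, idempotence and residual normality", {
  pl <- plane_spec(c(0, 0, 0), c(0, 0, 1))
  expect_equal(project_plane_points(rbind(c(1, 2, 3)), pl),
               rbind(c(1, 2, 0)), ignore_attr = TRUE)
  on_plane <- rbind(c(4, -2, 0))
  expect_equal(project_plane_points(on_plane, pl), on_plane,
               ignore_attr = TRUE)
  withr::with_seed(5, {
    for (i in 1:20) {
      q <- stats::rnorm(3); nrm <- stats::rnorm(3)
      pl2 <- plane_spec(q, nrm)
      p <- matrix(stats::rnorm(30, 0, 5), 10, 3)
      pr <- project_plane_points(p, pl2)
      # residual parallel to the normal, projected point on the plane
      res <- p - pr
      cross_norm <- sqrt(rowSums((res - (res %*% pl2$normal) %*%
                                    t(pl2$normal))^2))
      expect_lt(max(cross_norm), 1e-9)
      expect_lt(max(abs((pr - matrix(pl2$origin, 10, 3, byrow = TRUE)) %*%
                          pl2$normal)), 1e-9)
      # idempotence
      expect_lt(max(abs(project_plane_points(pr, pl2) - pr)), 1e-12)
    }
  })
})

test_that("Mercator projection matches closed forms at reference points and clamps latitude", {
  mp <- mercator_params(center = c(0, 0, 0), scale = 1, lon0 = 0)
  expect_equal(project_mercator_points(rbind(c(1, 0, 0)), mp),
               rbind(c(0, 0, 0)), ignore_attr = TRUE)
  expect_equal(project_mercator_points(rbind(c(0, 1, 0)), mp),
               rbind(c(pi / 2, 0, 0)), ignore_attr = TRUE)
  # pole: clamped at the default 85-degree latitude
  phimax <- 85 * pi / 180
  y_expected <- log(tan(pi / 4 + phimax / 2))
  expect_equal(project_mercator_points(rbind(c(0, 0, 1)), mp),
               rbind(c(0, y_expected, 0)), ignore_attr = TRUE)
  # vertex at the center is refused by name
  expect_error(project_mercator_points(rbind(c(0, 0, 0)), mp), "vertex 1")
})

test_that("Mercator output is radius-invariant and scales with R0 and lon0", {
  withr::with_seed(6, {
    mp <- mercator_params(center = c(1, 2, 3), scale = 2.5, lon0 = 0.7)
    v <- matrix(stats::rnorm(30), 10, 3)
    p1 <- sweep(v, 2, c(-1, -2, -3))                 # center + v
    p2 <- sweep(3.7 * v, 2, c(-1, -2, -3))           # center + 3.7 v
    expect_equal(project_mercator_points(p1, mp),
                 project_mercator_points(p2, mp), tolerance = 1e-9)
  })
})

test_that("Mercator state flags segments crossing the longitude seam", {
  # two vertices on either side of the antimeridian (lon +/- ~179 deg)
  th <- 179 * pi / 180
  pos <- rbind(c(cos(th), sin(th), 0), c(cos(-th), sin(-th), 0),
               c(1, 0, 0), c(1, 0.1, 0))
  ts <- trajectory_set(pos, track = c("a", "a", "b", "b"))
  ts <- add_mercator_state(ts, mercator_params())
  expect_equal(get_attribute(ts, "seam"), c(1, 1, 0, 0))
  expect_true("mercator" %in% names(ts$states))
})

test_that("transforms preserve topology, attributes and track membership", {
  ts <- make_fixture("helix", n_tracks = 3, vertices_per_track = 10, seed = 4)
  ts <- add_bundled_state(ts, bundle_params(iterations = 2))
  ts <- add_plane_state(ts, plane_spec(c(0, 0, 0), c(1, 1, 1)), name = "planar")
  ts <- add_mercator_state(ts, mercator_params(center = c(0, 0, -50)))
  expect_length(validate_trajectory_set(ts), 0)
  expect_equal(n_states(ts), 4)
  expect_equal(ts$positions, ts$states$original)
  for (st in ts$states) expect_equal(nrow(st), n_vertices(ts))
})

test_that("automatic axes span the bounding box with evenly spaced ticks", {
  ts <- trajectory_set(rbind(c(0, 0, 0), c(10, 10, 10)), track = c("a", "a"))
  ax <- auto_axes(ts, tick_count = 3)
  expect_equal(ax$ticks$x, c(0, 5, 10))
  expect_equal(ax$ticks$y, c(0, 5, 10))
  expect_equal(ax$ticks$z, c(0, 5, 10))
  expect_length(ax$polylines, 3)

  flat <- trajectory_set(rbind(c(0, 0, 5), c(10, 10, 5)), track = c("a", "a"))
  axf <- auto_axes(flat, tick_count = 3)
  expect_equal(axf$ticks$z, 5)  # degenerate dimension: single tick

  withr::with_seed(8, {
    for (i in 1:5) {
      lo <- stats::rnorm(3); hi <- lo + stats::runif(3, 0.5, 4)
      tb <- trajectory_set(rbind(lo, hi), track = c("a", "a"))
      tc <- sample(2:7, 1)
      axr <- auto_axes(tb, tick_count = tc)
      for (k in 1:3)
        expect_equal(unname(diff(axr$ticks[[k]])[1]),
                     unname((hi[k] - lo[k]) / (tc - 1)), tolerance = 1e-12)
    }
  })
})

test_that("axes transform vertex-wise with the same mapping as the data", {
  ts <- make_fixture("random_walk", n_tracks = 2, vertices_per_track = 8,
                     seed = 6)
  ax <- auto_axes(ts, 4)
  same <- transform_axes(ax, identity)
  expect_equal(same$polylines, ax$polylines)

  pl <- plane_spec(c(0, 0, 0), c(0, 0, 1))
  flat <- transform_axes(ax, function(p) project_plane_points(p, pl))
  for (poly in flat$polylines) expect_true(all(poly[, 3] == 0))

  # per-vertex oracle for an arbitrary polyline under the Mercator map
  mp <- mercator_params(center = c(100, 100, 100))
  outline <- axes_spec(list(coast = matrix(stats::rnorm(30), 10, 3)))
  mapped <- transform_axes(outline, function(p)
    project_mercator_points(p, mp))
  manual <- t(apply(outline$polylines$coast, 1, function(v)
    as.vector(project_mercator_points(rbind(v), mp))))
  expect_equal(unname(mapped$polylines$coast), unname(manual),
               tolerance = 1e-12)
})
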