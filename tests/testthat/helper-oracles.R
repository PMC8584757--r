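# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use plain per-element loops, not the package's
# vectorized code paths.

# tiny hand-built set: two tracks ("a": 3 vertices, "b": 2 vertices)
tiny_ts <- function() {
  trajectory_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0),
                       c(5, 5, 5), c(6, 5, 5)),
                 track = c("a", "a", "a", "b", "b"),
                 attributes = list(signal = c(5, 6, 7, 1, 2)))
}

# brute-force per-vertex filter + cutting-plane predicate
oracle_filter_mask <- function(ts, sel) {
  n <- n_vertices(ts)
  out <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (f in sel$filters) {
      v <- get_attribute(ts, f$attribute)[i]
      if (!(v >= f$lo && v <= f$hi)) ok <- FALSE
    }
    for (cp in sel$planes) {
      d <- sum((ts$positions[i, ] - cp$plane$origin) * cp$plane$normal)
      if (cp$keep_side * d < 0) ok <- FALSE
    }
    out[i] <- ok
  }
  out
}

oracle_shape_hit_vertex <- function(shape, p) {
  if (inherits(shape, "roi_sphere")) {
    sqrt(sum((p - shape$center)^2)) <= shape$radius
  } else {
    all(p >= shape$min) && all(p <= shape$max)
  }
}

# brute-force ordered set algebra over ROI steps
oracle_roi <- function(ts, sel) {
  n <- n_vertices(ts)
  tracks <- unique(ts$track)
  per_track <- sel$granularity == "track"
  focus <- rep(FALSE, if (per_track) length(tracks) else n)
  for (st in sel$roi_steps) {
    hit_v <- vapply(seq_len(n), function(i)
      oracle_shape_hit_vertex(st$shape, ts$positions[i, ]), TRUE)
    hit <- if (per_track)
      vapply(tracks, function(tk) any(hit_v[ts$track == tk]), TRUE)
    else hit_v
    focus <- switch(st$op,
                    add = focus | hit,
                    intersect = focus & hit,
                    subtract = focus & !hit)
  }
  unname(focus)
}

# random selection state over the attributes/geometry of a fixture
random_selection <- function(ts) {
  bb <- bounding_box(ts)
  rng_attr <- function(name) {
    a <- ts$attributes[[name]]
    b <- sort(stats::runif(2, a$vmin, a$vmax))
    attribute_filter(name, b[1], b[2])
  }
  filters <- list()
  if (stats::runif(1) < 0.7) filters <- c(filters, list(rng_attr("time")))
  if (stats::runif(1) < 0.7) filters <- c(filters, list(rng_attr("signal")))
  planes <- list()
  if (stats::runif(1) < 0.5) {
    nrm <- stats::rnorm(3)
    planes <- list(cut_plane(plane_spec(stats::runif(3, bb$min, bb$max), nrm),
                             keep_side = sample(c(-1, 1), 1)))
  }
  rand_shape <- function() {
    if (stats::runif(1) < 0.5) {
      roi_sphere(stats::runif(3, bb$min, bb$max),
                 stats::runif(1, 0.2, 1) * sqrt(sum((bb$max - bb$min)^2)) / 2)
    } else {
      a <- stats::runif(3, bb$min, bb$max); b <- stats::runif(3, bb$min, bb$max)
      roi_box(pmin(a, b), pmax(a, b))
    }
  }
  n_steps <- sample(0:3, 1)
  steps <- lapply(seq_len(n_steps), function(i)
    roi_step(rand_shape(), sample(c("add", "intersect", "subtract"), 1)))
  selection_state(filters = filters, planes = planes, roi_steps = steps,
                  granularity = sample(c("track", "vertex"), 1))
}

# recursive (independent) replay of set_value timing semantics
oracle_value_at <- function(actions, t, initial) {
  # actions: data.frame(start, end, target) for a single path
  val_before <- function(j) {
    if (j == 0) return(initial)
    actions$target[j]
  }
  value <- initial
  k <- nrow(actions)
  if (k == 0) return(initial)
  for (j in seq_len(k)) {
    if (t < actions$start[j]) return(val_before(j - 1))
    if (t < actions$end[j]) {
      frac <- (t - actions$start[j]) / (actions$end[j] - actions$start[j])
      return(val_before(j - 1) +
               frac * (actions$target[j] - val_before(j - 1)))
    }
  }
  val_before(k)
}

# mean within-bundle nearest-neighbour track distance (equal-length tracks)
mean_bundle_nn_distance <- function(pos, ts) {
  idx <- split(seq_len(nrow(pos)), factor(ts$track, levels = unique(ts$track)))
  bundle_of <- vapply(idx, function(ix)
    get_attribute(ts, "bundle")[ix[1]], 0)
  track_dist <- function(a, b)
    mean(sqrt(rowSums((pos[idx[[a]], , drop = FALSE] -
                         pos[idx[[b]], , drop = FALSE])^2)))
  nn <- vapply(seq_along(idx), function(i) {
    same <- setdiff(which(bundle_of == bundle_of[i]), i)
    min(vapply(same, function(j) track_dist(i, j), 0))
  }, 0)
  mean(nn)
}

# random rigid transform (rotation + translation)
random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = stats::rnorm(3, 0, 10))
}

expect_sets_close <- function(a, b, tol = 1e-9, attrs = TRUE) {
  expect_equal(n_vertices(a), n_vertices(b))
  expect_equal(a$segments, b$segments)
  expect_lt(max(abs(a$positions - b$positions), 0), tol)
  if (attrs) {
    expect_setequal(names(a$attributes), names(b$attributes))
    for (nm in names(a$attributes))
      expect_lt(max(abs(get_attribute(a, nm) - get_attribute(b, nm)), 0), tol)
  }
}

fixture_kinds <- c("parallel_bundles", "helix", "random_walk",
                   "grid2d_trails", "two_hemispheres")
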