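#' Deterministic synthetic trajectory fixtures
#'
#' Generators with known ground truth, standing in for the kinds of real
#' data the package targets: `parallel_bundles` (two groups of
#' near-parallel lines -- bundling contraction tests; group membership is
#' emitted as attribute `"bundle"`), `helix` (constant-curvature tracks
#' -- turning-angle and orientation tests), `random_walk` (isotropic
#' Gaussian walks -- filter/ROI tests), `grid2d_trails` (planar z = 0
#' lattice trails, like 2D+t ant-trail data), and `two_hemispheres`
#' (tracks confined to the x > 0 or x < 0 half-space -- half-space
#' selections; membership emitted as attribute `"hemisphere"`). Every
#' fixture carries a `"time"` attribute (per-track vertex rank) and a
#' synthetic `"signal"` attribute.
#'
#' A fixed `seed` gives byte-identical output; the generator uses a
#' private RNG stream and neither reads nor disturbs the global RNG
#' state.
#'
#' @param kind fixture kind (see above).
#' @param n_tracks number of tracks (even for the two-group kinds).
#' @param vertices_per_track vertices per track (>= 1).
#' @param noise per-vertex Gaussian jitter standard deviation, in the
#'   fixture's own spatial units.
#' @param seed integer RNG seed.
#' @return A [trajectory_set()].
#' @examples
#' ts <- make_fixture("parallel_bundles", n_tracks = 10,
#'                    vertices_per_track = 20, seed = 1)
#' table(get_attribute(ts, "bundle"))
#' @export
make_fixture <- function(kind = c("parallel_bundles", "helix", "random_walk",
                                  "grid2d_trails", "two_hemispheres"),
                         n_tracks = 10L, vertices_per_track = 20L,
                         noise = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  if (n_tracks < 0 || vertices_per_track < 1)
    stopf("n_tracks must be >= 0 and vertices_per_track >= 1")
  if (!is_number(noise) || noise < 0) stopf("noise must be >= 0")
  n_tracks <- as.integer(n_tracks)
  k <- as.integer(vertices_per_track)
  with_private_seed(seed, {
    if (n_tracks == 0L)
      return(trajectory_set(matrix(numeric(), ncol = 3), track = character(),
                            attributes = list(time = numeric(),
                                              signal = numeric())))
    gen <- switch(kind,
                  parallel_bundles = gen_parallel_bundles,
                  helix = gen_helix,
                  random_walk = gen_random_walk,
                  grid2d_trails = gen_grid2d_trails,
                  two_hemispheres = gen_two_hemispheres)
    gen(n_tracks, k, noise)
  })
}

fixture_base <- function(pos, n_tracks, k, extra = list()) {
  track <- rep(sprintf("trk%03d", seq_len(n_tracks)), each = k)
  tm <- rep(seq_len(k) - 1, n_tracks)
  signal <- as.vector(vapply(seq_len(n_tracks), function(i) {
    # smooth per-track signal: sine of time with random phase/amplitude
    amp <- stats::runif(1, 0.5, 2)
    phase <- stats::runif(1, 0, 2 * pi)
    amp * sin(2 * pi * (seq_len(k) - 1) / max(1, k - 1) + phase)
  }, numeric(k)))
  attributes <- c(list(time = tm, signal = signal), extra)
  trajectory_set(pos, track = track, attributes = attributes)
}

gen_parallel_bundles <- function(n_tracks, k, noise) {
  half <- ceiling(n_tracks / 2)
  bundle <- rep(c(0, 1), c(half, n_tracks - half))
  xs <- seq(0, 10, length.out = k)
  pos <- matrix(0, n_tracks * k, 3)
  for (i in seq_len(n_tracks)) {
    base_y <- if (bundle[i] == 0) 0 else 5
    off <- stats::runif(2, -0.2, 0.2)
    rows <- ((i - 1) * k + 1):(i * k)
    pos[rows, 1] <- xs
    pos[rows, 2] <- base_y + off[1] + stats::rnorm(k, 0, noise)
    pos[rows, 3] <- off[2] + stats::rnorm(k, 0, noise)
  }
  fixture_base(pos, n_tracks, k, extra = list(bundle = rep(bundle, each = k)))
}

gen_helix <- function(n_tracks, k, noise) {
  pos <- matrix(0, n_tracks * k, 3)
  for (i in seq_len(n_tracks)) {
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- phase + (seq_len(k) - 1) * (2 * pi / max(8, k))
    rows <- ((i - 1) * k + 1):(i * k)
    pos[rows, ] <- cbind(cos(theta), sin(theta),
                         0.1 * (theta - phase) + (i - 1) * 0.5) +
      matrix(stats::rnorm(3 * k, 0, noise), k, 3)
  }
  fixture_base(pos, n_tracks, k)
}

gen_random_walk <- function(n_tracks, k, noise) {
  pos <- matrix(0, n_tracks * k, 3)
  for (i in seq_len(n_tracks)) {
    start <- stats::runif(3, -5, 5)
    steps <- matrix(stats::rnorm(3 * k, 0, 0.5 + noise), k, 3)
    steps[1, ] <- 0
    rows <- ((i - 1) * k + 1):(i * k)
    walk <- matrix(apply(steps, 2, cumsum), ncol = 3)
    pos[rows, ] <- sweep(walk, 2, -start)
  }
  fixture_base(pos, n_tracks, k)
}

gen_grid2d_trails <- function(n_tracks, k, noise) {
  pos <- matrix(0, n_tracks * k, 3)
  for (i in seq_len(n_tracks)) {
    # axis-aligned lattice walk on a 10 x 10 grid, z = 0
    p <- c(sample(0:10, 1), sample(0:10, 1))
    rows <- ((i - 1) * k + 1):(i * k)
    for (j in seq_len(k)) {
      pos[rows[j], 1:2] <- p + stats::rnorm(2, 0, noise)
      step <- sample(1:4, 1)
      p <- p + switch(step, c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      p <- pmin(10, pmax(0, p))
    }
  }
  fixture_base(pos, n_tracks, k)
}

gen_two_hemispheres <- function(n_tracks, k, noise) {
  half <- ceiling(n_tracks / 2)
  hemi <- rep(c(0, 1), c(half, n_tracks - half))
  pos <- matrix(0, n_tracks * k, 3)
  for (i in seq_len(n_tracks)) {
    side <- if (hemi[i] == 0) -1 else 1
    center <- c(side * 3, stats::runif(2, -2, 2))
    steps <- matrix(stats::rnorm(3 * k, 0, 0.2 + noise), k, 3)
    steps[1, ] <- 0
    walk <- sweep(matrix(apply(steps, 2, cumsum), ncol = 3), 2, -center)
    # confine strictly to the track's half-space, margin 0.1 off the plane
    walk[, 1] <- side * pmax(0.1, abs(walk[, 1]))
    rows <- ((i - 1) * k + 1):(i * k)
    pos[rows, ] <- walk
  }
  fixture_base(pos, n_tracks, k,
               extra = list(hemisphere = rep(hemi, each = k)))
}

#' Write one fixture in every supported input format
#'
#' Emits the same trajectory set as a generic CSV (`fixture.csv`), a
#' biotracks data package (`biotracks/`), TGMM per-frame XML (`tgmm/`)
#' and an SVF linkage table (`svf.csv`), so the format readers can be
#' cross-checked against each other. Requires the per-track `"time"`
#' attribute to hold the vertex rank 0, 1, ... (as all fixtures do),
#' since TGMM needs one file per integer frame.
#'
#' @param ts a [trajectory_set()] with a `"time"` attribute.
#' @param out_dir output directory (created).
#' @return Invisibly, a list of the written paths (`csv`, `biotracks`,
#'   `tgmm`, `svf`).
#' @export
write_fixture_formats <- function(ts, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (n_vertices(ts) > 0 && !has_attribute(ts, "time"))
    stopf("fixture must carry a 'time' attribute")

  csv_path <- file.path(out_dir, "fixture.csv")
  write_selection_csv(ts, NULL, csv_path)

  bt_dir <- file.path(out_dir, "biotracks")
  write_biotracks_fixture(ts, bt_dir)

  tgmm_dir <- file.path(out_dir, "tgmm")
  write_tgmm_fixture(ts, tgmm_dir)

  svf_path <- file.path(out_dir, "svf.csv")
  write_svf_fixture(ts, svf_path)

  invisible(list(csv = csv_path, biotracks = bt_dir, tgmm = tgmm_dir,
                 svf = svf_path))
}

write_biotracks_fixture <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_vertices(ts)
  tm <- if (n > 0) get_attribute(ts, "time") else numeric()
  objects <- data.frame(OBJECT_ID = seq_len(n) - 1L,
                        FRAME = as.integer(tm),
                        X = ts$positions[, 1],
                        Y = ts$positions[, 2],
                        Z = ts$positions[, 3])
  links <- data.frame(LINK_ID = match(ts$track, unique(ts$track)) - 1L,
                      OBJECT_ID = seq_len(n) - 1L)
  utils::write.csv(objects, file.path(dir, "objects.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(links, file.path(dir, "links.csv"), row.names = FALSE,
                   quote = FALSE)
  desc <- list(name = "fixture-tracks",
               resources = list(
                 list(name = "objects_table", path = "objects.csv"),
                 list(name = "links_table", path = "links.csv")))
  write_text_file(to_json_text(desc), file.path(dir, "dataPackage.json"))
  invisible(dir)
}

write_tgmm_fixture <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_vertices(ts)
  tm <- if (n > 0) as.integer(get_attribute(ts, "time")) else integer()
  frames <- if (n > 0) 0:max(tm) else 0L
  # per-frame node id = track rank; parent = same track's id one frame back
  track_rank <- match(ts$track, unique(ts$track)) - 1L
  for (f in frames) {
    rows <- which(tm == f)
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               "<document>")
    for (r in rows) {
      parent <- if (f == 0 || !any(tm == f - 1L & track_rank == track_rank[r]))
        -1L else track_rank[r]
      lines <- c(lines, sprintf(
        '  <GaussianMixtureModel id="%d" parent="%d" m="%.12g %.12g %.12g"/>',
        track_rank[r], parent,
        ts$positions[r, 1], ts$positions[r, 2], ts$positions[r, 3]))
    }
    lines <- c(lines, "</document>")
    write_text_file(lines, file.path(dir, sprintf("frame_%04d.xml", f)))
  }
  invisible(dir)
}

write_svf_fixture <- function(ts, path) {
  n <- n_vertices(ts)
  tm <- if (n > 0) get_attribute(ts, "time") else numeric()
  cell_id <- sprintf("%s_f%04d", ts$track, as.integer(tm))
  parent <- rep("-1", n)
  if (n > 0) {
    for (ix in track_vertex_indices(ts)) {
      ord <- ix[order(tm[ix])]
      if (length(ord) > 1) parent[ord[-1]] <- cell_id[ord[-length(ord)]]
    }
  }
  df <- data.frame(cell_id = cell_id, x = ts$positions[, 1],
                   y = ts$positions[, 2], z = ts$positions[, 3],
                   t = tm, parent_id = parent)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
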