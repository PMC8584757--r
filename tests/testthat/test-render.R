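ortho_cam <- function(w = 32, h = 32, scale = 1) {
  render_camera(eye = c(0, 0, 10), look_at = c(0, 0, 0), up = c(0, 1, 0),
                scale = scale, width = w, height = h)
}

segment_ts <- function(p0, p1, tracks = "a") {
  trajectory_set(rbind(p0, p1), track = rep(tracks[1], 2))
}

test_that("vertex colours follow the colour and opacity modes", {
  # orientation mode on a +x segment is pure red
  ts <- add_orientation(segment_ts(c(0, 0, 0), c(2, 0, 0)))
  rgba <- vertex_colour(ts, visual_style(colour_orientation(),
                                         opacity_constant(1)))
  expect_equal(rgba[, 1:3], matrix(c(1, 0, 0), 2, 3, byrow = TRUE))

  # attribute mode hits the colormap endpoints at vmin/vmax
  ts2 <- trajectory_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        track = rep("a", 3),
                        attributes = list(v = c(10, 15, 20)))
  tab <- colormap_table("viridis")
  rgba2 <- vertex_colour(ts2, visual_style(colour_attribute("v"),
                                           opacity_constant(1)))
  expect_equal(unname(rgba2[1, 1:3]), unname(tab[1, ]))
  expect_equal(unname(rgba2[3, 1:3]), unname(tab[256, ]))

  # opacity ramp: mid-range attribute value -> alpha 0.5
  rgba3 <- vertex_colour(ts2, visual_style(colour_uniform(c(1, 1, 1)),
                                           opacity_attribute("v", 0, 1)))
  expect_equal(rgba3[, 4], c(0, 0.5, 1))

  expect_error(vertex_colour(ts2, visual_style(colour_orientation(),
                                               opacity_constant(1))),
               "add_orientation")
})

test_that("orientation colouring is invariant to segment direction reversal", {
  fwd <- add_orientation(segment_ts(c(0, 0, 0), c(1, 2, -2)))
  rev <- add_orientation(segment_ts(c(1, 2, -2), c(0, 0, 0)))
  st <- visual_style(colour_orientation(), opacity_constant(1))
  expect_equal(vertex_colour(fwd, st)[, 1:3], vertex_colour(rev, st)[, 1:3])
})

test_that("state blending reproduces endpoints exactly and midpoints componentwise", {
  ts <- tiny_ts()
  ts <- add_state(ts, "shifted", ts$positions + 5)
  expect_equal(blend_states(ts, 1, 2, 0), ts$states$original)
  expect_equal(blend_states(ts, 1, 2, 1), ts$states$shifted)
  expect_equal(blend_states(ts, 1, 2, 0.5),
               (ts$states$original + ts$states$shifted) / 2)
  expect_error(blend_states(ts, 1, 2, 1.5), "\\[0, 1\\]")
  expect_error(blend_states(ts, 1, "nope", 0.5), "unknown state")
})

test_that("an empty selection renders the flat background", {
  ts <- make_fixture("random_walk", 2, 5, seed = 1)
  sel <- selection_state(filters = list(attribute_filter("time", -2, -1)))
  img <- render_trajectories(ts, visual_style(), ortho_cam(16, 16, 10), sel)
  expect_equal(dim(img), c(16, 16, 3))
  expect_true(all(img == 0.5))
})

test_that("a full-width opaque horizontal segment rasterizes across its row", {
  ts <- segment_ts(c(-1.2, 0, 0), c(1.2, 0, 0))
  st <- visual_style(colour_uniform(c(1, 1, 1)), opacity_constant(1),
                     background = c(0, 0, 0))
  img <- render_trajectories(ts, st, ortho_cam(32, 32, 1))
  row_hits <- apply(img[, , 1] > 0, 1, sum)
  expect_gte(max(row_hits), 30)  # the crossed row is essentially full
  expect_equal(sum(row_hits > 0), 1)  # 1-px line touches exactly one row
})

test_that("the over operator composites two coincident half-transparent segments to 0.75", {
  base <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0))
  ts <- trajectory_set(rbind(base, base), track = c("a", "a", "b", "b"))
  st <- visual_style(colour_uniform(c(1, 1, 1)), opacity_constant(0.5),
                     background = c(0, 0, 0))
  img <- render_trajectories(ts, st, ortho_cam(16, 16, 1))
  covered <- img[, , 1][img[, , 1] > 0]
  expect_gt(length(covered), 0)
  # 0.5 + 0.5 * 0.5 over black
  expect_true(all(abs(covered - 0.75) < 1e-12))
})

test_that("rendering is bit-deterministic for identical inputs", {
  ts <- add_orientation(make_fixture("helix", 3, 12, seed = 5))
  st <- visual_style(colour_orientation(), opacity_constant(0.7))
  cam <- render_camera(eye = c(0, 0, 8), look_at = c(0, 0, 0),
                       scale = 3, width = 48, height = 48)
  img1 <- render_trajectories(ts, st, cam)
  img2 <- render_trajectories(ts, st, cam)
  expect_identical(img1, img2)
})

test_that("with full opacity the covered pixel set is order-independent", {
  ts <- make_fixture("parallel_bundles", 4, 8, seed = 2)
  st <- visual_style(colour_uniform(c(1, 0, 0)), opacity_constant(1),
                     background = c(0, 0, 0))
  cam <- render_camera(eye = c(5, 2.5, 30), look_at = c(5, 2.5, 0),
                       scale = 8, width = 32, height = 32)
  img_fwd <- render_trajectories(ts, st, cam)
  # reversed segment order: same geometry, same opaque coverage
  ts_rev <- ts
  ts_rev$segments <- ts$segments[rev(seq_len(n_segments(ts))), ]
  img_rev <- render_trajectories(ts_rev, st, cam)
  expect_equal(img_fwd[, , 1] > 0, img_rev[, , 1] > 0)
})

test_that("tour frame export: frame count, constancy and midpoint cross-check", {
  ts <- tiny_ts()
  ts <- add_state(ts, "proj", ts$positions * c(1, 1, 0))
  st <- visual_style(colour_uniform(c(1, 1, 1)), opacity_constant(1))
  cam <- render_camera(eye = c(3, 2, 20), look_at = c(3, 2, 0),
                       scale = 6, width = 24, height = 24)

  # 2-second tour at 10 fps -> 21 frames
  tr <- tour(list(action_set_value("blend", 1, delay = 0, duration = 2)))
  frames <- render_tour_frames(ts, tr, fps = 10, out_dir = NULL, st, cam,
                               blend_from = 1, blend_to = "proj")
  expect_length(frames, 21)

  # frame at the transition midpoint equals a direct render at value_at
  w_mid <- tour_value_at(tr, "blend", 1, initial = 0)
  direct <- render_trajectories(ts, st, cam,
                                positions = blend_states(ts, 1, "proj", w_mid))
  expect_identical(frames[[11]], direct)

  # a tour with no actions yields identical frames; files are written
  tr0 <- tour(list(action_marker("hold", delay = 0.45)))
  dir <- withr::local_tempdir()
  paths <- render_tour_frames(ts, tr0, fps = 10, out_dir = dir, st, cam)
  expect_length(paths, floor(0.45 * 10) + 1)
  expect_true(all(file.exists(paths)))
  hashes <- tools::md5sum(paths)
  expect_equal(length(unique(unname(hashes))), 1)
})
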