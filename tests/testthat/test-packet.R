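demo_set <- function() {
  ts <- make_fixture("helix", n_tracks = 3, vertices_per_track = 8, seed = 6)
  ts <- add_local_angle(ts)
  ts <- add_bundled_state(ts, bundle_params(iterations = 1))
  add_plane_state(ts, plane_spec(c(0, 0, 0), c(0, 0, 1)), name = "planar")
}

test_that("packet buffers have the flat layout and matching lengths", {
  ts <- trajectory_set(rbind(c(0, 0, 0), c(1, 0, 0)), track = c("a", "a"))
  dir <- withr::local_tempdir()
  build_packet(ts, dir, name = "minimal")
  dat <- jsonlite::fromJSON(file.path(dir, "data.json"))
  expect_length(dat$positions, 6)  # 3N
  expect_length(dat$indices, 2)    # 2M, 0-based
  expect_equal(dat$indices, c(0, 1))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$counts$vertices, 2)
  expect_equal(man$counts$segments, 1)
  expect_true(file.exists(file.path(dir, "index.html")))
  expect_true(file.exists(file.path(dir, "tours.json")))
  expect_true(file.exists(file.path(dir, "axes.json")))

  ts2 <- demo_set()
  dir2 <- withr::local_tempdir()
  build_packet(ts2, dir2)
  dat2 <- jsonlite::fromJSON(file.path(dir2, "data.json"),
                             simplifyDataFrame = FALSE)
  expect_length(dat2$states, 2)  # extra states only
  for (st in dat2$states)
    expect_length(st$positions, 3 * n_vertices(ts2))
})

test_that("manifest counts always equal actual buffer lengths", {
  for (kind in c("random_walk", "two_hemispheres")) {
    ts <- make_fixture(kind, n_tracks = 4, vertices_per_track = 6, seed = 2)
    dir <- withr::local_tempdir()
    build_packet(ts, dir)
    dat <- jsonlite::fromJSON(file.path(dir, "data.json"),
                              simplifyDataFrame = FALSE)
    man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                              simplifyDataFrame = FALSE)
    expect_equal(man$counts$vertices * 3, length(dat$positions))
    expect_equal(man$counts$segments * 2, length(dat$indices))
    expect_equal(man$counts$attributes, length(dat$attributes))
    expect_equal(man$counts$states, length(dat$states) + 1)
  }
})

test_that("rebuilding from identical inputs is byte-identical", {
  ts <- demo_set()
  ax <- auto_axes(ts, 4)
  trs <- list(tour(list(action_set_value("blend", 1, 1, 2)), name = "demo"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_packet(ts, d1, name = "x", axes = ax, tours = trs)
  build_packet(ts, d2, name = "x", axes = ax, tours = trs)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("build -> load round trips every fixture within serialization precision", {
  for (kind in fixture_kinds) {
    ts <- make_fixture(kind, n_tracks = 4, vertices_per_track = 6, seed = 3)
    ts <- add_state(ts, "alt", ts$positions * 0.5)
    dir <- withr::local_tempdir()
    build_packet(ts, dir, name = kind)
    lp <- load_packet(dir)
    scale <- max(abs(ts$positions), 1)
    expect_lt(max(abs(lp$ts$positions - ts$positions)) / scale, 1e-6)
    expect_equal(lp$ts$segments, ts$segments)
    expect_equal(lp$ts$track, ts$track)
    expect_setequal(names(lp$ts$attributes), names(ts$attributes))
    for (nm in names(ts$attributes))
      expect_equal(get_attribute(lp$ts, nm), get_attribute(ts, nm),
                   tolerance = 1e-6)
    expect_lt(max(abs(lp$ts$states$alt - ts$states$alt)) / scale, 1e-6)
  }
})

test_that("truncated buffers and unknown versions are rejected by name", {
  ts <- demo_set()
  dir <- withr::local_tempdir()
  build_packet(ts, dir)
  dat <- jsonlite::fromJSON(file.path(dir, "data.json"),
                            simplifyDataFrame = FALSE)
  dat$positions <- dat$positions[-(1:3)]
  writeLines(as.character(jsonlite::toJSON(dat, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(dir, "data.json"))
  expect_error(load_packet(dir), "positions")

  dir2 <- withr::local_tempdir()
  build_packet(ts, dir2)
  man <- jsonlite::fromJSON(file.path(dir2, "manifest.json"),
                            simplifyDataFrame = FALSE)
  man$version <- "99"
  writeLines(as.character(jsonlite::toJSON(man, auto_unbox = TRUE)),
             file.path(dir2, "manifest.json"))
  expect_error(load_packet(dir2), "version")
})

test_that("UI schema emits one slider per attribute and one blend slider per extra state", {
  # 3 attributes, 1 state -> 3 sliders, no blend controls
  ts <- make_fixture("random_walk", 2, 5, seed = 1)  # time, signal
  ts <- set_attribute(ts, "extra", seq_len(n_vertices(ts)) * 1.0)
  sch <- ui_schema(ts)
  expect_length(sch, 3)
  expect_true(all(vapply(sch, `[[`, "", "type") == "range_slider"))

  # slider bounds equal recomputed attribute ranges
  for (ctrl in sch) {
    v <- get_attribute(ts, ctrl$name)
    expect_equal(ctrl$min, min(v))
    expect_equal(ctrl$max, max(v))
  }

  # 1 attribute, 3 states -> 1 slider + 2 blend sliders
  ts2 <- trajectory_set(rbind(c(0, 0, 0), c(1, 0, 0)), track = c("a", "a"),
                        attributes = list(s = c(0, 1)))
  ts2 <- add_state(ts2, "b1", ts2$positions + 1)
  ts2 <- add_state(ts2, "b2", ts2$positions + 2)
  sch2 <- ui_schema(ts2)
  expect_length(sch2, 3)
  expect_equal(sum(vapply(sch2, `[[`, "", "type") == "blend_slider"), 2)
})

test_that("packet size grows linearly with vertex count", {
  sizes <- vapply(c(10L, 100L, 1000L), function(k) {
    ts <- make_fixture("random_walk", n_tracks = 10, vertices_per_track = k,
                       seed = 4)
    dir <- withr::local_tempdir()
    build_packet(ts, dir)
    file.size(file.path(dir, "data.json"))
  }, 0)
  # bytes per vertex roughly constant across two decades
  per_vertex <- sizes / (10 * c(10, 100, 1000))
  expect_lt(max(per_vertex) / min(per_vertex), 2)
})

test_that("building an invalid set is refused with the validation report", {
  ts <- tiny_ts()
  ts$segments[1, 2] <- 99L
  expect_error(build_packet(ts, withr::local_tempdir()), "out of range")
})
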