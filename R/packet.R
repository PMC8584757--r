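PACKET_FORMAT_VERSION <- "1"

#' Build a self-contained visualisation packet folder
#'
#' Writes the flat viewer buffers and metadata a browser viewer consumes:
#' `data.json` (flat x/y/z coordinate list, 0-based segment index pairs,
#' per-attribute flat value arrays in vertex order, each extra geometry
#' state's coordinates, and the per-vertex track map), `manifest.json`
#' (dataset name, counts, bounding box, attribute and state descriptors,
#' UI schema, format version), `tours.json`, `axes.json` and an
#' `index.html` stub that summarises the dataset and links the files (the
#' template is a replaceable packaged asset, so a full WebGL viewer can
#' be dropped in). Numbers are serialized with at most 9 significant
#' digits and a fixed key order, so rebuilding from equal inputs is
#' byte-identical.
#'
#' @param ts a [trajectory_set()]; must pass [validate_trajectory_set()].
#' @param out_dir output folder (created; existing packet files are
#'   overwritten).
#' @param name dataset name for the manifest.
#' @param axes optional `axes_spec`.
#' @param tours list of [tour()] objects embedded in the packet.
#' @return `out_dir`, invisibly.
#' @export
build_packet <- function(ts, out_dir, name = "dataset", axes = NULL,
                         tours = list()) {
  rep <- validate_trajectory_set(ts)
  if (length(rep) > 0)
    stopf("refusing to pack an invalid trajectory set:\n  %s",
          paste(rep, collapse = "\n  "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  extra_states <- ts$states[-1]
  data_obj <- list(
    version = PACKET_FORMAT_VERSION,
    positions = I(as.vector(t(ts$positions))),
    indices = I(as.vector(t(ts$segments)) - 1L),  # 0-based for the viewer
    track = I(ts$track),
    attributes = lapply(unname(ts$attributes), function(a)
      list(name = a$name, values = I(a$values))),
    states = lapply(seq_along(extra_states), function(i)
      list(name = names(extra_states)[i],
           positions = I(as.vector(t(extra_states[[i]])))))
  )
  write_text_file(to_json_text(data_obj), file.path(out_dir, "data.json"))

  manifest <- packet_manifest(ts, name = name, tours = tours,
                              has_axes = !is.null(axes))
  write_text_file(to_json_text(manifest), file.path(out_dir, "manifest.json"))

  tours_obj <- list(version = PACKET_FORMAT_VERSION,
                    tours = lapply(tours, tour_to_plain))
  write_text_file(to_json_text(tours_obj, digits = I(17)),
                  file.path(out_dir, "tours.json"))

  axes_obj <- if (is.null(axes)) list(version = PACKET_FORMAT_VERSION,
                                      axes = list())
  else list(version = PACKET_FORMAT_VERSION,
            axes = lapply(seq_along(axes$polylines), function(i)
              list(name = names(axes$polylines)[i],
                   polyline = I(as.vector(t(axes$polylines[[i]]))),
                   ticks = I(as.double(axes$ticks[[i]])),
                   labels = I(as.character(axes$labels[[i]])))))
  write_text_file(to_json_text(axes_obj), file.path(out_dir, "axes.json"))

  template <- readLines(system.file("extdata", "packet_index_template.html",
                                    package = "trajpacket"), warn = FALSE)
  summary_txt <- sprintf("%d vertices, %d segments, %d tracks, %d attributes, %d states",
                         n_vertices(ts), n_segments(ts),
                         length(unique(ts$track)),
                         length(ts$attributes), n_states(ts))
  html <- gsub("{{NAME}}", name, template, fixed = TRUE)
  html <- gsub("{{SUMMARY}}", summary_txt, html, fixed = TRUE)
  write_text_file(html, file.path(out_dir, "index.html"))
  invisible(out_dir)
}

#' Packet manifest (metadata + UI schema)
#' @noRd
packet_manifest <- function(ts, name, tours, has_axes) {
  bb <- if (n_vertices(ts) > 0) bounding_box(ts)
        else list(min = c(0, 0, 0), max = c(0, 0, 0))
  list(
    version = PACKET_FORMAT_VERSION,
    name = name,
    counts = list(vertices = n_vertices(ts),
                  segments = n_segments(ts),
                  states = n_states(ts),
                  attributes = length(ts$attributes)),
    bounding_box = list(min = I(unname(bb$min)), max = I(unname(bb$max))),
    attributes = lapply(unname(ts$attributes), function(a)
      list(name = a$name, vmin = a$vmin, vmax = a$vmax,
           shared = a$shared,
           default_filter = I(c(a$vmin, a$vmax)))),
    states = lapply(names(ts$states), function(nm)
      list(name = nm, blend_default = if (nm == names(ts$states)[1]) 1 else 0)),
    ui = ui_schema(ts),
    tour_names = I(vapply(tours, `[[`, "", "name")),
    has_axes = has_axes
  )
}

#' UI control schema for a trajectory set
#'
#' The viewer interface is generated per dataset: one range slider per
#' attribute (bounds = the attribute's recorded min/max, driving filter
#' and colour mapping) and, when more than one geometry state is
#' available, one blend slider per extra state for fading between the
#' original and that state.
#'
#' @param ts a [trajectory_set()].
#' @return List of control descriptors (`type`, `name`, bounds/defaults).
#' @export
ui_schema <- function(ts) {
  sliders <- lapply(unname(ts$attributes), function(a)
    list(type = "range_slider", name = a$name, min = a$vmin, max = a$vmax))
  blends <- if (n_states(ts) > 1)
    lapply(names(ts$states)[-1], function(nm)
      list(type = "blend_slider", name = nm, min = 0, max = 1, default = 0))
  else list()
  c(sliders, blends)
}

#' Load a visualisation packet back into a trajectory set
#'
#' Inverse of [build_packet()] for analysis round trips: rebuilds the
#' trajectory set (original positions, tracks, segments, attributes with
#' their manifest ranges, extra states) and returns it with the parsed
#' manifest. Unknown format versions and buffer-length mismatches are
#' errors.
#'
#' @param dir packet folder.
#' @return List with `ts` (the [trajectory_set()]) and `manifest`.
#' @export
load_packet <- function(dir) {
  data_path <- file.path(dir, "data.json")
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(data_path)) stopf("missing data.json in %s", dir)
  if (!file.exists(man_path)) stopf("missing manifest.json in %s", dir)
  dat <- jsonlite::fromJSON(data_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  man <- jsonlite::fromJSON(man_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  for (v in c(dat$version, man$version))
    if (!identical(v, PACKET_FORMAT_VERSION))
      stopf("unsupported packet format version '%s' (supported: %s)",
            v, PACKET_FORMAT_VERSION)
  n <- man$counts$vertices; m <- man$counts$segments
  if (length(dat$positions) != 3 * n)
    stopf("data.json: positions has %d values, expected %d (3 x %d vertices)",
          length(dat$positions), 3 * n, n)
  if (length(dat$indices) != 2 * m)
    stopf("data.json: indices has %d values, expected %d (2 x %d segments)",
          length(dat$indices), 2 * m, m)
  if (length(dat$track) != n)
    stopf("data.json: track map has %d values, expected %d",
          length(dat$track), n)
  pos <- matrix(dat$positions, ncol = 3, byrow = TRUE)
  seg <- matrix(as.integer(dat$indices), ncol = 2, byrow = TRUE) + 1L
  attr_meta <- man$attributes
  attributes <- lapply(seq_along(dat$attributes), function(i) {
    a <- dat$attributes[[i]]
    if (length(a$values) != n)
      stopf("data.json: attribute '%s' has %d values, expected %d",
            a$name, length(a$values), n)
    meta <- if (i <= length(attr_meta)) attr_meta[[i]] else NULL
    attribute_column(a$name, as.double(a$values),
                     vmin = meta$vmin %||% NULL, vmax = meta$vmax %||% NULL,
                     shared = isTRUE(meta$shared))
  })
  ts <- trajectory_set(pos, track = as.character(dat$track), segments = seg,
                       attributes = attributes)
  for (st in dat$states) {
    if (length(st$positions) != 3 * n)
      stopf("data.json: state '%s' has %d coordinates, expected %d",
            st$name, length(st$positions), 3 * n)
    ts <- add_state(ts, st$name, matrix(st$positions, ncol = 3, byrow = TRUE))
  }
  list(ts = ts, manifest = man)
}
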