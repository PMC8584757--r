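#' Visual styles for the headless renderer
#'
#' A style bundles a colour mode, an opacity mode, the background colour
#' and a line width. Colour modes: `colour_uniform()` (single RGB),
#' `colour_attribute()` (min-max-normalized attribute through a 256-entry
#' colormap), `colour_orientation()` (absolute movement-direction
#' components `dir_x`/`dir_y`/`dir_z` mapped to RGB -- reversal
#' invariant). Opacity modes: `opacity_constant()` or
#' `opacity_attribute()` (linear ramp over the attribute's recorded
#' range, e.g. mapping time to the opacity channel).
#'
#' @param colour_mode one of the colour mode constructors below.
#' @param opacity_mode one of the opacity mode constructors below.
#' @param background length-3 RGB in \[0, 1\] (default mid grey, the
#'   baseline render setting).
#' @param line_width line width in pixels (>= 1; widened by orthogonal
#'   dilation).
#' @return An object of class `visual_style`.
#' @export
visual_style <- function(colour_mode = colour_uniform(c(1, 1, 1)),
                         opacity_mode = opacity_constant(0.5),
                         background = c(0.5, 0.5, 0.5),
                         line_width = 1L) {
  stopifnot(inherits(colour_mode, "colour_mode"),
            inherits(opacity_mode, "opacity_mode"))
  background <- as.double(background)
  if (length(background) != 3 || any(background < 0 | background > 1))
    stopf("background must be RGB in [0, 1]")
  if (line_width < 1) stopf("line_width must be >= 1")
  structure(list(colour_mode = colour_mode, opacity_mode = opacity_mode,
                 background = background, line_width = as.integer(line_width)),
            class = "visual_style")
}

#' @rdname visual_style
#' @param rgb length-3 RGB in \[0, 1\].
#' @export
colour_uniform <- function(rgb) {
  rgb <- as.double(rgb)
  if (length(rgb) != 3 || any(rgb < 0 | rgb > 1))
    stopf("rgb must be length 3 in [0, 1]")
  structure(list(kind = "uniform", rgb = rgb), class = "colour_mode")
}

#' @rdname visual_style
#' @param name attribute name.
#' @param colormap colormap name (currently `"viridis"`).
#' @export
colour_attribute <- function(name, colormap = "viridis") {
  structure(list(kind = "attribute", name = name, colormap = colormap),
            class = "colour_mode")
}

#' @rdname visual_style
#' @export
colour_orientation <- function() {
  structure(list(kind = "orientation_xyz"), class = "colour_mode")
}

#' @rdname visual_style
#' @param alpha opacity in \[0, 1\].
#' @export
opacity_constant <- function(alpha) {
  if (!is_number(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must be in [0, 1]")
  structure(list(kind = "constant", alpha = alpha), class = "opacity_mode")
}

#' @rdname visual_style
#' @param alpha_lo,alpha_hi opacity ramp endpoints in \[0, 1\], mapped
#'   over the attribute's recorded \[vmin, vmax\].
#' @export
opacity_attribute <- function(name, alpha_lo = 0, alpha_hi = 1) {
  for (a in c(alpha_lo, alpha_hi))
    if (a < 0 || a > 1) stopf("opacity ramp endpoints must be in [0, 1]")
  structure(list(kind = "attribute", name = name,
                 alpha_lo = alpha_lo, alpha_hi = alpha_hi),
            class = "opacity_mode")
}

# 256-entry RGB colormap tables, loaded once per session from the
# packaged plain-text asset so output is platform-independent.
.colormap_cache <- new.env(parent = emptyenv())

#' 256 x 3 RGB colormap table in [0, 1]
#' @param name colormap name.
#' @return 256 x 3 numeric matrix.
#' @export
colormap_table <- function(name = "viridis") {
  if (!is.null(.colormap_cache[[name]])) return(.colormap_cache[[name]])
  path <- system.file("extdata", sprintf("colormap_%s.csv", name),
                      package = "trajpacket")
  if (path == "") stopf("unknown colormap '%s'", name)
  tab <- as.matrix(utils::read.csv(path))
  stopifnot(nrow(tab) == 256, ncol(tab) == 3)
  .colormap_cache[[name]] <- tab
  tab
}

#' Per-vertex RGBA colours under a visual style
#'
#' @param ts a [trajectory_set()] (orientation mode requires the
#'   `dir_x`/`dir_y`/`dir_z` attributes of [add_orientation()]).
#' @param style a [visual_style()].
#' @return N x 4 matrix (r, g, b, a) in \[0, 1\].
#' @export
vertex_colour <- function(ts, style) {
  n <- n_vertices(ts)
  cm <- style$colour_mode
  rgb <- switch(cm$kind,
    uniform = matrix(cm$rgb, n, 3, byrow = TRUE),
    attribute = {
      a <- ts$attributes[[cm$name]]
      if (is.null(a)) stopf("missing attribute '%s' for colour mode", cm$name)
      tab <- colormap_table(cm$colormap)
      tnorm <- if (a$vmax > a$vmin) (a$values - a$vmin) / (a$vmax - a$vmin)
               else rep(0, n)
      tab[1L + round(pmin(1, pmax(0, tnorm)) * 255), , drop = FALSE]
    },
    orientation_xyz = {
      for (nm in c("dir_x", "dir_y", "dir_z"))
        if (!has_attribute(ts, nm))
          stopf("missing attribute '%s'; run add_orientation() first", nm)
      cbind(abs(get_attribute(ts, "dir_x")),
            abs(get_attribute(ts, "dir_y")),
            abs(get_attribute(ts, "dir_z")))
    },
    stopf("unknown colour mode '%s'", cm$kind))
  om <- style$opacity_mode
  alpha <- switch(om$kind,
    constant = rep(om$alpha, n),
    attribute = {
      a <- ts$attributes[[om$name]]
      if (is.null(a)) stopf("missing attribute '%s' for opacity mode", om$name)
      tnorm <- if (a$vmax > a$vmin) (a$values - a$vmin) / (a$vmax - a$vmin)
               else rep(0, n)
      om$alpha_lo + pmin(1, pmax(0, tnorm)) * (om$alpha_hi - om$alpha_lo)
    },
    stopf("unknown opacity mode '%s'", om$kind))
  unname(cbind(rgb, alpha))
}

#' Blend two geometry states
#'
#' Componentwise `(1 - w) * state_a + w * state_b`, the fade a viewer
#' performs between the original data and a bundled or projected state.
#'
#' @param ts a [trajectory_set()].
#' @param a,b state names or indices.
#' @param w blend weight in \[0, 1\] (0 = state `a` exactly, 1 = state
#'   `b` exactly).
#' @return N x 3 coordinate matrix.
#' @export
blend_states <- function(ts, a, b, w) {
  if (!is_number(w) || w < 0 || w > 1) stopf("blend weight w must be in [0, 1]")
  pa <- ts$states[[a]]; pb <- ts$states[[b]]
  if (is.null(pa)) stopf("unknown state '%s'", a)
  if (is.null(pb)) stopf("unknown state '%s'", b)
  (1 - w) * pa + w * pb
}

#' Camera for headless rendering
#'
#' @param eye,look_at,up camera position, target and up vector (`up` must
#'   not be parallel to the view direction).
#' @param projection `"orthographic"` or `"perspective"`.
#' @param scale orthographic half-height of the view volume, world units.
#' @param fov vertical field of view in degrees (perspective).
#' @param width,height image size in pixels.
#' @return An object of class `render_camera`.
#' @export
render_camera <- function(eye, look_at, up = c(0, 1, 0),
                          projection = c("orthographic", "perspective"),
                          scale = 1, fov = 45, width = 256L, height = 256L) {
  projection <- match.arg(projection)
  eye <- as.double(eye); look_at <- as.double(look_at); up <- as.double(up)
  fwd <- look_at - eye
  if (sqrt(sum(fwd^2)) == 0) stopf("eye and look_at coincide")
  fwd <- fwd / sqrt(sum(fwd^2))
  cr <- c(fwd[2] * up[3] - fwd[3] * up[2],
          fwd[3] * up[1] - fwd[1] * up[3],
          fwd[1] * up[2] - fwd[2] * up[1])
  if (sqrt(sum(cr^2)) < 1e-12)
    stopf("up vector is parallel to the view direction")
  structure(list(eye = eye, look_at = look_at, up = up,
                 projection = projection, scale = scale, fov = fov,
                 width = as.integer(width), height = as.integer(height)),
            class = "render_camera")
}

#' Project world points to pixel coordinates + depth
#' @noRd
camera_project <- function(p, cam) {
  fwd <- cam$look_at - cam$eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * cam$up[3] - fwd[3] * cam$up[2],
             fwd[3] * cam$up[1] - fwd[1] * cam$up[3],
             fwd[1] * cam$up[2] - fwd[2] * cam$up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  rel <- sweep(p, 2, cam$eye)
  xc <- rel %*% right; yc <- rel %*% upv; zc <- rel %*% fwd
  if (cam$projection == "perspective") {
    half <- tan(cam$fov / 2 * pi / 180)
    zs <- pmax(zc, 1e-9)
    xn <- xc / (zs * half); yn <- yc / (zs * half)
  } else {
    xn <- xc / cam$scale; yn <- yc / cam$scale
  }
  cbind(px = cam$width / 2 + as.vector(xn) * cam$height / 2,
        py = cam$height / 2 - as.vector(yn) * cam$height / 2,
        depth = as.vector(zc))
}

#' Deterministic CPU render of a trajectory set
#'
#' Projects every visible segment (both endpoints visible under the
#' selection) through the camera, rasterizes it with an integer
#' Bresenham-style walk (no antialiasing; width >= 1 by orthogonal
#' dilation), interpolates the endpoint RGBA linearly along the segment,
#' and composites back-to-front with the "over" operator onto the
#' background. Segment depth is the midpoint distance along the view
#' axis; depth ties are broken by segment index, so output is
#' bit-reproducible for identical inputs.
#'
#' @param ts a [trajectory_set()].
#' @param style a [visual_style()].
#' @param cam a [render_camera()].
#' @param selection optional [selection_state()]; invisible vertices drop
#'   their segments. Focus/context styling can be rendered by two passes
#'   with the masks from [effective_visibility()].
#' @param positions optional N x 3 coordinate override (e.g. from
#'   [blend_states()]); default the original state.
#' @param vertex_mask optional logical per-vertex visibility mask,
#'   combined (AND) with the selection.
#' @return height x width x 3 numeric array in \[0, 1\].
#' @export
render_trajectories <- function(ts, style, cam, selection = NULL,
                                positions = NULL, vertex_mask = NULL) {
  p <- if (is.null(positions)) ts$positions else as_xyz_matrix(positions)
  if (nrow(p) != n_vertices(ts))
    stopf("positions override has %d vertices, expected %d",
          nrow(p), n_vertices(ts))
  visible <- rep(TRUE, n_vertices(ts))
  if (!is.null(selection)) visible <- selection_vertex_mask(ts, selection)
  if (!is.null(vertex_mask)) visible <- visible & vertex_mask
  img <- array(rep(style$background, each = cam$height * cam$width),
               dim = c(cam$height, cam$width, 3))
  seg <- ts$segments
  if (nrow(seg) == 0) return(img)
  keep <- visible[seg[, 1]] & visible[seg[, 2]]
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0) return(img)
  proj <- camera_project(p, cam)
  rgba <- vertex_colour(ts, style)
  mid_depth <- (proj[seg[, 1], 3] + proj[seg[, 2], 3]) / 2
  ord <- order(-mid_depth, seq_len(nrow(seg)))  # back to front, stable
  for (si in ord) {
    a <- seg[si, 1]; b <- seg[si, 2]
    img <- composite_segment(img, proj[a, 1:2], proj[b, 1:2],
                             rgba[a, ], rgba[b, ], style$line_width)
  }
  img
}

#' Rasterize one segment and composite it onto the image
#' @noRd
composite_segment <- function(img, pa, pb, ca, cb, lw) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- round(pa[1]); y0 <- round(pa[2])
  x1 <- round(pb[1]); y1 <- round(pb[2])
  steps <- max(abs(x1 - x0), abs(y1 - y0))
  ss <- if (steps == 0) 0 else 0:steps
  tt <- if (steps == 0) 0 else ss / steps
  xs <- round(x0 + tt * (x1 - x0))
  ys <- round(y0 + tt * (y1 - y0))
  # orthogonal dilation for line width > 1
  offs <- if (lw > 1) (-((lw - 1) %/% 2)):((lw %/% 2)) else 0L
  horiz_dom <- abs(x1 - x0) >= abs(y1 - y0)
  for (k in seq_along(xs)) {
    col <- (1 - tt[k]) * ca + tt[k] * cb
    alpha <- col[4]
    for (o in offs) {
      xk <- xs[k] + if (horiz_dom) 0L else o
      yk <- ys[k] + if (horiz_dom) o else 0L
      # pixel coordinates are 0-based in projection space
      r <- yk + 1L; c_ <- xk + 1L
      if (r < 1 || r > h || c_ < 1 || c_ > w) next
      img[r, c_, ] <- alpha * col[1:3] + (1 - alpha) * img[r, c_, ]
    }
  }
  img
}

#' Render the frames of a tour
#'
#' Samples the tour at `fps` frames per second from t = 0 to the tour's
#' total duration inclusive (frame count `floor(duration * fps) + 1`) and
#' renders each frame with the tour-resolved parameters: `set_value`
#' actions on path `"opacity"` drive a constant opacity override, path
#' `"blend"` drives the blend weight between `blend_from` and `blend_to`
#' states, and `camera` actions move the camera. Frames are written as
#' `frame_000001.png`, ... via [png::writePNG()].
#'
#' @param ts a [trajectory_set()].
#' @param tr a [tour()].
#' @param fps frames per second (> 0).
#' @param out_dir output directory (created if needed); `NULL` returns
#'   the frames as a list of arrays instead of writing files.
#' @param style base [visual_style()].
#' @param cam initial [render_camera()].
#' @param selection optional [selection_state()].
#' @param blend_from,blend_to state names/indices used when the tour
#'   drives `"blend"`.
#' @return Invisibly, the vector of file paths (or list of arrays when
#'   `out_dir` is `NULL`).
#' @export
render_tour_frames <- function(ts, tr, fps, out_dir, style, cam,
                               selection = NULL, blend_from = 1L,
                               blend_to = NULL) {
  if (!is_number(fps) || fps <= 0) stopf("fps must be > 0")
  total <- tour_duration(tr)
  nframes <- floor(total * fps) + 1
  times <- (seq_len(nframes) - 1) / fps
  drives <- function(path) any(vapply(tr$actions, function(a)
    a$kind == "set_value" && identical(a$path, path), TRUE))
  has_cam <- any(vapply(tr$actions, function(a) a$kind == "camera", TRUE))
  to_file <- !is.null(out_dir)
  if (to_file && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- if (to_file) character(nframes) else vector("list", nframes)
  cam0 <- list(eye = cam$eye, look_at = cam$look_at, up = cam$up)
  for (i in seq_len(nframes)) {
    t <- times[i]
    st <- style
    if (drives("opacity"))
      st$opacity_mode <- opacity_constant(
        min(1, max(0, tour_value_at(tr, "opacity", t,
                                    initial = style$opacity_mode$alpha %||% 1))))
    pos <- NULL
    if (drives("blend")) {
      if (is.null(blend_to)) stopf("tour drives 'blend' but blend_to is not set")
      w <- min(1, max(0, tour_value_at(tr, "blend", t, initial = 0)))
      pos <- blend_states(ts, blend_from, blend_to, w)
    }
    cam_i <- cam
    if (has_cam) {
      cs <- tour_camera_at(tr, t, cam0)
      cam_i$eye <- cs$eye; cam_i$look_at <- cs$look_at; cam_i$up <- cs$up
    }
    frame <- render_trajectories(ts, st, cam_i, selection = selection,
                                 positions = pos)
    if (to_file) {
      path <- file.path(out_dir, sprintf("frame_%06d.png", i))
      png::writePNG(frame, path)
      out[i] <- path
    } else {
      out[[i]] <- frame
    }
  }
  invisible(out)
}
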