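#' CSV dialect description for generic trajectory tables
#'
#' Describes how a plain CSV file maps onto the trajectory model: which
#' columns hold the track id and the x/y/z coordinates, an optional time
#' column, the delimiter and decimal mark, and which extra columns become
#' per-vertex attributes. Column matching is case-insensitive.
#'
#' @param id,x,y,z required column names. `z = NULL` accepts 2D input
#'   (z is padded with 0, as for planar trail data).
#' @param t optional time column; when present it orders vertices within a
#'   track and is stored as attribute `"time"`.
#' @param delim single-character field delimiter.
#' @param dec decimal mark, `"."` or `","`.
#' @param attrs character vector of extra attribute columns, or `NULL` to
#'   take every remaining numeric column.
#' @return An object of class `csv_dialect`.
#' @export
csv_dialect <- function(id = "id", x = "x", y = "y", z = "z", t = NULL,
                        delim = ",", dec = ".", attrs = NULL) {
  req <- c(id = id, x = x, y = y)
  if (!is.null(z)) req <- c(req, z = z)
  if (anyDuplicated(tolower(req)))
    stopf("required columns must be distinct (got %s)",
          paste(req, collapse = ", "))
  if (nchar(delim) != 1L) stopf("delimiter must be a single character")
  structure(list(id = id, x = x, y = y, z = z, t = t,
                 delim = delim, dec = dec, attrs = attrs),
            class = "csv_dialect")
}

match_column <- function(df, name, required = TRUE) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0) {
    if (required) stopf("missing required column '%s' (found: %s)",
                        name, paste(names(df), collapse = ", "))
    return(NA_integer_)
  }
  hit[1]
}

numeric_column <- function(df, j, what) {
  v <- df[[j]]
  if (is.numeric(v)) return(as.double(v))
  suppress <- suppressWarnings(as.double(v))
  bad <- which(is.na(suppress) & !is.na(v) & nzchar(trimws(v)))
  if (length(bad) > 0)
    stopf("non-numeric value '%s' in column '%s' at data row %d",
          v[bad[1]], what, bad[1])
  suppress
}

#' Read trajectory data from a generic plain CSV file
#'
#' One row per vertex. Rows sharing an id form one track, ordered by the
#' time column when the dialect names one (ties broken by file order, with
#' a warning) or by file order otherwise. Every extra numeric column
#' becomes a per-vertex attribute; the time column is stored as attribute
#' `"time"`.
#'
#' @param path CSV file path.
#' @param dialect a [csv_dialect()].
#' @return A [trajectory_set()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,x,y,z,signal", "A,0,0,0,5", "A,1,0,0,7"), f)
#' read_trajectory_csv(f)
#' @export
read_trajectory_csv <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = dialect$delim, dec = dialect$dec,
                        check.names = FALSE, stringsAsFactors = FALSE)
  trajectory_set_from_table(df, dialect)
}

#' @noRd
trajectory_set_from_table <- function(df, dialect = csv_dialect()) {
  j_id <- match_column(df, dialect$id)
  j_x <- match_column(df, dialect$x)
  j_y <- match_column(df, dialect$y)
  j_z <- if (is.null(dialect$z)) NA_integer_ else
    match_column(df, dialect$z, required = FALSE)
  if (!is.null(dialect$z) && is.na(j_z))
    j_z <- NA_integer_  # tolerate missing z: planar data, padded below
  j_t <- if (is.null(dialect$t)) NA_integer_ else match_column(df, dialect$t)

  id <- as.character(df[[j_id]])
  x <- numeric_column(df, j_x, names(df)[j_x])
  y <- numeric_column(df, j_y, names(df)[j_y])
  z <- if (is.na(j_z)) rep(0, nrow(df)) else numeric_column(df, j_z, names(df)[j_z])
  tm <- if (is.na(j_t)) NULL else numeric_column(df, j_t, names(df)[j_t])

  taken <- c(j_id, j_x, j_y, j_z, j_t)
  extra_j <- if (is.null(dialect$attrs)) {
    which(!(seq_along(df) %in% taken) &
            vapply(df, function(v) is.numeric(v) ||
                     all(!is.na(suppressWarnings(as.double(v[nzchar(trimws(as.character(v)))])))),
                   TRUE))
  } else {
    vapply(dialect$attrs, function(nm) match_column(df, nm), 0L)
  }

  # order rows: by id group (first-appearance order), then time within group
  ord <- order_vertex_rows(id, tm)
  id <- id[ord]
  pos <- cbind(x, y, z)[ord, , drop = FALSE]
  attributes <- list()
  if (!is.null(tm))
    attributes$time <- tm[ord]
  for (j in extra_j) {
    nm <- names(df)[j]
    attributes[[nm]] <- numeric_column(df, j, nm)[ord]
  }
  trajectory_set(pos, track = id, attributes = attributes)
}

#' Natural order of track identifiers: numeric when all ids parse as
#' numbers, else lexicographic (locale-independent radix sort), so reader
#' output does not depend on the row order of the input file.
#' @noRd
natural_id_order <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num, method = "radix")
  else order(ids, method = "radix")
}

#' Stable row order: tracks in natural id order, vertices by time (ties
#' keep file order, with a warning), or file order without time.
#' @noRd
order_vertex_rows <- function(id, tm) {
  u <- unique(id)
  grp <- match(id, u[natural_id_order(u)])
  if (is.null(tm)) return(order(grp))
  ties <- vapply(split(tm, grp), anyDuplicated, 0L)
  if (any(ties > 0))
    warnf("tied time values within %d track(s); ties broken by file order",
          sum(ties > 0))
  order(grp, tm)  # stable sort: file order breaks ties
}

#' Export selected trajectories as a CSV file
#'
#' Writes the vertices whose tracks (or vertices, depending on the
#' selection granularity) are in focus, in track order, with header
#' `id,x,y,z` plus one column per attribute. The file is re-readable by
#' [read_trajectory_csv()], yielding the selected subset. An empty
#' selection produces a header-only file.
#'
#' @param ts a [trajectory_set()].
#' @param selection a [selection_state()], or a logical per-vertex mask, or
#'   `NULL` to export everything.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_selection_csv <- function(ts, selection, path) {
  keep <- selection_vertex_mask(ts, selection)
  df <- data.frame(id = ts$track,
                   x = ts$positions[, 1],
                   y = ts$positions[, 2],
                   z = ts$positions[, 3],
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (a in ts$attributes) df[[a$name]] <- a$values
  utils::write.csv(df[keep, , drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Resolve a selection argument into a per-vertex logical mask
#' @noRd
selection_vertex_mask <- function(ts, selection) {
  n <- n_vertices(ts)
  if (is.null(selection)) return(rep(TRUE, n))
  if (is.logical(selection)) {
    if (length(selection) != n)
      stopf("logical selection mask has length %d, expected %d",
            length(selection), n)
    return(selection)
  }
  if (inherits(selection, "selection_state")) {
    vis <- vertex_passes_filters(ts, selection)
    if (length(selection$roi_steps) > 0) {
      focus <- roi_select(ts, selection)
      if (selection$granularity == "track")
        focus <- focus[match(ts$track, unique(ts$track))]
      return(vis & focus)
    }
    return(vis)
  }
  stopf("selection must be NULL, a logical mask or a selection_state")
}
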