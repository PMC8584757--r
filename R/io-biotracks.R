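#' Read a biotracks frictionless data package
#'
#' biotracks packages describe cell-tracking results as a frictionless
#' data package: a JSON descriptor (`dataPackage.json` or
#' `datapackage.json`) referencing an objects table (one row per detected
#' object, with its frame and coordinates) and a links table associating
#' object ids into links. Each link becomes one track whose vertices are
#' its objects ordered by frame; the frame is stored as attribute
#' `"time"`. Gaps (missing frames inside a link) are bridged by a straight
#' segment.
#'
#' @param package_dir directory containing the package descriptor and its
#'   CSV resources.
#' @return A [trajectory_set()], one track per link.
#' @export
read_biotracks <- function(package_dir) {
  desc_path <- NULL
  for (cand in c("dataPackage.json", "datapackage.json")) {
    p <- file.path(package_dir, cand)
    if (file.exists(p)) { desc_path <- p; break }
  }
  if (is.null(desc_path))
    stopf("no data package descriptor (dataPackage.json) in %s", package_dir)
  desc <- jsonlite::fromJSON(desc_path, simplifyVector = FALSE)
  res <- desc$resources
  if (is.null(res)) stopf("descriptor lists no resources")
  find_resource <- function(key) {
    for (r in res) {
      nm <- tolower(r$name %||% "")
      if (grepl(key, nm)) return(r)
    }
    NULL
  }
  r_obj <- find_resource("object")
  r_lnk <- find_resource("link")
  if (is.null(r_obj)) stopf("missing objects table in biotracks package")
  if (is.null(r_lnk)) stopf("missing links table in biotracks package")

  objects <- read_resource_csv(package_dir, r_obj)
  links <- read_resource_csv(package_dir, r_lnk)

  j_oid <- match_column(objects, "OBJECT_ID")
  j_frame <- match_column(objects, "FRAME")
  j_x <- match_column(objects, "X")
  j_y <- match_column(objects, "Y")
  j_z <- match_column(objects, "Z", required = FALSE)
  j_lid <- match_column(links, "LINK_ID")
  j_lobj <- match_column(links, "OBJECT_ID")

  oid <- as.character(objects[[j_oid]])
  lid <- as.character(links[[j_lid]])
  lobj <- as.character(links[[j_lobj]])
  row_of <- match(lobj, oid)
  if (anyNA(row_of))
    stopf("link references unknown object id(s): %s",
          paste(utils::head(unique(lobj[is.na(row_of)]), 5), collapse = ", "))

  frame <- numeric_column(objects, j_frame, "FRAME")[row_of]
  pos <- cbind(numeric_column(objects, j_x, "X")[row_of],
               numeric_column(objects, j_y, "Y")[row_of],
               if (is.na(j_z)) rep(0, length(row_of))
               else numeric_column(objects, j_z, "Z")[row_of])

  ord <- order_vertex_rows(lid, frame)
  trajectory_set(pos[ord, , drop = FALSE], track = lid[ord],
                 attributes = list(time = frame[ord]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_resource_csv <- function(dir, resource) {
  path <- resource$path %||% resource$url
  if (is.null(path)) stopf("resource '%s' has no path", resource$name %||% "?")
  full <- file.path(dir, path)
  if (!file.exists(full)) stopf("missing table: %s", full)
  utils::read.csv(full, check.names = FALSE, stringsAsFactors = FALSE)
}
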