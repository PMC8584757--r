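#' Read TGMM per-timepoint XML tracking output
#'
#' TGMM writes one XML document per timepoint; each Gaussian-mixture node
#' carries a numeric `id` (unique within the frame), a `parent` id
#' referring to a node of the previous frame (-1 or missing for a track
#' root) and a mean position `m` of three reals. Tracks are maximal
#' parent-chains across frames; the frame index is stored as attribute
#' `"time"`.
#'
#' At a cell division (two children naming the same parent) the policy
#' decides the track structure: `"split-at-division"` (default) ends the
#' parent track and starts one new track per child, keeping tracks simple
#' polylines; `"duplicate-history"` instead copies the shared ancestry
#' into every child track, so each daughter track runs from the lineage
#' root.
#'
#' @param xml_dir directory of per-frame XML files.
#' @param frame_pattern regular expression selecting the frame files;
#'   files are ordered by name (natural file order = frame order).
#' @param lineage_policy `"split-at-division"` or `"duplicate-history"`.
#' @return A [trajectory_set()].
#' @export
read_tgmm <- function(xml_dir, frame_pattern = "\\.xml$",
                      lineage_policy = c("split-at-division",
                                         "duplicate-history")) {
  lineage_policy <- match.arg(lineage_policy)
  files <- sort(list.files(xml_dir, pattern = frame_pattern,
                           full.names = TRUE))
  if (length(files) == 0) stopf("no XML frame files in %s", xml_dir)

  # flat per-node records across frames
  frame <- integer(); id <- integer(); parent <- integer()
  pos <- matrix(numeric(), ncol = 3)
  for (fi in seq_along(files)) {
    doc <- xml2::read_xml(files[fi])
    nodes <- xml2::xml_find_all(doc, ".//*[@m]")
    for (nd in nodes) {
      nid <- as.integer(xml2::xml_attr(nd, "id"))
      npar <- xml2::xml_attr(nd, "parent")
      npar <- if (is.na(npar) || npar == "") -1L else as.integer(npar)
      m <- xml2::xml_attr(nd, "m")
      xyz <- suppressWarnings(as.numeric(strsplit(trimws(m), "[[:space:]]+")[[1]]))
      if (length(xyz) != 3 || anyNA(xyz))
        stopf("malformed position string '%s' for node id %d in %s",
              m, nid, basename(files[fi]))
      frame <- c(frame, fi - 1L); id <- c(id, nid); parent <- c(parent, npar)
      pos <- rbind(pos, xyz)
    }
  }
  n <- length(id)
  if (n == 0) {
    return(trajectory_set(matrix(numeric(), ncol = 3), track = character(),
                          attributes = list(time = numeric())))
  }

  # resolve each node's parent record in the previous frame
  key <- paste(frame, id)
  parent_rec <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (parent[i] < 0) next
    hit <- match(paste(frame[i] - 1L, parent[i]), key)
    if (is.na(hit)) {
      warnf("node id %d in frame %d names unknown parent %d; treated as track start",
            id[i], frame[i], parent[i])
    } else {
      parent_rec[i] <- hit
    }
  }
  child_count <- tabulate(parent_rec[!is.na(parent_rec)], nbins = n)

  # walk lineages into polyline tracks
  out_rows <- integer(); out_track <- character(); track_id <- 0L
  if (lineage_policy == "split-at-division") {
    # a node starts a track if it has no parent record or its parent divided
    is_start <- vapply(seq_len(n), function(i)
      is.na(parent_rec[i]) || child_count[parent_rec[i]] > 1, TRUE)
    starts <- which(is_start)
    children_of <- split(seq_len(n)[!is.na(parent_rec)],
                         parent_rec[!is.na(parent_rec)])
    for (s in starts) {
      track_id <- track_id + 1L
      cur <- s
      chain <- cur
      repeat {
        kids <- children_of[[as.character(cur)]]
        if (is.null(kids) || length(kids) != 1L) break
        cur <- kids
        chain <- c(chain, cur)
      }
      out_rows <- c(out_rows, chain)
      out_track <- c(out_track, rep(sprintf("t%04d", track_id), length(chain)))
    }
  } else {
    # duplicate-history: one track per leaf, back-walked to the root
    is_leaf <- child_count == 0
    for (leaf in which(is_leaf)) {
      track_id <- track_id + 1L
      chain <- leaf
      cur <- leaf
      guard <- 0L
      while (!is.na(parent_rec[cur])) {
        cur <- parent_rec[cur]
        chain <- c(cur, chain)
        guard <- guard + 1L
        if (guard > n) stopf("lineage cycle detected")
      }
      out_rows <- c(out_rows, chain)
      out_track <- c(out_track, rep(sprintf("t%04d", track_id), length(chain)))
    }
  }

  trajectory_set(pos[out_rows, , drop = FALSE], track = out_track,
                 attributes = list(time = as.double(frame[out_rows])))
}
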