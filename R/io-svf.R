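#' Read an SVF-style linkage table
#'
#' Expects a CSV table with one row per cell observation and columns
#' `cell_id`, `x`, `y`, `z`, `t` and `parent_id`, where `parent_id` names
#' the same cell's previous observation (its `cell_id`) or is empty / -1
#' at a track root. Tracks are reconstructed by following the linkage
#' forward over time; the time value is stored as attribute `"time"`.
#' The result is independent of the row order in the file.
#'
#' @param path CSV file path.
#' @return A [trajectory_set()].
#' @export
read_svf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  j_cid <- match_column(df, "cell_id")
  j_x <- match_column(df, "x"); j_y <- match_column(df, "y")
  j_z <- match_column(df, "z", required = FALSE)
  j_t <- match_column(df, "t")
  j_par <- match_column(df, "parent_id")

  cid <- as.character(df[[j_cid]])
  if (anyDuplicated(cid)) stopf("duplicate cell_id value(s)")
  par <- as.character(df[[j_par]])
  par[is.na(par) | par %in% c("", "-1")] <- NA_character_
  parent_row <- match(par, cid)
  if (any(!is.na(par) & is.na(parent_row)))
    stopf("parent_id references unknown cell_id: %s",
          paste(utils::head(par[!is.na(par) & is.na(parent_row)], 5),
                collapse = ", "))

  n <- nrow(df)
  pos <- cbind(numeric_column(df, j_x, "x"),
               numeric_column(df, j_y, "y"),
               if (is.na(j_z)) rep(0, n) else numeric_column(df, j_z, "z"))
  tm <- numeric_column(df, j_t, "t")

  roots <- which(is.na(parent_row))
  roots <- roots[natural_id_order(cid[roots])]  # row-order independence
  children_of <- split(seq_len(n)[!is.na(parent_row)],
                       parent_row[!is.na(parent_row)])
  visited <- rep(FALSE, n)
  out_rows <- integer(); out_track <- character()
  for (k in seq_along(roots)) {
    chain <- integer(); cur <- roots[k]
    repeat {
      if (visited[cur]) stopf("cyclic linkage at cell_id '%s'", cid[cur])
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      kids <- children_of[[as.character(cur)]]
      if (is.null(kids) || length(kids) == 0) break
      if (length(kids) > 1)
        stopf("cell_id '%s' has %d successors; linkage must be a chain",
              cid[cur], length(kids))
      cur <- kids
    }
    chain <- chain[order(tm[chain])]
    out_rows <- c(out_rows, chain)
    out_track <- c(out_track, rep(cid[roots[k]], length(chain)))
  }
  if (!all(visited) && n > 0) stopf("cyclic linkage: %d row(s) unreachable from any root",
                                    sum(!visited))
  trajectory_set(pos[out_rows, , drop = FALSE], track = out_track,
                 attributes = list(time = tm[out_rows]))
}
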