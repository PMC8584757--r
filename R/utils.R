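# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Coerce to an N x 3 numeric coordinate matrix
#' @noRd
as_xyz_matrix <- function(x, what = "positions") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stopf("%s length (%d) is not a multiple of 3", what, length(x))
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stopf("%s must be an N x 3 numeric matrix or a flat length-3N vector", what)
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  x
}

#' Run code with a private RNG state seeded from `seed`
#'
#' Saves and restores `.Random.seed` so generators never leak global
#' RNG state (and are unaffected by it).
#' @noRd
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Row-wise Euclidean norms
#' @noRd
row_norms <- function(m) sqrt(rowSums(m * m))

#' Normalize rows to unit length; zero rows stay zero
#' @noRd
normalize_rows <- function(m) {
  n <- row_norms(m)
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m[!ok, ] <- 0
  m
}

#' Deterministic JSON text (sorted-stable structure is the caller's job)
#' @noRd
to_json_text <- function(x, digits = I(9)) {
  as.character(jsonlite::toJSON(x, digits = digits, auto_unbox = TRUE,
                                null = "null", na = "null"))
}

#' Write a text file with a single trailing newline and unix line endings
#' @noRd
write_text_file <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
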