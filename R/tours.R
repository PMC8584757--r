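#' Tour actions
#'
#' A tour is an ordered list of timed actions replayed as a guided
#' presentation. Three kinds are supported: `set_value` (drive a numeric
#' visualisation parameter to a target, optionally over a transition),
#' `camera` (move eye / look-at / up, interpolated componentwise), and
#' `marker` (timed text annotation). Each action starts `delay` seconds
#' after the *end* of the previous action and its transition lasts
#' `duration` seconds.
#'
#' @param path parameter path the action drives (e.g. `"opacity"`,
#'   `"blend"`).
#' @param value numeric target value.
#' @param delay seconds after the previous action's end (>= 0, finite).
#' @param duration transition length in seconds (>= 0, finite; 0 is a
#'   step change).
#' @return An object of class `tour_action`.
#' @export
action_set_value <- function(path, value, delay = 0, duration = 0) {
  new_tour_action("set_value", delay, duration,
                  path = as.character(path), value = as.double(value))
}

#' @rdname action_set_value
#' @param eye,look_at,up camera vectors (length 3 each).
#' @export
action_camera <- function(eye, look_at, up = c(0, 1, 0), delay = 0,
                          duration = 0) {
  new_tour_action("camera", delay, duration,
                  eye = as.double(eye), look_at = as.double(look_at),
                  up = as.double(up))
}

#' @rdname action_set_value
#' @param text marker text.
#' @export
action_marker <- function(text, delay = 0, duration = 0) {
  new_tour_action("marker", delay, duration, text = as.character(text))
}

new_tour_action <- function(kind, delay, duration, ...) {
  if (!is_number(delay) || delay < 0) stopf("delay must be finite and >= 0")
  if (!is_number(duration) || duration < 0)
    stopf("duration must be finite and >= 0")
  structure(c(list(kind = kind, delay = as.double(delay),
                   duration = as.double(duration)), list(...)),
            class = "tour_action")
}

#' Assemble a tour from actions
#' @param actions list of `tour_action` objects.
#' @param name tour name.
#' @return An object of class `tour`.
#' @export
tour <- function(actions = list(), name = "tour") {
  for (a in actions) stopifnot(inherits(a, "tour_action"))
  structure(list(name = as.character(name), actions = actions),
            class = "tour")
}

#' Compute the action schedule of a tour
#'
#' Start and end time per action: the first action ends its delay after
#' time 0, and every subsequent action starts `delay` after the previous
#' action's end; `end = start + duration`. Start times are therefore
#' non-decreasing.
#'
#' @param tr a [tour()].
#' @return Data frame with one row per action: `kind`, `start`, `end`.
#' @examples
#' tr <- tour(list(action_set_value("opacity", 1, delay = 1, duration = 3),
#'                 action_marker("done", delay = 2)))
#' tour_schedule(tr)  # spans (1,4) and (6,6)
#' @export
tour_schedule <- function(tr) {
  stopifnot(inherits(tr, "tour"))
  k <- length(tr$actions)
  start <- numeric(k); end <- numeric(k)
  prev_end <- 0
  for (i in seq_len(k)) {
    a <- tr$actions[[i]]
    start[i] <- prev_end + a$delay
    end[i] <- start[i] + a$duration
    prev_end <- end[i]
  }
  data.frame(kind = vapply(tr$actions, `[[`, "", "kind"),
             start = start, end = end)
}

#' Total duration of a tour (end of its last action)
#' @param tr a [tour()].
#' @return Single number (0 for an empty tour).
#' @export
tour_duration <- function(tr) {
  s <- tour_schedule(tr)
  if (nrow(s) == 0) 0 else s$end[nrow(s)]
}

#' Value of a driven parameter at a given time
#'
#' Replays the tour's `set_value` actions for one parameter path: before
#' any action the parameter holds `initial`; during a transition of
#' positive duration the value interpolates linearly from its value at
#' the transition start to the target; a zero-duration action is a step
#' change at its start time; between transitions the last reached target
#' holds. Continuous in t wherever durations are positive.
#'
#' @param tr a [tour()].
#' @param path parameter path (must be driven by at least one action, or
#'   known via `initial`).
#' @param t time in seconds (vectorized).
#' @param initial value before the first action (default 0).
#' @return Numeric vector, one value per element of `t`.
#' @export
tour_value_at <- function(tr, path, t, initial = 0) {
  stopifnot(inherits(tr, "tour"))
  sched <- tour_schedule(tr)
  is_sv <- vapply(tr$actions, function(a)
    a$kind == "set_value" && identical(a$path, path), TRUE)
  ai <- which(is_sv)
  if (length(ai) == 0 && missing(initial))
    stopf("unknown parameter path '%s': no action drives it and no initial value was given",
          path)
  starts <- sched$start[ai]; ends <- sched$end[ai]
  targets <- vapply(tr$actions[ai], `[[`, 0, "value")
  vapply(t, function(tt) {
    val <- initial
    prev <- initial
    for (j in seq_along(ai)) {
      if (tt < starts[j]) break
      if (tt >= ends[j]) {
        prev <- targets[j]
        val <- targets[j]
      } else {
        frac <- (tt - starts[j]) / (ends[j] - starts[j])
        val <- prev + frac * (targets[j] - prev)
        break
      }
    }
    val
  }, 0)
}

#' Camera state at a given time
#'
#' Componentwise linear interpolation of eye / look-at / up through the
#' tour's `camera` actions, with the same timing semantics as
#' [tour_value_at()].
#'
#' @param tr a [tour()].
#' @param t single time in seconds.
#' @param initial list with `eye`, `look_at`, `up` before the first
#'   camera action.
#' @return List with `eye`, `look_at`, `up`.
#' @export
tour_camera_at <- function(tr, t, initial) {
  sched <- tour_schedule(tr)
  ai <- which(vapply(tr$actions, function(a) a$kind == "camera", TRUE))
  cur <- initial
  for (j in ai) {
    a <- tr$actions[[j]]
    if (t < sched$start[j]) break
    if (t >= sched$end[j]) {
      cur <- list(eye = a$eye, look_at = a$look_at, up = a$up)
    } else {
      frac <- (t - sched$start[j]) / (sched$end[j] - sched$start[j])
      cur <- list(eye = cur$eye + frac * (a$eye - cur$eye),
                  look_at = cur$look_at + frac * (a$look_at - cur$look_at),
                  up = cur$up + frac * (a$up - cur$up))
      break
    }
  }
  cur
}

# Largest binary payload of a version-40, error-correction-L QR code.
QR_CAPACITY_BYTES <- 2953L

#' Serialize a tour to URL-safe text
#'
#' Deterministic, versioned encoding for sharing a tour in a URL query
#' parameter (`?tour=...`) or a QR code: the tour is written as compact
#' JSON with a fixed key order and base64url-encoded behind the version
#' header `"TP1."`. The empty default tour encodes to the bare header
#' `"TP1."`. Payloads beyond the 2,953-byte QR capacity (version 40-L)
#' are refused -- such tours belong inside the visualisation packet
#' instead.
#'
#' @param tr a [tour()].
#' @return URL-safe character scalar.
#' @export
serialize_tour <- function(tr) {
  stopifnot(inherits(tr, "tour"))
  payload <- if (length(tr$actions) == 0 && identical(tr$name, "tour")) ""
  else {
    json <- to_json_text(tour_to_plain(tr), digits = I(17))
    jsonlite::base64url_enc(charToRaw(json))
  }
  out <- paste0("TP1.", payload)
  if (nchar(out, type = "bytes") > QR_CAPACITY_BYTES)
    stopf("tour too large for QR (%d > %d bytes); embed it in the packet instead",
          nchar(out, type = "bytes"), QR_CAPACITY_BYTES)
  out
}

#' @rdname serialize_tour
#' @param text a string produced by `serialize_tour()`.
#' @export
deserialize_tour <- function(text) {
  if (!startsWith(text, "TP1."))
    stopf("unsupported tour encoding version (expected 'TP1.' header)")
  payload <- substring(text, 5L)
  if (payload == "") return(tour())
  json <- rawToChar(jsonlite::base64url_dec(payload))
  plain_to_tour(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

#' @noRd
tour_to_plain <- function(tr) {
  list(name = tr$name,
       actions = lapply(tr$actions, function(a) {
         base <- list(kind = a$kind, delay = a$delay, duration = a$duration)
         extra <- switch(a$kind,
                         set_value = list(path = a$path, value = a$value),
                         camera = list(eye = as.list(a$eye),
                                       look_at = as.list(a$look_at),
                                       up = as.list(a$up)),
                         marker = list(text = a$text))
         c(base, extra)
       }))
}

#' @noRd
plain_to_tour <- function(pl) {
  actions <- lapply(pl$actions, function(a) {
    switch(a$kind,
           set_value = action_set_value(a$path, a$value, a$delay, a$duration),
           camera = action_camera(unlist(a$eye), unlist(a$look_at),
                                  unlist(a$up), a$delay, a$duration),
           marker = action_marker(a$text, a$delay, a$duration),
           stopf("unknown action kind '%s'", a$kind))
  })
  tour(actions, name = pl$name)
}
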