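#' Moving-average landmark stabilizer
#'
#' Detector-estimated facial landmarks fluctuate frame to frame with image
#' noise; averaging the landmarks of successive frames stabilizes the
#' downstream head-landmark overlay at the cost of a lag of one window
#' length after a head movement.  `stabilizer()` creates the state;
#' `stabilizer_push()` consumes one frame and returns the smoothed frame
#' (the coordinate-wise mean of the last `min(seen, window)` frames)
#' together with the updated state.
#'
#' @param window Averaging window length in frames (positive integer;
#'   1 = pass-through; 3/5/8/10 are the typical trade-off settings).
#' @return `stabilizer()`: a `stabilizer_state`.
#' @export
#' @examples
#' st <- stabilizer(3)
#' f <- facial_landmarks(matrix(0.5, 24, 3), "synthetic24")
#' out <- stabilizer_push(st, f)
#' out$frame$points[1, ]
stabilizer <- function(window = 1L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) {
    stop("window must be a positive integer", call. = FALSE)
  }
  structure(list(window = window, buffer = list(), convention = NULL),
            class = "stabilizer_state")
}

#' @rdname stabilizer
#' @param state A `stabilizer_state`.
#' @param frame A [facial_landmarks()] frame; the convention must stay
#'   constant across the stream.
#' @return `stabilizer_push()`: a list with `frame` (the smoothed
#'   [facial_landmarks()]) and `state` (the updated state).
#' @export
stabilizer_push <- function(state, frame) {
  stopifnot(inherits(state, "stabilizer_state"),
            inherits(frame, "facial_landmarks"))
  if (is.null(state$convention)) {
    state$convention <- frame$convention
  } else if (state$convention != frame$convention) {
    stop(sprintf("landmark convention changed mid-stream ('%s' -> '%s')",
                 state$convention, frame$convention), call. = FALSE)
  }
  state$buffer <- c(state$buffer, list(frame$points))
  if (length(state$buffer) > state$window) {
    state$buffer <- state$buffer[-1L]
  }
  avg <- Reduce(`+`, state$buffer) / length(state$buffer)
  smoothed <- facial_landmarks(avg, convention = frame$convention,
                               frame = frame$frame)
  list(frame = smoothed, state = state)
}

#' Per-frame tracking pipeline
#'
#' Composes the full per-frame workflow over a recorded facial-landmark
#' stream: stabilize, predict cranial landmarks, fit the atlas registration,
#' transform the atlas layout, apply the manual offset, and project to an
#' image overlay.  The registration is refitted every frame (an optional
#' `refit_interval` reuses the previous transform in between for speed).
#' Frames with no detected face (`NULL` entries or empty point sets) are
#' skipped: no overlay is emitted and the stabilizer buffer is left
#' untouched.
#'
#' @param frames List of [facial_landmarks()] (normalized-camera frame), or
#'   `NULL` for undetected frames.
#' @param map A [fit_linear_headmap()] result.
#' @param atlas An [atlas_bundle()].
#' @param config List of options: `density` (default `"10-20"`), `mode`
#'   (`"five-point"`), `window` (1), `offset` (`c(0,0,0)`), `image_size`
#'   (`c(640, 480)`), `refit_interval` (1 = every frame).
#' @return List of [project_overlay()] frames (one per detected frame, with
#'   `frame_index` set to the input position), with attribute `log`: a
#'   data.frame of per-frame stage timings in seconds.
#' @export
process_stream <- function(frames, map, atlas, config = list()) {
  stopifnot(inherits(map, "linear_headmap"), inherits(atlas, "atlas_bundle"))
  if (length(frames) == 0L) stop("empty frame stream", call. = FALSE)
  cfg <- modifyList(list(density = "10-20", mode = "five-point", window = 1L,
                         offset = c(0, 0, 0), image_size = c(640L, 480L),
                         refit_interval = 1L), config)
  layout0 <- atlas$layouts[[cfg$density]]
  if (is.null(layout0)) {
    stop(sprintf("atlas bundle has no layout at density '%s'", cfg$density),
         call. = FALSE)
  }
  st <- stabilizer(cfg$window)
  overlays <- list()
  log_rows <- list()
  tf <- NULL
  n_since_fit <- Inf
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.null(fr) || (inherits(fr, "facial_landmarks") && nrow(fr$points) == 0L)) {
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      sp <- stabilizer_push(st, fr)
      st <- sp$state
      pred <- predict_cranial(map, sp$frame)
      if (n_since_fit >= cfg$refit_interval || is.null(tf)) {
        tf <- fit_registration(pred, atlas$cranial, mode = cfg$mode)
        n_since_fit <- 0L
      }
      n_since_fit <- n_since_fit + 1L
      ly <- apply_offset(transform_layout(layout0, tf), cfg$offset)
      project_overlay(ly, cfg$image_size, frame_index = i)
    }, error = function(e) {
      stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    overlays[[length(overlays) + 1L]] <- res
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(frame = i, elapsed_s = proc.time()[["elapsed"]] - t0)
  }
  if (length(overlays) == 0L) stop("stream contained no detectable frames",
                                   call. = FALSE)
  attr(overlays, "log") <- do.call(rbind, log_rows)
  overlays
}
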