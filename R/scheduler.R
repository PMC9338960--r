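#' Expand a program into illumination events
#'
#' Loop expansion: pulse `k` (0-based) of a command starts at
#' `start_s + k * interval_s` for `k < repeats`. Each event carries the
#' command's resolved LED set (targets are resolved once per command), a
#' half-open interval `[t_on, t_off)`, the color, and the index of its source
#' command. Message-only commands produce no events. Events are sorted by
#' `t_on` (stable).
#'
#' @param program A `stim_program`.
#' @param placement A `placement`; default is the program's plate at its
#'   default placement.
#' @param matrix A `matrix_spec`.
#' @return List of events; each is a list with `led`, `t_on_s`, `t_off_s`,
#'   `color`, `source_command`.
#' @export
expand_program <- function(program, placement = NULL,
                           matrix = default_matrix()) {
  stopifnot(inherits(program, "stim_program"))
  if (is.null(placement)) placement <- default_placement(program$plate, matrix)
  events <- list()
  for (i in seq_along(program$commands)) {
    cm <- program$commands[[i]]
    if (!nzchar(cm$target)) next
    leds <- resolve_target(cm$target, placement, matrix)
    step <- if (is.na(cm$interval_s)) 0L else cm$interval_s
    for (k in seq_len(cm$repeats) - 1L) {
      t_on <- cm$start_s + k * step
      events[[length(events) + 1L]] <- list(
        led = leds, t_on_s = t_on, t_off_s = t_on + cm$duration_s,
        color = cm$color, source_command = i)
    }
  }
  if (length(events) > 1L) {
    events <- events[order(vapply(events, `[[`, integer(1), "t_on_s"))]
  }
  events
}

#' Compile events into a 1 Hz frame timeline
#'
#' The timeline holds, for every second with any light, a full
#' `n_rows x n_cols x 3` intensity grid; all-off seconds are absent (sparse
#' contract). Overlapping events combine channel-wise by maximum — an
#' idempotent, order-independent policy that cannot exceed the 255 hardware
#' ceiling.
#'
#' @param events Event list from [expand_program()].
#' @param matrix A `matrix_spec`.
#' @param horizon_s Timeline horizon; default the last event off-time.
#' @return Object of class `frame_timeline`: list with `horizon_s` and
#'   `frames`, a list of integer arrays named by second.
#' @export
build_timeline <- function(events, matrix = default_matrix(),
                           horizon_s = NULL) {
  if (length(events) > 0L) {
    last_off <- max(vapply(events, `[[`, integer(1), "t_off_s"))
  } else {
    last_off <- 0L
  }
  if (is.null(horizon_s)) horizon_s <- last_off
  horizon_s <- as.integer(horizon_s)
  if (last_off > horizon_s) stop("event extends past the timeline horizon")
  frames <- new.env(parent = emptyenv())
  dims <- c(matrix$n_rows, matrix$n_cols, 3L)
  for (ev in events) {
    if (nrow(ev$led) == 0L) next
    on_ch <- which(ev$color > 0L)
    if (length(on_ch) == 0L) next
    idx1 <- ev$led$row + 1L
    idx2 <- ev$led$col + 1L
    for (t in ev$t_on_s:(ev$t_off_s - 1L)) {
      key <- as.character(t)
      fr <- frames[[key]]
      if (is.null(fr)) fr <- array(0L, dims)
      for (ch in on_ch) {
        sel <- cbind(idx1, idx2, ch)
        fr[sel] <- pmax(fr[sel], ev$color[[ch]])
      }
      frames[[key]] <- fr
    }
  }
  keys <- as.character(sort(as.integer(ls(frames))))
  structure(list(horizon_s = horizon_s,
                 frames = mget(keys, envir = frames)),
            class = "frame_timeline")
}

#' @export
print.frame_timeline <- function(x, ...) {
  cat(sprintf("<frame_timeline> horizon %d s, %d lit frames\n",
              x$horizon_s, length(x$frames)))
  invisible(x)
}

#' Frame at a given second
#'
#' @param timeline A `frame_timeline`.
#' @param t_s Second (integer, `0 <= t < horizon`).
#' @param matrix A `matrix_spec` (shape of the all-off frame).
#' @return Integer `n_rows x n_cols x 3` array (all zeros for unlit seconds).
#' @export
timeline_frame <- function(timeline, t_s, matrix = default_matrix()) {
  fr <- timeline$frames[[as.character(as.integer(t_s))]]
  if (is.null(fr)) array(0L, c(matrix$n_rows, matrix$n_cols, 3L)) else fr
}

#' Total lit LED-seconds of a timeline
#'
#' Number of (LED, second) pairs with any nonzero channel.
#' @param timeline A `frame_timeline`.
#' @return Integer count.
#' @export
lit_led_seconds <- function(timeline) {
  sum(vapply(timeline$frames, function(fr) {
    sum(apply(fr > 0L, c(1, 2), any))
  }, numeric(1)))
}

#' Duty cycle of one LED over a window
#'
#' Fraction of seconds in the half-open window `[from, to)` during which the
#' LED has any nonzero channel. Duty cycle drives both light dose and
#' heating: longer and more frequent stimulation means a higher duty cycle.
#'
#' @param timeline A `frame_timeline`.
#' @param led Length-2 integer `(row, col)`, 0-based.
#' @param window Length-2 integer `(from, to)` seconds; default the full
#'   horizon.
#' @return Fraction in `[0, 1]`.
#' @examples
#' # a 10 s pulse every 120 s has duty cycle 10/120
#' @export
duty_cycle <- function(timeline, led, window = c(0L, timeline$horizon_s)) {
  window <- as.integer(window)
  if (window[2] <= window[1]) stop("empty window: duty cycle is undefined")
  if (window[1] < 0L || window[2] > timeline$horizon_s) {
    stop("window outside the timeline horizon")
  }
  secs <- as.integer(names(timeline$frames))
  secs <- secs[secs >= window[1] & secs < window[2]]
  on <- vapply(as.character(secs), function(k) {
    any(timeline$frames[[k]][led[1] + 1L, led[2] + 1L, ] > 0L)
  }, logical(1))
  sum(on) / (window[2] - window[1])
}

#' Design a staggered schedule with a simultaneous endpoint
#'
#' Time-course experiments on one plate are run by staggering stimulation
#' starts so that every condition reaches its target stimulation-to-fixation
#' interval at one common endpoint: well `k` receives the pulse starting at
#' `horizon - time_point_k`, and all wells are fixed together at `horizon`.
#'
#' @param time_points_s Stimulation-to-end intervals (seconds), one per well.
#' @param pulse A [command()] used as template (its target and start are
#'   ignored).
#' @param wells Well addresses, same length as `time_points_s`.
#' @param horizon_s Common endpoint; default `max(time_points_s)`.
#' @param plate Plate format name for the program metadata.
#' @return A `stim_program` whose commands start at `horizon - time_point`;
#'   the common endpoint is recorded in its `endpoint_s` attribute.
#' @examples
#' p <- reverse_schedule(120 * (1:12), command("A01", 0, 10, "blue"),
#'                       sprintf("A%02d", 1:12))
#' @export
reverse_schedule <- function(time_points_s, pulse, wells,
                             horizon_s = max(time_points_s), plate = "96") {
  stopifnot(inherits(pulse, "stim_command"),
            length(time_points_s) == length(wells))
  time_points_s <- as.integer(time_points_s)
  if (any(time_points_s < pulse$duration_s)) {
    stop("every time point must be >= the pulse duration, ",
         "or the pulse would outlast the experiment")
  }
  if (any(time_points_s > horizon_s)) {
    stop("time point exceeds the horizon")
  }
  cmds <- lapply(seq_along(wells), function(k) {
    command(target = wells[k], start_s = horizon_s - time_points_s[k],
            duration_s = pulse$duration_s, color = pulse$color,
            repeats = pulse$repeats, interval_s = pulse$interval_s,
            message = pulse$message, buzzer = pulse$buzzer)
  })
  out <- stim_program(cmds, plate = plate, name = "staggered_schedule")
  attr(out, "endpoint_s") <- as.integer(horizon_s)
  out
}

#' Emulate device-side actions for a program
#'
#' Produces the chronological list of actions the device would perform:
#' `frame_change` at every second where the displayed grid differs from the
#' previous second, `message_show` when a command's message appears,
#' `countdown_tick` each second while the countdown runs (payload = seconds
#' remaining), and `buzzer` when a flagged countdown reaches zero. At equal
#' times, actions are ordered frame_change < message_show < countdown_tick <
#' buzzer.
#'
#' @param program A `stim_program`.
#' @param placement A `placement` (default: program's plate, default
#'   placement).
#' @param matrix A `matrix_spec`.
#' @param timeline Optional precompiled `frame_timeline`.
#' @return Data frame with columns `time_s`, `kind`, `payload`.
#' @export
emulate_program <- function(program, placement = NULL,
                            matrix = default_matrix(), timeline = NULL) {
  if (is.null(placement)) placement <- default_placement(program$plate, matrix)
  if (is.null(timeline)) {
    timeline <- build_timeline(expand_program(program, placement, matrix),
                               matrix)
  }
  actions <- list()
  add <- function(time_s, kind, payload) {
    actions[[length(actions) + 1L]] <<- data.frame(
      time_s = time_s, kind = kind, payload = payload)
  }

  lit <- sort(as.integer(names(timeline$frames)))
  candidates <- sort(unique(c(lit, lit + 1L)))
  candidates <- candidates[candidates <= timeline$horizon_s]
  prev <- NULL
  prev_t <- -1L
  for (t in candidates) {
    if (t - 1L != prev_t) prev <- NULL  # gap: previous second was all-off
    cur <- timeline$frames[[as.character(t)]]
    changed <- if (is.null(prev) && is.null(cur)) FALSE else
      if (is.null(prev) || is.null(cur)) TRUE else !identical(prev, cur)
    if (changed) add(t, "frame_change", sprintf("%d LEDs lit",
      if (is.null(cur)) 0L else sum(apply(cur > 0L, c(1, 2), any))))
    prev <- cur
    prev_t <- t
  }

  for (i in seq_along(program$commands)) {
    cm <- program$commands[[i]]
    if (is.null(cm$message)) next
    add(cm$start_s, "message_show", cm$message)
    for (s in seq_len(cm$duration_s)) {
      add(cm$start_s + s, "countdown_tick",
          as.character(cm$duration_s - s))
    }
    if (cm$buzzer) add(cm$start_s + cm$duration_s, "buzzer", cm$message)
  }

  if (length(actions) == 0L) {
    return(data.frame(time_s = integer(), kind = character(),
                      payload = character()))
  }
  out <- do.call(rbind, actions)
  kind_rank <- match(out$kind, c("frame_change", "message_show",
                                 "countdown_tick", "buzzer"))
  out <- out[order(out$time_s, kind_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
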