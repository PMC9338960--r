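#' Construct an illumination command
#'
#' One command is one row of an illumination program: a target, a start time,
#' a pulse duration, a color, optional repetition, and an optional operator
#' message with a countdown. Times are integer seconds; the minimal pulse
#' duration is 1 s (the device firmware's constraint). Commands with an
#' interval shorter than the duration (self-overlapping repeats) can be
#' constructed but are flagged by [validate_program()].
#'
#' @param target Target keyword (see [resolve_target()]); may be `""` for a
#'   message-only command.
#' @param start_s Start time, integer seconds >= 0.
#' @param duration_s Pulse duration, integer seconds >= 1. For a command with
#'   a message, also the countdown length.
#' @param color A color name or `(red, green, blue)` triple (see
#'   [as_color()]).
#' @param repeats Number of pulses, integer >= 1. Pulse `k` (0-based) starts
#'   at `start_s + k * interval_s`.
#' @param interval_s Pulse spacing in seconds; required when `repeats > 1`.
#' @param message Optional operator message shown with a countdown.
#' @param buzzer If `TRUE`, the buzzer sounds when the message countdown
#'   reaches zero.
#' @return An object of class `stim_command`.
#' @export
command <- function(target, start_s, duration_s, color = "blue",
                    repeats = 1L, interval_s = NA_integer_,
                    message = NULL, buzzer = FALSE) {
  check_time <- function(x, what, min) {
    if (length(x) != 1L || is.na(x) || !is.finite(x)) stop(what, " must be a single finite number")
    if (x != floor(x)) stop(what, " must be an integer number of seconds (sub-second times are rejected, not rounded)")
    if (x < min) {
      if (what == "duration_s" && min == 1) {
        stop("duration_s must be >= 1 s: the minimal pulse duration is 1 s")
      }
      stop(what, " must be >= ", min)
    }
    as.integer(x)
  }
  start_s <- check_time(start_s, "start_s", 0L)
  duration_s <- check_time(duration_s, "duration_s", 1L)
  repeats <- check_time(repeats, "repeats", 1L)
  if (repeats > 1L) {
    if (is.na(interval_s)) stop("interval_s is required when repeats > 1")
    interval_s <- check_time(interval_s, "interval_s", 1L)
  } else if (!is.na(interval_s)) {
    interval_s <- check_time(interval_s, "interval_s", 1L)
  }
  if (!is.null(message) && (!is.character(message) || length(message) != 1L)) {
    stop("message must be a single string or NULL")
  }
  target <- as.character(target)
  # canonical well spelling: "a2" / "A2" -> "A02"
  m <- regmatches(target, regexec("^([A-Za-z])([0-9]{1,2})$", target))[[1]]
  if (length(m) == 3L && !grepl("^[0-9]+$", target)) {
    target <- paste0(toupper(m[2]), sprintf("%02d", as.integer(m[3])))
  }
  structure(list(target = target, start_s = start_s,
                 duration_s = duration_s, color = as_color(color),
                 repeats = repeats, interval_s = as.integer(interval_s),
                 message = message, buzzer = isTRUE(buzzer)),
            class = "stim_command")
}

#' @export
print.stim_command <- function(x, ...) {
  rep_txt <- if (x$repeats > 1L) sprintf(" x%d every %ds", x$repeats, x$interval_s) else ""
  cat(sprintf("<command> %s @ %ds for %ds rgb(%d,%d,%d)%s%s\n",
              if (nzchar(x$target)) x$target else "<message only>",
              x$start_s, x$duration_s, x$color[1], x$color[2], x$color[3],
              rep_txt, if (!is.null(x$message)) paste0(" msg:", x$message) else ""))
  invisible(x)
}

#' Construct an illumination program
#'
#' @param commands List of [command()] objects.
#' @param plate Plate format name the program is written for.
#' @param name Program name (metadata).
#' @return An object of class `stim_program`.
#' @export
stim_program <- function(commands = list(), plate = "96", name = "program") {
  stopifnot(is.list(commands),
            all(vapply(commands, inherits, TRUE, "stim_command")))
  structure(list(commands = commands, plate = as.character(plate),
                 name = as.character(name)),
            class = "stim_program")
}

#' @export
print.stim_program <- function(x, ...) {
  cat(sprintf("<stim_program> '%s' (%s-well): %d commands, horizon %d s\n",
              x$name, x$plate, length(x$commands), program_horizon(x)))
  invisible(x)
}

#' Program horizon
#'
#' Last off-time over all commands (the end of the program), in seconds.
#' @param program A `stim_program`.
#' @return Integer seconds (0 for an empty program).
#' @export
program_horizon <- function(program) {
  if (length(program$commands) == 0L) return(0L)
  max(vapply(program$commands, function(cm) {
    last_start <- cm$start_s +
      (cm$repeats - 1L) * (if (is.na(cm$interval_s)) 0L else cm$interval_s)
    last_start + cm$duration_s
  }, integer(1)))
}

#' Validate a program against a placement
#'
#' Collects all findings rather than stopping at the first: unknown or empty
#' targets, self-overlapping repeats (interval shorter than duration),
#' messages scheduled past the program horizon, and placement-level findings
#' from [validate_placement()].
#'
#' @param program A `stim_program`.
#' @param placement A `placement`; default is the program's plate at its
#'   default placement.
#' @param matrix A `matrix_spec`.
#' @return Data frame of findings with columns `command` (index or NA),
#'   `issue`, `detail`; zero rows if the program is clean.
#' @export
validate_program <- function(program, placement = NULL,
                             matrix = default_matrix()) {
  if (is.null(placement)) placement <- default_placement(program$plate, matrix)
  findings <- list()
  add <- function(command, issue, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      command = command, issue = issue, detail = detail)
  }
  lit <- vapply(program$commands, function(cm) nzchar(cm$target), TRUE)
  lit_horizon <- if (any(lit)) {
    program_horizon(stim_program(program$commands[lit], program$plate))
  } else 0L
  for (i in seq_along(program$commands)) {
    cm <- program$commands[[i]]
    if (nzchar(cm$target)) {
      leds <- tryCatch(
        withCallingHandlers(
          resolve_target(cm$target, placement, matrix),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(leds, "error")) {
        add(i, "target", conditionMessage(leds))
      } else if (nrow(leds) == 0L) {
        add(i, "empty_target", sprintf("target '%s' addresses no LEDs", cm$target))
      }
    } else if (is.null(cm$message)) {
      add(i, "empty_target", "command has neither target nor message")
    }
    if (cm$repeats > 1L && !is.na(cm$interval_s) && cm$interval_s < cm$duration_s) {
      add(i, "self_overlap",
          sprintf("interval %d s < duration %d s: repeats of one command overlap",
                  cm$interval_s, cm$duration_s))
    }
    if (!is.null(cm$message) && lit_horizon > 0L && cm$start_s >= lit_horizon) {
      add(i, "message_out_of_horizon",
          sprintf("message at %d s starts at/after the illumination horizon (%d s)",
                  cm$start_s, lit_horizon))
    }
  }
  pf <- validate_placement(placement, matrix)
  if (nrow(pf) > 0L) {
    for (k in seq_len(nrow(pf))) {
      add(NA_integer_, paste0("placement_", pf$issue[k]),
          sprintf("well %s: %s", pf$well[k], pf$detail[k]))
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(command = integer(), issue = character(),
                      detail = character()))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
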