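#' @title The CSV program dialect
#' @description
#' An illumination program is a CSV file with one command per line. Columns
#' (header names are fixed; order is free; unknown columns are rejected):
#'
#' | column     | meaning                                                    |
#' |------------|------------------------------------------------------------|
#' | `target`   | target keyword (see [resolve_target()]); empty for a message-only row |
#' | `start`    | start time: integer seconds or `HH:MM:SS`                  |
#' | `duration` | pulse duration (and message countdown), >= 1 s             |
#' | `red`,`green`,`blue` | channel intensities 0-255 (missing column = 0)   |
#' | `repeats`  | number of pulses (default 1)                               |
#' | `interval` | pulse spacing, seconds or `HH:MM:SS`                       |
#' | `until`    | absolute end time; alternative to `repeats` — pulses start every `interval` while strictly before `until` (end-exclusive) |
#' | `message`  | operator message shown with a countdown of `duration` s    |
#' | `buzzer`   | 1/true to sound the buzzer when the countdown ends         |
#'
#' Lines beginning with `#` are comments; both `,` and `;` separate fields
#' (spreadsheet-locale tolerance); sub-second times are rejected, not rounded.
#' With `until`, the pulse count is `ceiling((until - start) / interval)`:
#' a pulse every 5 min until one hour gives 12 pulses (t = 0, 300, ..., 3300).
#' @name program-dialect
NULL

program_headers <- c("target", "start", "duration", "red", "green", "blue",
                     "repeats", "interval", "until", "message", "buzzer")

# "123" or "HH:MM:SS" -> integer seconds; context gives line/column for errors.
parse_time_s <- function(x, context) {
  x <- trimws(x)
  if (grepl("^[0-9]+$", x)) return(as.integer(x))
  m <- regmatches(x, regexec("^([0-9]{1,3}):([0-5]?[0-9]):([0-5]?[0-9])$", x))[[1]]
  if (length(m) == 4L) {
    return(as.integer(m[2]) * 3600L + as.integer(m[3]) * 60L + as.integer(m[4]))
  }
  if (grepl("^[0-9]*\\.[0-9]+$", x)) {
    stop(context, ": sub-second time '", x, "' rejected (times are integer seconds)")
  }
  stop(context, ": malformed time '", x, "' (use integer seconds or HH:MM:SS)")
}

#' Parse a CSV illumination program
#'
#' See the dialect description at [program-dialect]. Every parse error names
#' the offending line number and column.
#'
#' @param text CSV content as a single string or character vector of lines;
#'   alternatively use `file` to read from disk.
#' @param file Path to a CSV file (used when `text` is missing).
#' @param plate Plate format name recorded in the program metadata.
#' @param name Program name recorded in the metadata.
#' @return A `stim_program`.
#' @export
parse_program <- function(text, file = NULL, plate = "96", name = "program") {
  if (missing(text)) {
    if (is.null(file)) stop("either text or file must be given")
    text <- readLines(file, warn = FALSE, encoding = "UTF-8")
    if (is.null(name) || identical(name, "program")) {
      name <- sub("\\.[^.]*$", "", basename(file))
    }
  }
  if (length(text) == 1L) text <- strsplit(text, "\r?\n")[[1]]
  keep <- !grepl("^\\s*#", text)
  lines <- text[keep]
  line_no <- seq_along(text)[keep]
  nonblank <- grepl("[^[:space:],;]", lines)
  lines <- lines[nonblank]; line_no <- line_no[nonblank]
  if (length(lines) == 0L) stop("program has no header line")

  sep <- if (lengths(regmatches(lines[1], gregexpr(";", lines[1]))) >
             lengths(regmatches(lines[1], gregexpr(",", lines[1])))) ";" else ","
  split_row <- function(s) trimws(strsplit(s, sep, fixed = TRUE)[[1]])

  header <- tolower(split_row(lines[1]))
  unknown <- setdiff(header, program_headers)
  if (length(unknown) > 0L) {
    stop("line ", line_no[1], ": unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  required <- c("target", "start", "duration")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop("line ", line_no[1], ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  get <- function(fields, colname) {
    i <- match(colname, header)
    if (is.na(i) || i > length(fields)) "" else fields[i]
  }
  commands <- list()
  for (k in seq_along(lines)[-1]) {
    fields <- split_row(lines[k])
    ln <- line_no[k]
    ctx <- function(colname) sprintf("line %d, column '%s'", ln, colname)

    target <- get(fields, "target")
    start_s <- parse_time_s(get(fields, "start"), ctx("start"))
    dur_raw <- get(fields, "duration")
    if (grepl("^[0-9]*\\.[0-9]+$", dur_raw)) {
      dval <- as.numeric(dur_raw)
      if (dval < 1) {
        stop(ctx("duration"), ": duration ", dval,
             " s is below the 1 s minimal pulse duration")
      }
      stop(ctx("duration"), ": sub-second time '", dur_raw,
           "' rejected (times are integer seconds)")
    }
    duration_s <- parse_time_s(dur_raw, ctx("duration"))
    if (duration_s < 1L) {
      stop(ctx("duration"), ": duration ", duration_s,
           " s is below the 1 s minimal pulse duration")
    }

    chan <- function(colname) {
      v <- get(fields, colname)
      if (!nzchar(v)) return(0L)
      if (!grepl("^[0-9]+$", v)) {
        stop(ctx(colname), ": intensity '", v, "' is not a whole number")
      }
      v <- as.integer(v)
      if (v > 255L) {
        stop(ctx(colname), ": intensity ", v,
             " out of range 0-255 (256 levels)")
      }
      v
    }
    color <- c(chan("red"), chan("green"), chan("blue"))

    rep_raw <- get(fields, "repeats")
    until_raw <- get(fields, "until")
    int_raw <- get(fields, "interval")
    interval_s <- if (nzchar(int_raw)) parse_time_s(int_raw, ctx("interval")) else NA_integer_
    if (nzchar(rep_raw) && nzchar(until_raw)) {
      stop(ctx("until"), ": give either repeats or until, not both")
    }
    if (nzchar(until_raw)) {
      until_s <- parse_time_s(until_raw, ctx("until"))
      if (is.na(interval_s)) {
        stop(ctx("interval"), ": until requires an interval")
      }
      if (until_s <= start_s) {
        stop(ctx("until"), ": until (", until_s, " s) must be after start (",
             start_s, " s)")
      }
      repeats <- as.integer(ceiling((until_s - start_s) / interval_s))
    } else if (nzchar(rep_raw)) {
      if (!grepl("^[0-9]+$", rep_raw)) {
        stop(ctx("repeats"), ": '", rep_raw, "' is not a whole number")
      }
      repeats <- as.integer(rep_raw)
      if (repeats < 1L) stop(ctx("repeats"), ": repeats must be >= 1")
    } else {
      repeats <- 1L
    }
    if (repeats > 1L && is.na(interval_s)) {
      stop(ctx("interval"), ": interval is required when repeating")
    }

    msg <- get(fields, "message")
    buz_raw <- tolower(get(fields, "buzzer"))
    buzzer <- buz_raw %in% c("1", "true", "yes")
    if (nzchar(buz_raw) && !buzzer && !buz_raw %in% c("0", "false", "no")) {
      stop(ctx("buzzer"), ": '", buz_raw, "' is not a flag (use 1/0)")
    }
    if (!nzchar(target) && !nzchar(msg)) {
      stop(ctx("target"), ": row has neither a target nor a message")
    }

    cm <- tryCatch(
      command(target = target, start_s = start_s, duration_s = duration_s,
              color = color, repeats = repeats, interval_s = interval_s,
              message = if (nzchar(msg)) msg else NULL, buzzer = buzzer),
      error = function(e) stop("line ", ln, ": ", conditionMessage(e),
                               call. = FALSE))
    commands[[length(commands) + 1L]] <- cm
  }
  stim_program(commands, plate = plate, name = name)
}

#' Serialize a program to CSV
#'
#' Inverse of [parse_program()]: `parse_program(serialize_program(p))` is
#' semantically identical to `p` (loop counts are written as explicit
#' `repeats`).
#'
#' @param program A `stim_program`.
#' @param file Optional path; when given the CSV is written there.
#' @return The CSV content as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
serialize_program <- function(program, file = NULL) {
  stopifnot(inherits(program, "stim_program"))
  header <- paste(program_headers[program_headers != "until"], collapse = ",")
  rows <- vapply(program$commands, function(cm) {
    paste(c(cm$target, cm$start_s, cm$duration_s,
            cm$color[1], cm$color[2], cm$color[3],
            cm$repeats,
            if (is.na(cm$interval_s)) "" else cm$interval_s,
            if (is.null(cm$message)) "" else cm$message,
            if (cm$buzzer) "1" else ""),
          collapse = ",")
  }, character(1))
  out <- c(header, rows)
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Export a parsed program as JSON
#'
#' Machine-readable form of the program for downstream tools.
#' @param program A `stim_program`.
#' @param file Optional output path.
#' @return JSON string (invisibly when `file` is given).
#' @export
program_to_json <- function(program, file = NULL) {
  x <- list(
    name = program$name, plate = program$plate,
    commands = lapply(program$commands, function(cm) {
      list(target = cm$target, start_s = cm$start_s,
           duration_s = cm$duration_s, color = as.list(cm$color),
           repeats = cm$repeats,
           interval_s = if (is.na(cm$interval_s)) NULL else cm$interval_s,
           message = cm$message, buzzer = cm$buzzer)
    }))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Semantic equality of two programs
#'
#' Compares plate, and per command: target, timing, color, repetition,
#' message and buzzer flag. Used to verify serialization round-trips.
#' @param a,b `stim_program` objects.
#' @return `TRUE` or `FALSE`.
#' @export
programs_equal <- function(a, b) {
  if (!identical(a$plate, b$plate)) return(FALSE)
  if (length(a$commands) != length(b$commands)) return(FALSE)
  for (i in seq_along(a$commands)) {
    x <- a$commands[[i]]; y <- b$commands[[i]]
    same_interval <- (is.na(x$interval_s) && is.na(y$interval_s)) ||
      (x$repeats == 1L && y$repeats == 1L) ||
      identical(x$interval_s, y$interval_s)
    if (!(identical(x$target, y$target) &&
          identical(x$start_s, y$start_s) &&
          identical(x$duration_s, y$duration_s) &&
          identical(unname(x$color), unname(y$color)) &&
          identical(x$repeats, y$repeats) && same_interval &&
          identical(x$message, y$message) &&
          identical(x$buzzer, y$buzzer))) return(FALSE)
  }
  TRUE
}
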