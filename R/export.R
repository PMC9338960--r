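#' Export a timeline as a JSON event list
#'
#' Writes the compiled events (one object per event: LED coordinates,
#' half-open on/off times, color, source command index).
#'
#' @param events Event list from [expand_program()].
#' @param file Output path (or `NULL` to return the JSON string).
#' @return JSON string, invisibly when written to a file.
#' @export
write_events_json <- function(events, file = NULL) {
  x <- lapply(events, function(ev) {
    list(t_on_s = ev$t_on_s, t_off_s = ev$t_off_s,
         color = as.list(ev$color), source_command = ev$source_command,
         leds = unname(apply(as.data.frame(ev$led), 1L, as.list)))
  })
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Export a timeline as a sparse per-second CSV
#'
#' One row per lit (second, LED): columns `t, row, col, red, green, blue`.
#'
#' @param timeline A `frame_timeline`.
#' @param path Output CSV path.
#' @export
write_timeline_csv <- function(timeline, path) {
  rows <- list()
  for (key in names(timeline$frames)) {
    fr <- timeline$frames[[key]]
    lit <- which(fr[, , 1] > 0L | fr[, , 2] > 0L | fr[, , 3] > 0L,
                 arr.ind = TRUE)
    if (nrow(lit) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      t = as.integer(key), row = lit[, 1] - 1L, col = lit[, 2] - 1L,
      red = fr[cbind(lit, 1L)], green = fr[cbind(lit, 2L)],
      blue = fr[cbind(lit, 3L)])
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(t = integer(), row = integer(), col = integer(),
               red = integer(), green = integer(), blue = integer())
  out <- out[order(out$t, out$row, out$col), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a frame as a PNG snapshot
#'
#' Writes the `n_rows x n_cols x 3` intensity grid as an RGB image, one pixel
#' per LED (optionally upscaled by an integer factor).
#'
#' @param frame Intensity array (e.g. from [timeline_frame()]).
#' @param path Output PNG path.
#' @param scale Integer pixel upscaling factor.
#' @export
write_frame_png <- function(frame, path, scale = 4L) {
  img <- frame / 255
  if (scale > 1L) {
    img <- img[rep(seq_len(dim(img)[1]), each = scale),
               rep(seq_len(dim(img)[2]), each = scale), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Save an irradiance field as CSV and/or PNG heatmap
#'
#' The CSV holds the channel-summed irradiance matrix (rows = y, columns =
#' x, cell centers in the header); the PNG is a grayscale heatmap normalized
#' to the field peak.
#'
#' @param field An `irradiance_field`.
#' @param csv,png Output paths (`NULL` to skip either).
#' @export
write_field <- function(field, csv = NULL, png = NULL) {
  z <- field_total(field)
  if (!is.null(csv)) {
    df <- as.data.frame(z)
    names(df) <- sprintf("x%.3f", field$x_mm)
    df <- cbind(data.frame(y_mm = field$y_mm), df)
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(png)) {
    peak <- max(z)
    img <- if (peak > 0) z / peak else z
    png::writePNG(img, png)
  }
  invisible(field)
}

#' Plain-text animation preview of a timeline
#'
#' Renders selected seconds of a timeline as character plate maps.
#'
#' @param timeline A `frame_timeline`.
#' @param seconds Seconds to render; default the first lit second.
#' @param matrix A `matrix_spec`.
#' @return Character vector of preview lines.
#' @export
preview_text <- function(timeline, seconds = NULL,
                         matrix = default_matrix()) {
  if (is.null(seconds)) {
    lit <- as.integer(names(timeline$frames))
    seconds <- if (length(lit) > 0L) min(lit) else 0L
  }
  out <- character()
  for (t in seconds) {
    fr <- timeline_frame(timeline, t, matrix)
    on <- fr[, , 1] > 0L | fr[, , 2] > 0L | fr[, , 3] > 0L
    leds <- which(on, arr.ind = TRUE)
    ls <- led_set(leds[, 1] - 1L, leds[, 2] - 1L, matrix)
    out <- c(out, sprintf("t = %d s", t), plate_map_text(ls, matrix), "")
  }
  out
}
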