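#' Construct a set of LED coordinates
#'
#' An `led_set` is a set (no duplicates) of 0-based (row, col) LED indices,
#' row-major from the matrix top-left. Stored as a sorted two-column data
#' frame.
#'
#' @param row,col Integer vectors of equal length, 0-based.
#' @param matrix A `matrix_spec` for bounds checking.
#' @return An object of class `led_set` (a data frame with columns `row`,
#'   `col`).
#' @export
led_set <- function(row = integer(), col = integer(),
                    matrix = default_matrix()) {
  row <- as.integer(row); col <- as.integer(col)
  stopifnot(length(row) == length(col))
  if (any(row < 0L | row >= matrix$n_rows | col < 0L | col >= matrix$n_cols)) {
    stop("LED coordinate out of matrix bounds")
  }
  df <- unique(data.frame(row = row, col = col))
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("led_set", "data.frame")
  df
}

#' @export
print.led_set <- function(x, ...) {
  cat(sprintf("<led_set> %d LEDs\n", nrow(x)))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

led_union <- function(...) {
  parts <- list(...)
  df <- unique(do.call(rbind, lapply(parts, as.data.frame)))
  if (is.null(df)) df <- data.frame(row = integer(), col = integer())
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("led_set", "data.frame")
  df
}

# LEDs of the full matrix as a data.frame of 0-based indices with centers;
# memoized per lattice geometry (hot path of target resolution).
.led_grid_cache <- new.env(parent = emptyenv())
led_grid <- function(matrix) {
  key <- paste(matrix$n_rows, matrix$n_cols, matrix$pitch_mm)
  g <- .led_grid_cache[[key]]
  if (is.null(g)) {
    g <- expand.grid(row = seq_len(matrix$n_rows) - 1L,
                     col = seq_len(matrix$n_cols) - 1L)
    ctr <- led_center(matrix, g$row, g$col)
    g$x <- ctr[, 1]; g$y <- ctr[, 2]
    .led_grid_cache[[key]] <- g
  }
  g
}

# LEDs whose centers lie strictly within `radius` of `center` (x, y mm).
# `clip = FALSE` counts lattice points on the infinite lattice (used to
# detect boundary truncation).
leds_within_circle <- function(center, radius, matrix, clip = TRUE) {
  if (clip) {
    g <- led_grid(matrix)
    keep <- (g$x - center[1])^2 + (g$y - center[2])^2 < radius^2
    led_set(g$row[keep], g$col[keep], matrix)
  } else {
    p <- matrix$pitch_mm
    cols <- seq(floor((center[1] - radius) / p - 1), ceiling((center[1] + radius) / p + 1))
    rows <- seq(floor((center[2] - radius) / p - 1), ceiling((center[2] + radius) / p + 1))
    g <- expand.grid(row = rows, col = cols)
    x <- p * g$col + p / 2; y <- p * g$row + p / 2
    sum((x - center[1])^2 + (y - center[2])^2 < radius^2)
  }
}

#' Resolve a target keyword to LED coordinates
#'
#' Translates the program dialect's target keywords into the set of matrix
#' LEDs they address:
#' \describe{
#'   \item{`"A2"` / `"A02"`}{one well — every LED whose center lies strictly
#'     within the well radius of the (snapped) well center.}
#'   \item{`"D"`}{a whole well row (union of its wells).}
#'   \item{`"3"`}{a whole well column.}
#'   \item{`"Plate"`}{all wells of the placed plate.}
#'   \item{`"Whole"`}{every LED of the matrix.}
#'   \item{`"Rec_A1_D4"`}{all wells in the rectangle spanned by two corner
#'     addresses.}
#'   \item{`"Cir_x_y_r"`}{LEDs within `r` mm of the point (`x`, `y`) mm.}
#'   \item{`"Led_r_c"` (or `"Led_r_c|r_c|..."`)}{explicit 0-based LED
#'     coordinates.}
#' }
#' A target that resolves to no LEDs returns an empty set with a warning, not
#' silently.
#'
#' @param target Target keyword string.
#' @param placement A `placement` (ignored for `"Whole"`, `Cir`, `Led`).
#' @param matrix A `matrix_spec`.
#' @return An `led_set`.
#' @examples
#' nrow(resolve_target("A01", default_placement("96")))  # 4
#' @export
resolve_target <- function(target, placement = NULL, matrix = default_matrix()) {
  target <- trimws(target)
  out <- NULL

  if (toupper(target) == "WHOLE") {
    g <- led_grid(matrix)
    out <- led_set(g$row, g$col, matrix)
  } else if (grepl("^Led_", target)) {
    pairs <- strsplit(strsplit(sub("^Led_", "", target), "\\|")[[1]], "_")
    bad <- vapply(pairs, function(p) length(p) != 2L || anyNA(suppressWarnings(as.integer(p))), TRUE)
    if (any(bad)) stop("cannot parse LED-list target '", target, "'")
    rc <- do.call(rbind, lapply(pairs, as.integer))
    out <- led_set(rc[, 1], rc[, 2], matrix)
  } else if (grepl("^Cir_", target)) {
    parts <- suppressWarnings(as.numeric(strsplit(sub("^Cir_", "", target), "_")[[1]]))
    if (length(parts) != 3L || anyNA(parts)) {
      stop("cannot parse circle target '", target, "': expected Cir_x_y_r (mm)")
    }
    out <- leds_within_circle(parts[1:2], parts[3], matrix)
  } else {
    if (is.null(placement)) stop("target '", target, "' requires a placement")
    plate <- placement$plate
    resolve_well <- function(address) {
      wg <- well_geometry(placement, address, matrix)
      leds_within_circle(wg$center_mm, wg$radius_mm, matrix)
    }
    if (toupper(target) == "PLATE") {
      out <- do.call(led_union, lapply(well_addresses(plate), resolve_well))
    } else if (grepl("^Rec_", target, ignore.case = TRUE)) {
      corners <- strsplit(sub("^Rec_", "", target, ignore.case = TRUE), "_")[[1]]
      if (length(corners) != 2L) {
        stop("cannot parse rectangle target '", target, "': expected Rec_A1_D4")
      }
      a <- parse_well_address(corners[1], plate)
      b <- parse_well_address(corners[2], plate)
      rows <- seq(min(a["row"], b["row"]), max(a["row"], b["row"]))
      cols <- seq(min(a["col"], b["col"]), max(a["col"], b["col"]))
      addrs <- as.vector(outer(LETTERS[rows + 1L], cols + 1L,
                               function(r, c) paste0(r, sprintf("%02d", c))))
      out <- do.call(led_union, lapply(addrs, resolve_well))
    } else if (grepl("^[A-Za-z]$", target)) {
      r <- match(toupper(target), LETTERS)
      if (r > plate$n_well_rows) {
        stop("row '", target, "' does not exist on the ", plate$name,
             "-well format")
      }
      addrs <- paste0(toupper(target), sprintf("%02d", seq_len(plate$n_well_cols)))
      out <- do.call(led_union, lapply(addrs, resolve_well))
    } else if (grepl("^[0-9]{1,2}$", target)) {
      cnum <- as.integer(target)
      if (cnum < 1L || cnum > plate$n_well_cols) {
        stop("column '", target, "' does not exist on the ", plate$name,
             "-well format")
      }
      addrs <- paste0(LETTERS[seq_len(plate$n_well_rows)], sprintf("%02d", cnum))
      out <- do.call(led_union, lapply(addrs, resolve_well))
    } else if (grepl("^[A-Za-z][0-9]{1,2}$", target)) {
      out <- resolve_well(target)
    } else {
      stop("unknown target keyword '", target, "'")
    }
  }

  if (nrow(out) == 0L) {
    warning("target '", target, "' resolves to an empty LED set")
  }
  out
}

#' Validate plate placements against the matrix
#'
#' Reports, per placement, any well whose resolved LED set is empty or
#' truncated by the matrix boundary, and any LED claimed by wells of two
#' different placements.
#'
#' @param placements A `placement` or list of placements.
#' @param matrix A `matrix_spec`.
#' @return A data frame of findings with columns `placement`, `well`, `issue`,
#'   `detail` (zero rows when the layout is clean).
#' @export
validate_placement <- function(placements, matrix = default_matrix()) {
  if (inherits(placements, "placement")) placements <- list(placements)
  findings <- list()
  claimed <- list()  # per placement: data.frame(row, col, well)
  for (i in seq_along(placements)) {
    pl <- placements[[i]]
    claim <- data.frame(row = integer(), col = integer(), well = character())
    for (w in well_addresses(pl$plate)) {
      wg <- well_geometry(pl, w, matrix)
      leds <- leds_within_circle(wg$center_mm, wg$radius_mm, matrix)
      full <- leds_within_circle(wg$center_mm, wg$radius_mm, matrix, clip = FALSE)
      if (nrow(leds) == 0L) {
        findings[[length(findings) + 1L]] <- data.frame(
          placement = i, well = w, issue = "empty",
          detail = "no LED center falls inside the well")
      } else if (nrow(leds) < full) {
        findings[[length(findings) + 1L]] <- data.frame(
          placement = i, well = w, issue = "truncated",
          detail = sprintf("%d of %d LEDs fall outside the matrix",
                           full - nrow(leds), full))
      }
      if (nrow(leds) > 0L) {
        claim <- rbind(claim, data.frame(row = leds$row, col = leds$col, well = w))
      }
    }
    claimed[[i]] <- claim
  }
  if (length(placements) > 1L) {
    for (i in seq_along(placements)) for (j in seq_along(placements)) {
      if (j <= i) next
      ov <- merge(claimed[[i]], claimed[[j]], by = c("row", "col"))
      if (nrow(ov) > 0L) {
        findings[[length(findings) + 1L]] <- data.frame(
          placement = i, well = paste(unique(ov$well.x), collapse = ","),
          issue = "overlap",
          detail = sprintf("%d LEDs shared with placement %d", nrow(ov), j))
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(placement = integer(), well = character(),
                      issue = character(), detail = character()))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Reference outline of a placed plate
#'
#' Perimeter LEDs of the bounding rectangle of the plate's resolved well LEDs,
#' for displaying an alignment outline on the matrix before an experiment.
#'
#' @param placement A `placement`.
#' @param matrix A `matrix_spec`.
#' @return An `led_set` (empty for a plate with no resolvable wells).
#' @export
outline_set <- function(placement, matrix = default_matrix()) {
  all_leds <- suppressWarnings(resolve_target("Plate", placement, matrix))
  if (nrow(all_leds) == 0L) return(led_set(matrix = matrix))
  r0 <- min(all_leds$row); r1 <- max(all_leds$row)
  c0 <- min(all_leds$col); c1 <- max(all_leds$col)
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- g$row %in% c(r0, r1) | g$col %in% c(c0, c1)
  led_set(g$row[keep], g$col[keep], matrix)
}

#' Export an LED set as CSV
#'
#' Writes 0-based `row,col` pairs, one LED per line.
#' @param leds An `led_set`.
#' @param path Output file path.
#' @export
write_led_csv <- function(leds, path) {
  utils::write.csv(as.data.frame(leds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plain-text plate map of an LED set
#'
#' Renders the matrix as character rows, `#` for LEDs in the set and `.`
#' otherwise — a quick visual check of what a target resolves to.
#'
#' @param leds An `led_set`.
#' @param matrix A `matrix_spec`.
#' @return Character vector, one string per matrix row.
#' @export
plate_map_text <- function(leds, matrix = default_matrix()) {
  grid <- base::matrix(".", matrix$n_rows, matrix$n_cols)
  if (nrow(leds) > 0L) grid[cbind(leds$row + 1L, leds$col + 1L)] <- "#"
  apply(grid, 1L, paste, collapse = "")
}
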