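#' Plate format registry
#'
#' Well-array geometry of the supported labware formats. The 96-well entry
#' (9 mm pitch, 6.38 mm well diameter) is anchored to the reference hardware's
#' plate; the remaining multiwell entries follow ANSI/SLAS footprint
#' conventions, and the 100 mm dish entry uses its nominal growth-area
#' diameter. All entries can be overridden via a YAML registry file
#' (see [load_plate_registry()]).
#'
#' @return A data frame with columns `name`, `n_well_rows`, `n_well_cols`,
#'   `well_pitch_mm`, `well_diameter_mm`, `geometry_kind`.
#' @export
plate_registry <- function() {
  data.frame(
    name = c("6", "12", "24", "48", "96", "dish100"),
    n_well_rows = c(2L, 3L, 4L, 6L, 8L, 1L),
    n_well_cols = c(3L, 4L, 6L, 8L, 12L, 1L),
    well_pitch_mm = c(39.12, 26.0, 19.3, 13.0, 9.0, 86.0),
    well_diameter_mm = c(34.8, 22.1, 15.6, 11.0, 6.38, 86.0),
    geometry_kind = c(rep("circular_well", 5L), "dish"),
    stringsAsFactors = FALSE
  )
}

#' Load a plate registry from a YAML file
#'
#' The file holds a list of format entries with the same fields as
#' [plate_registry()]. Entries replace or extend the built-in registry.
#'
#' @param path Path to a YAML registry file.
#' @return A registry data frame.
#' @export
load_plate_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  reg <- plate_registry()
  for (e in entries) {
    row <- data.frame(name = as.character(e$name),
                      n_well_rows = as.integer(e$n_well_rows),
                      n_well_cols = as.integer(e$n_well_cols),
                      well_pitch_mm = as.numeric(e$well_pitch_mm),
                      well_diameter_mm = as.numeric(e$well_diameter_mm),
                      geometry_kind = as.character(e$geometry_kind),
                      stringsAsFactors = FALSE)
    reg <- rbind(reg[reg$name != row$name, , drop = FALSE], row)
  }
  reg
}

#' Look up a plate format
#'
#' @param name Format name (e.g. `"96"`, `"6"`, `"dish100"`).
#' @param registry Registry data frame, default [plate_registry()].
#' @return An object of class `plate_format`.
#' @export
plate_format <- function(name, registry = plate_registry()) {
  if (inherits(name, "plate_format")) return(name)
  i <- match(as.character(name), registry$name)
  if (is.na(i)) {
    stop("unknown plate format '", name, "'; registry has: ",
         paste(registry$name, collapse = ", "))
  }
  row <- registry[i, ]
  if (row$geometry_kind == "circular_well" &&
      !(row$well_pitch_mm >= row$well_diameter_mm && row$well_diameter_mm > 0)) {
    stop("invalid format geometry: need pitch >= diameter > 0")
  }
  structure(as.list(row), class = "plate_format")
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf("<plate_format> %s: %d x %d wells, pitch %.3g mm, diameter %.3g mm\n",
              x$name, x$n_well_rows, x$n_well_cols, x$well_pitch_mm,
              x$well_diameter_mm))
  invisible(x)
}

#' Placement of a plate on the matrix
#'
#' A placement fixes where well A1's center sits relative to the matrix
#' top-left corner and whether well centers snap to the LED sub-lattice.
#' With `per_well_snap` (the default) each well center is moved to the nearest
#' point whose coordinates are both multiples of the LED pitch — a midpoint of
#' a 2x2 LED cell — so every well of a format receives a congruent LED
#' pattern even when the well pitch is not a multiple of the LED pitch.
#' `rigid` keeps nominal centers, for physical-fidelity simulation.
#'
#' @param plate A `plate_format` or format name.
#' @param origin_offset_mm Length-2 numeric, (x, y) of well A1's center in mm
#'   from the matrix top-left corner.
#' @param snap_mode `"per_well_snap"` or `"rigid"`.
#' @param registry Plate registry used when `plate` is a name.
#' @return An object of class `placement`.
#' @export
placement <- function(plate, origin_offset_mm, snap_mode = "per_well_snap",
                      registry = plate_registry()) {
  plate <- plate_format(plate, registry)
  origin_offset_mm <- as.numeric(origin_offset_mm)
  stopifnot(length(origin_offset_mm) == 2L, all(is.finite(origin_offset_mm)))
  snap_mode <- match.arg(snap_mode, c("per_well_snap", "rigid"))
  structure(list(plate = plate, origin_offset_mm = origin_offset_mm,
                 snap_mode = snap_mode),
            class = "placement")
}

#' Default placement of a format on the matrix
#'
#' Aligns the plate to the matrix top-left corner: well A1's center is put at
#' the 2x2-cell midpoint nearest to half a well diameter from the corner in
#' each axis. For the 96-well format this yields A1 at (3, 3) mm and the
#' characteristic 2x2 LED block centered in every well.
#'
#' @inheritParams placement
#' @param matrix A `matrix_spec`.
#' @return A `placement`.
#' @examples
#' default_placement("96")$origin_offset_mm  # c(3, 3)
#' @export
default_placement <- function(plate, matrix = default_matrix(),
                              snap_mode = "per_well_snap",
                              registry = plate_registry()) {
  plate <- plate_format(plate, registry)
  half <- plate$well_diameter_mm / 2
  origin <- floor(half / matrix$pitch_mm + 0.5) * matrix$pitch_mm
  placement(plate, c(origin, origin), snap_mode, registry)
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %s-well at A1 = (%.3g, %.3g) mm, %s\n",
              x$plate$name, x$origin_offset_mm[1], x$origin_offset_mm[2],
              x$snap_mode))
  invisible(x)
}

# Parse a well address like "A2" / "A02" into 0-based (row, col) for a format.
parse_well_address <- function(address, plate) {
  m <- regmatches(address, regexec("^([A-Za-z])([0-9]{1,2})$", address))[[1]]
  if (length(m) != 3L) {
    stop("malformed well address '", address,
         "': expected letter + 1-2 digits (e.g. 'A2' or 'A02')")
  }
  row <- match(toupper(m[2]), LETTERS) - 1L
  col <- as.integer(m[3]) - 1L
  if (row >= plate$n_well_rows || col < 0L || col >= plate$n_well_cols) {
    stop("well '", address, "' does not exist on the ", plate$name,
         "-well format (", plate$n_well_rows, " x ", plate$n_well_cols, ")")
  }
  c(row = row, col = col)
}

#' All well addresses of a format
#'
#' @param plate A `plate_format` or name.
#' @return Character vector in row-major order ("A01", "A02", ...).
#' @export
well_addresses <- function(plate) {
  plate <- plate_format(plate)
  as.vector(t(outer(LETTERS[seq_len(plate$n_well_rows)],
                    sprintf("%02d", seq_len(plate$n_well_cols)), paste0)))
}

#' Physical center of a well
#'
#' The nominal center is `origin + (col * pitch, row * pitch)` (0-based well
#' indices). Under `per_well_snap` it is snapped to the nearest point with both
#' coordinates multiples of the LED pitch (a 2x2 LED-cell midpoint); the snap
#' displacement is at most half a pitch per axis.
#'
#' @param placement A `placement`.
#' @param address Well address ("A2" / "A02").
#' @param matrix A `matrix_spec` (supplies the snap lattice pitch).
#' @return Named numeric `c(x_mm =, y_mm =)`.
#' @examples
#' well_center(default_placement("96"), "A01")  # (3, 3)
#' @export
well_center <- function(placement, address, matrix = default_matrix()) {
  stopifnot(inherits(placement, "placement"))
  rc <- parse_well_address(address, placement$plate)
  nominal <- c(placement$origin_offset_mm[1] + rc["col"] * placement$plate$well_pitch_mm,
               placement$origin_offset_mm[2] + rc["row"] * placement$plate$well_pitch_mm)
  if (placement$snap_mode == "per_well_snap") {
    nominal <- floor(nominal / matrix$pitch_mm + 0.5) * matrix$pitch_mm
  }
  names(nominal) <- c("x_mm", "y_mm")
  nominal
}

#' Circular footprint of a well
#'
#' @inheritParams well_center
#' @return List with `center_mm` (x, y) and `radius_mm`.
#' @export
well_geometry <- function(placement, address, matrix = default_matrix()) {
  list(center_mm = unname(well_center(placement, address, matrix)),
       radius_mm = placement$plate$well_diameter_mm / 2)
}
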