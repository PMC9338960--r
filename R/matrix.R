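#' LED matrix specification
#'
#' Describes the physical LED lattice: a grid of RGB LEDs on a regular pitch,
#' with a fixed intensity depth per channel and a per-channel maximum power
#' density at the calibration plane. The default corresponds to a 32 x 64 RGB
#' matrix with a 3 mm pitch, 256 intensity levels per channel and a measured
#' maximum blue power density of 135 uW/cm2; red and green maxima are left
#' unknown (`NA`) because only blue is calibrated on the reference hardware.
#'
#' @param n_rows,n_cols Lattice dimensions (LEDs).
#' @param pitch_mm Center-to-center LED spacing in mm.
#' @param channels Ordered color channel names.
#' @param intensity_levels Number of representable intensity levels per channel
#'   (levels `0 .. intensity_levels - 1`).
#' @param max_power_uW_cm2 Named per-channel maximum power density (uW/cm2) at
#'   full intensity; `NA` for uncalibrated channels.
#' @param peak_wavelength_nm Named list of per-channel peak emission ranges (nm).
#' @return An object of class `matrix_spec`.
#' @examples
#' m <- matrix_spec()
#' m$n_rows * m$n_cols  # 2048
#' @export
matrix_spec <- function(n_rows = 32L, n_cols = 64L, pitch_mm = 3.0,
                        channels = c("red", "green", "blue"),
                        intensity_levels = 256L,
                        max_power_uW_cm2 = c(red = NA_real_, green = NA_real_,
                                             blue = 135.0),
                        peak_wavelength_nm = list(red = c(620, 630),
                                                  green = c(520, 525),
                                                  blue = c(465, 470))) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, pitch_mm > 0,
            length(channels) >= 1L, intensity_levels >= 2L)
  if (!all(is.na(max_power_uW_cm2) | max_power_uW_cm2 >= 0)) {
    stop("max_power_uW_cm2 must be >= 0 where given")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
                 channels = channels,
                 intensity_levels = as.integer(intensity_levels),
                 max_power_uW_cm2 = max_power_uW_cm2,
                 peak_wavelength_nm = peak_wavelength_nm),
            class = "matrix_spec")
}

#' Default LED matrix
#'
#' The 32 x 64, 3 mm-pitch RGB matrix with 256 intensity levels.
#' @return A `matrix_spec`.
#' @export
default_matrix <- function() matrix_spec()

#' @export
print.matrix_spec <- function(x, ...) {
  cat(sprintf("<matrix_spec> %d x %d LEDs, %.3g mm pitch, %d levels/channel\n",
              x$n_rows, x$n_cols, x$pitch_mm, x$intensity_levels))
  invisible(x)
}

#' Physical center of an LED
#'
#' LED indices are 0-based, row-major from the top-left corner of the matrix;
#' physical coordinates are in mm from that same corner, x along columns and
#' y along rows. The LED at (0, 0) is centered half a pitch in from the corner.
#'
#' @param matrix A `matrix_spec`.
#' @param row,col 0-based LED indices (vectorized).
#' @return A two-column matrix `cbind(x_mm, y_mm)`.
#' @examples
#' led_center(default_matrix(), 0, 0)  # (1.5, 1.5)
#' @export
led_center <- function(matrix, row, col) {
  stopifnot(inherits(matrix, "matrix_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= matrix$n_rows | col < 0L | col >= matrix$n_cols)) {
    stop("LED index out of bounds for ", matrix$n_rows, " x ", matrix$n_cols,
         " matrix")
  }
  cbind(x_mm = matrix$pitch_mm * col + matrix$pitch_mm / 2,
        y_mm = matrix$pitch_mm * row + matrix$pitch_mm / 2)
}

#' RGB color triple
#'
#' Per-channel intensities are integers in `[0, 255]` (256 levels). Named
#' shortcuts: `"red"`, `"green"`, `"blue"`, `"white"`, `"off"`.
#'
#' @param x Either a length-3 numeric vector `(red, green, blue)` or a color
#'   name.
#' @return Named integer vector `c(red =, green =, blue =)`.
#' @examples
#' as_color("blue")        # 0, 0, 255
#' as_color(c(10, 0, 128))
#' @export
as_color <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    shortcuts <- list(red = c(255, 0, 0), green = c(0, 255, 0),
                      blue = c(0, 0, 255), white = c(255, 255, 255),
                      off = c(0, 0, 0))
    if (!x %in% names(shortcuts)) stop("unknown color name: ", x)
    x <- shortcuts[[x]]
  }
  if (length(x) != 3L || any(is.na(x))) {
    stop("color must be a name or 3 intensities (red, green, blue)")
  }
  if (any(x != floor(x))) stop("color intensities must be integers")
  x <- as.integer(x)
  if (any(x < 0L | x > 255L)) {
    stop("color intensity out of range: levels are 0..255 (256 levels)")
  }
  names(x) <- c("red", "green", "blue")
  x
}
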