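#' Generalized-Lambertian emission model
#'
#' Each LED is modelled as a point emitter with angular intensity
#' proportional to `cos^m(theta)`; the irradiance it delivers to a parallel
#' sample plane at height `h` and lateral offset `r` is
#' \deqn{E(r, h) = S \, h^{m+1} / (r^2 + h^2)^{(m+3)/2}}
#' where `S` is fixed per channel so that one full-intensity LED delivers the
#' calibrated power density on-axis at the calibration height. The default
#' calibration is the measured blue maximum of 135 uW/cm2 at 2 mm — the
#' sample height of a standard 96-well plate bottom; red and green are left
#' uncalibrated (`NA`) and contribute nothing to physical fields.
#'
#' The exponent `m` controls beam concentration (`m = 0` is an isotropic
#' point source). It is a free parameter of the model — the reference
#' hardware characterizes its field empirically and states no emitter
#' profile — and can be fitted to a homogeneity target with
#' [calibrate_emission()].
#'
#' @param exponent_m Angular order `m >= 0`.
#' @param calib_power_uW_cm2 Named per-channel on-axis power density at full
#'   intensity at the calibration height (uW/cm2); `NA` = uncalibrated.
#' @param calib_height_mm Calibration height (mm).
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(exponent_m = 1,
                           calib_power_uW_cm2 = c(red = NA_real_,
                                                  green = NA_real_,
                                                  blue = 135.0),
                           calib_height_mm = 2.0) {
  stopifnot(exponent_m >= 0, calib_height_mm > 0)
  if (!any(!is.na(calib_power_uW_cm2) & calib_power_uW_cm2 > 0)) {
    stop("at least one channel must have a positive calibration power")
  }
  structure(list(exponent_m = exponent_m,
                 calib_power_uW_cm2 = calib_power_uW_cm2,
                 calib_height_mm = calib_height_mm),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf("<emission_model> m = %.4g, calib %s uW/cm2 at %.3g mm\n",
              x$exponent_m,
              paste(names(x$calib_power_uW_cm2), x$calib_power_uW_cm2,
                    sep = "=", collapse = " "),
              x$calib_height_mm))
  invisible(x)
}

# Single-LED irradiance at lateral offset r (mm) and height h (mm), for a
# channel calibrated to `calib` on-axis at `calib_h`.
led_irradiance <- function(r2, h, m, calib, calib_h) {
  s <- calib * calib_h^2          # E(0, h) = S / h^2  =>  S = calib * calib_h^2
  s * h^(m + 1) / (r2 + h^2)^((m + 3) / 2)
}

#' Simulated sample-plane irradiance of a frame
#'
#' Sums the generalized-Lambertian contributions of every lit LED
#' (superposition) on a regular grid over a rectangular window of the sample
#' plane at height `h_mm`. Grid points sit at cell centers with spacing
#' `res_mm`. Channels without calibration that are nevertheless lit are
#' skipped with a warning.
#'
#' @param frame `n_rows x n_cols x 3` intensity array (a timeline frame), or
#'   an `led_set` (treated as full intensity on `channel`).
#' @param h_mm Sample height above the LED plane (mm), > 0.
#' @param model An `emission_model`.
#' @param window `c(x0, x1, y0, y1)` in mm; default covers the whole matrix.
#' @param res_mm Grid resolution (mm), default 0.25.
#' @param matrix A `matrix_spec`.
#' @param channel Channel used when `frame` is an `led_set`.
#' @return Object of class `irradiance_field`: list with `values` (an
#'   `ny x nx x 3` array, uW/cm2), `x_mm`, `y_mm` (cell-center coordinates),
#'   `h_mm`, `res_mm`.
#' @export
irradiance_field <- function(frame, h_mm, model = emission_model(),
                             window = NULL, res_mm = 0.25,
                             matrix = default_matrix(), channel = "blue") {
  if (h_mm <= 0) stop("sample height h_mm must be > 0")
  if (inherits(frame, "led_set")) {
    fr <- array(0L, c(matrix$n_rows, matrix$n_cols, 3L))
    ch <- match(channel, c("red", "green", "blue"))
    if (nrow(frame) > 0L) fr[cbind(frame$row + 1L, frame$col + 1L, ch)] <- 255L
    frame <- fr
  }
  if (is.null(window)) {
    window <- c(0, matrix$n_cols * matrix$pitch_mm,
                0, matrix$n_rows * matrix$pitch_mm)
  }
  nx <- max(1L, as.integer(round((window[2] - window[1]) / res_mm)))
  ny <- max(1L, as.integer(round((window[4] - window[3]) / res_mm)))
  x <- window[1] + res_mm * (seq_len(nx) - 0.5)
  y <- window[3] + res_mm * (seq_len(ny) - 0.5)
  values <- array(0, c(ny, nx, 3L))
  m <- model$exponent_m
  for (ch in 1:3) {
    lit <- which(frame[, , ch] > 0L, arr.ind = TRUE)
    if (nrow(lit) == 0L) next
    calib <- model$calib_power_uW_cm2[[ch]]
    if (is.na(calib)) {
      warning("channel '", c("red", "green", "blue")[ch],
              "' is lit but has no calibration; it contributes no irradiance")
      next
    }
    plane <- base::matrix(0, ny, nx)
    ctr <- led_center(matrix, lit[, 1] - 1L, lit[, 2] - 1L)
    scale <- frame[cbind(lit[, 1], lit[, 2], ch)] / 255
    dx2 <- outer(x, ctr[, 1], function(a, b) (a - b)^2)  # nx x nled
    dy2 <- outer(y, ctr[, 2], function(a, b) (a - b)^2)  # ny x nled
    for (k in seq_len(nrow(lit))) {
      r2 <- outer(dy2[, k], dx2[, k], `+`)
      plane <- plane + scale[k] *
        led_irradiance(r2, h_mm, m, calib, model$calib_height_mm)
    }
    values[, , ch] <- plane
  }
  structure(list(values = values, x_mm = x, y_mm = y, h_mm = h_mm,
                 res_mm = res_mm),
            class = "irradiance_field")
}

#' @export
print.irradiance_field <- function(x, ...) {
  cat(sprintf("<irradiance_field> %d x %d points at h = %.3g mm, peak %.4g uW/cm2\n",
              length(x$y_mm), length(x$x_mm), x$h_mm, max(x$values)))
  invisible(x)
}

# Total (channel-summed) irradiance matrix of a field.
field_total <- function(field) {
  field$values[, , 1] + field$values[, , 2] + field$values[, , 3]
}

# Bilinear interpolation of the channel-summed field at points (px, py) mm.
interp_field <- function(field, px, py) {
  z <- field_total(field)
  x <- field$x_mm; y <- field$y_mm
  ix <- findInterval(px, x, all.inside = TRUE)
  iy <- findInterval(py, y, all.inside = TRUE)
  x0 <- x[ix]; x1 <- x[ix + 1L]; y0 <- y[iy]; y1 <- y[iy + 1L]
  tx <- pmin(pmax((px - x0) / (x1 - x0), 0), 1)
  ty <- pmin(pmax((py - y0) / (y1 - y0), 0), 1)
  z00 <- z[cbind(iy, ix)];      z10 <- z[cbind(iy, ix + 1L)]
  z01 <- z[cbind(iy + 1L, ix)]; z11 <- z[cbind(iy + 1L, ix + 1L)]
  (1 - ty) * ((1 - tx) * z00 + tx * z10) + ty * ((1 - tx) * z01 + tx * z11)
}

#' Illumination homogeneity within a well
#'
#' `V = 1 - min(boundary irradiance) / center irradiance`, clipped to
#' `[0, 1]`: the maximum fractional intensity drop from the well center to
#' its edge. `V = 0` is a perfectly uniform well. The boundary minimum is
#' taken over points sampled on the well's rim circle (bilinear
#' interpolation on the field grid).
#'
#' @param field An `irradiance_field` whose window contains the well.
#' @param well Well geometry from [well_geometry()]: list with `center_mm`
#'   and `radius_mm`.
#' @param n_boundary Number of rim sample points.
#' @return Homogeneity `V` in `[0, 1]`.
#' @export
homogeneity <- function(field, well, n_boundary = 360L) {
  ctr <- interp_field(field, well$center_mm[1], well$center_mm[2])
  if (ctr <= 0) stop("center irradiance is zero: homogeneity is undefined")
  th <- 2 * pi * (seq_len(n_boundary) - 1L) / n_boundary
  bx <- well$center_mm[1] + well$radius_mm * cos(th)
  by <- well$center_mm[2] + well$radius_mm * sin(th)
  v <- 1 - min(interp_field(field, bx, by)) / ctr
  min(max(v, 0), 1)
}

#' Spillover into neighbouring wells
#'
#' With only one well's LEDs lit, the fraction of the integrated sample-plane
#' irradiance that lands in the footprints of *other* wells, relative to the
#' total integrated irradiance over all wells. Raising the sample height
#' improves in-well homogeneity at the cost of increasing spillover — the
#' device's fundamental geometric trade-off.
#'
#' @param placement A `placement`.
#' @param source_well Address of the lit well.
#' @param h_mm Sample height (mm).
#' @param model An `emission_model`.
#' @param res_mm Integration grid resolution (mm).
#' @param matrix A `matrix_spec`.
#' @param field Optional precomputed `irradiance_field` covering all wells;
#'   computed internally when `NULL`.
#' @return Spillover fraction in `[0, 1]`.
#' @export
spillover <- function(placement, source_well, h_mm,
                      model = emission_model(), res_mm = 0.5,
                      matrix = default_matrix(), field = NULL) {
  addrs <- well_addresses(placement$plate)
  geoms <- lapply(addrs, well_geometry, placement = placement, matrix = matrix)
  if (is.null(field)) {
    centers <- do.call(rbind, lapply(geoms, `[[`, "center_mm"))
    rad <- geoms[[1]]$radius_mm
    window <- c(min(centers[, 1]) - rad, max(centers[, 1]) + rad,
                min(centers[, 2]) - rad, max(centers[, 2]) + rad)
    leds <- resolve_target(source_well, placement, matrix)
    field <- irradiance_field(leds, h_mm, model, window, res_mm, matrix)
  }
  z <- field_total(field)
  pts <- expand.grid(y = field$y_mm, x = field$x_mm)
  total <- 0; other <- 0
  for (i in seq_along(addrs)) {
    g <- geoms[[i]]
    inside <- (pts$x - g$center_mm[1])^2 + (pts$y - g$center_mm[2])^2 <
      g$radius_mm^2
    s <- sum(z[inside])
    total <- total + s
    if (addrs[i] != toupper(normalize_address(source_well, placement$plate))) {
      other <- other + s
    }
  }
  if (total <= 0) return(0)
  other / total
}

# "A2" -> "A02" for comparison with well_addresses() output.
normalize_address <- function(address, plate) {
  rc <- parse_well_address(address, plate)
  paste0(LETTERS[rc["row"] + 1L], sprintf("%02d", rc["col"] + 1L))
}

# Homogeneity of an isolated 2x2 full-intensity LED block centered in a well
# footprint, for a given exponent m — the calibration geometry.
block_homogeneity <- function(m, h_mm, well_radius_mm, model_template,
                              pitch_mm = 3, res_mm = 0.05) {
  model <- emission_model(m, model_template$calib_power_uW_cm2,
                          model_template$calib_height_mm)
  half <- pitch_mm / 2
  mat <- matrix_spec(n_rows = 2L, n_cols = 2L, pitch_mm = pitch_mm)
  center <- c(pitch_mm, pitch_mm)  # midpoint of the 2x2 block
  window <- c(center[1] - well_radius_mm - half, center[1] + well_radius_mm + half,
              center[2] - well_radius_mm - half, center[2] + well_radius_mm + half)
  leds <- led_set(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), mat)
  field <- irradiance_field(leds, h_mm, model, window, res_mm, mat)
  homogeneity(field, list(center_mm = center, radius_mm = well_radius_mm))
}

#' Fit the emission exponent to a homogeneity target
#'
#' Finds the angular order `m` for which the isolated 2x2 full-intensity LED
#' block, viewed through a circular well footprint at height `h_mm`, has
#' homogeneity `V_target`. `V` increases monotonically with `m` (a more
#' concentrated beam falls off faster towards the well edge), so the fit is a
#' bisection over `m in [0, 200]` to `|V - V_target| < tol`. If the target
#' lies outside the range attainable by any `m >= 0` at this height, the fit
#' stops with a calibration error: a point-emitter model cannot be made
#' arbitrarily uniform at close range.
#'
#' @param V_target Target homogeneity in (0, 1).
#' @param h_mm Sample height (mm).
#' @param well Well geometry (list with `radius_mm`); default the 96-well
#'   footprint (6.38 mm diameter).
#' @param model_template `emission_model` supplying calibration constants.
#' @param tol Convergence tolerance on `V`.
#' @param res_mm Field resolution used during fitting.
#' @return An `emission_model` with the fitted exponent.
#' @export
calibrate_emission <- function(V_target, h_mm,
                               well = list(radius_mm = 6.38 / 2),
                               model_template = emission_model(),
                               tol = 1e-3, res_mm = 0.05) {
  if (!(V_target > 0 && V_target < 1)) {
    stop("calibration error: V_target must lie strictly in (0, 1)")
  }
  f <- function(m) block_homogeneity(m, h_mm, well$radius_mm, model_template,
                                     res_mm = res_mm) - V_target
  lo <- 0; hi <- 200
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf(paste0(
      "calibration error: V_target = %.4g at h = %.3g mm is outside the ",
      "attainable range [%.4g, %.4g] for m in [0, 200]"),
      V_target, h_mm, f_lo + V_target, f_hi + V_target))
  }
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    # stop only once both V and m have converged: V tolerances alone leave m
    # poorly determined where dV/dm is shallow
    if (abs(f_mid) < tol && (hi - lo) < 1e-4 * max(1, mid)) break
    if (f_mid > 0) hi <- mid else lo <- mid
  }
  emission_model(mid, model_template$calib_power_uW_cm2,
                 model_template$calib_height_mm)
}

#' Light dose from irradiance and time
#'
#' `dose [mJ/cm2] = irradiance [uW/cm2] x seconds / 1000`. Ten seconds of the
#' full-intensity blue calibration irradiance (135 uW/cm2) is 1.35 mJ/cm2.
#'
#' @param irradiance_uW_cm2 Irradiance (uW/cm2).
#' @param seconds Exposure time (s).
#' @return Dose in mJ/cm2.
#' @export
dose_mJ_cm2 <- function(irradiance_uW_cm2, seconds) {
  irradiance_uW_cm2 * seconds / 1000
}

#' Per-well light dose of a compiled timeline
#'
#' For every well of the placement, integrates the mean in-well irradiance
#' over the timeline's lit seconds: the per-second mean irradiance over the
#' well footprint (grid summation) times 1 s, accumulated into a cumulative
#' dose in mJ/cm2. Repeated identical frames are evaluated once. Optionally
#' reports, for each lit well, the homogeneity of its time-maximum field and
#' its spillover fraction.
#'
#' @param timeline A `frame_timeline`.
#' @param model An `emission_model`.
#' @param placement A `placement`.
#' @param h_mm Sample height (mm).
#' @param res_mm Grid resolution for in-well integration (mm).
#' @param matrix A `matrix_spec`.
#' @param optics If `TRUE`, add `homogeneity` and `spillover` columns for lit
#'   wells (slower).
#' @details A well's `lit_seconds` counts the seconds during which *its own*
#'   LEDs are on; its dose nevertheless integrates all light reaching the
#'   well footprint, including spillover from neighbours, over every frame.
#'   `mean_irradiance_uW_cm2` is the mean in-well irradiance over the well's
#'   lit seconds (0 for a well never directly addressed).
#' @return Data frame (class `well_dose_report`) with one row per well:
#'   `well`, `lit_seconds`, `mean_irradiance_uW_cm2`, `dose_mJ_cm2`, and
#'   optionally `homogeneity`, `spillover`.
#' @export
well_dose <- function(timeline, model = emission_model(),
                      placement = default_placement("96"), h_mm = 2,
                      res_mm = 0.25, matrix = default_matrix(),
                      optics = FALSE) {
  addrs <- well_addresses(placement$plate)
  geoms <- lapply(addrs, well_geometry, placement = placement, matrix = matrix)

  # Pre-compute in-well grid points per well.
  grids <- lapply(geoms, function(g) {
    n <- max(3L, ceiling(2 * g$radius_mm / res_mm))
    xs <- g$center_mm[1] + res_mm * (seq_len(n) - (n + 1) / 2)
    ys <- g$center_mm[2] + res_mm * (seq_len(n) - (n + 1) / 2)
    pts <- expand.grid(y = ys, x = xs)
    keep <- (pts$x - g$center_mm[1])^2 + (pts$y - g$center_mm[2])^2 <
      g$radius_mm^2
    list(x = pts$x[keep], y = pts$y[keep],
         window = c(min(xs) - res_mm, max(xs) + res_mm,
                    min(ys) - res_mm, max(ys) + res_mm))
  })

  # Mean in-well irradiance for one frame, all wells; cached by frame content.
  cache <- new.env(parent = emptyenv())
  frame_means <- function(fr) {
    key <- paste(which(fr > 0L), fr[fr > 0L], collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    means <- vapply(seq_along(addrs), function(i) {
      g <- grids[[i]]
      field <- irradiance_field(fr, h_mm, model, g$window, res_mm, matrix)
      mean(interp_field(field, g$x, g$y))
    }, numeric(1))
    cache[[key]] <- means
    means
  }

  own_leds <- lapply(addrs, function(a) {
    s <- suppressWarnings(resolve_target(a, placement, matrix))
    cbind(s$row + 1L, s$col + 1L)
  })
  own_on <- function(fr) {
    any_on <- fr[, , 1] > 0L | fr[, , 2] > 0L | fr[, , 3] > 0L
    vapply(own_leds, function(sel) nrow(sel) > 0L && any(any_on[sel]),
           logical(1))
  }

  dose <- numeric(length(addrs))
  lit_dose <- numeric(length(addrs))
  lit_secs <- integer(length(addrs))
  for (fr in timeline$frames) {
    means <- frame_means(fr)
    on <- own_on(fr)
    dose <- dose + means / 1000          # uW/cm2 * 1 s -> mJ/cm2
    lit_dose <- lit_dose + ifelse(on, means / 1000, 0)
    lit_secs <- lit_secs + as.integer(on)
  }
  mean_irr <- ifelse(lit_secs > 0, lit_dose * 1000 / lit_secs, 0)

  out <- data.frame(well = addrs, lit_seconds = lit_secs,
                    mean_irradiance_uW_cm2 = mean_irr,
                    dose_mJ_cm2 = dose)
  if (optics && length(timeline$frames) > 0L) {
    peak <- Reduce(function(a, b) pmax(a, b), timeline$frames)
    out$homogeneity <- NA_real_
    out$spillover <- NA_real_
    for (i in seq_along(addrs)) {
      if (lit_secs[i] == 0L) next
      g <- grids[[i]]; geom <- geoms[[i]]
      field <- irradiance_field(peak, h_mm, model, g$window, res_mm, matrix)
      out$homogeneity[i] <- tryCatch(homogeneity(field, geom),
                                     error = function(e) NA_real_)
      out$spillover[i] <- spillover(placement, addrs[i], h_mm, model,
                                    res_mm = max(res_mm, 0.5), matrix = matrix)
    }
  }
  class(out) <- c("well_dose_report", "data.frame")
  out
}

#' Build a light-gradient program
#'
#' One command per LED column (axis `"x"`) or row (axis `"y"`) of the region,
#' with intensity linearly interpolated from `start_level` to `end_level` and
#' rounded to the nearest representable level — a cm-scale light gradient.
#'
#' @param region Target keyword resolved against `placement` (e.g. `"Whole"`,
#'   `"Rec_A1_D6"`).
#' @param axis `"x"` (gradient along columns) or `"y"` (along rows).
#' @param start_level,end_level Intensities 0-255 at the two ends.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param placement A `placement` (if the region needs one).
#' @param matrix A `matrix_spec`.
#' @param start_s,duration_s Timing applied to every command.
#' @return A `stim_program` with one command per lattice line of the region.
#' @export
gradient_program <- function(region, axis = c("x", "y"), start_level,
                             end_level, channel = "blue", placement = NULL,
                             matrix = default_matrix(), start_s = 0,
                             duration_s = 1) {
  axis <- match.arg(axis)
  stopifnot(start_level >= 0, start_level <= 255,
            end_level >= 0, end_level <= 255)
  leds <- resolve_target(region, placement, matrix)
  if (nrow(leds) == 0L) stop("gradient region is empty")
  key <- if (axis == "x") leds$col else leds$row
  lines_ <- sort(unique(key))
  n <- length(lines_)
  ch <- match(channel, c("red", "green", "blue"))
  cmds <- lapply(seq_along(lines_), function(i) {
    frac <- if (n == 1L) 0 else (i - 1) / (n - 1)
    level <- as.integer(floor(start_level + (end_level - start_level) * frac + 0.5))
    members <- leds[key == lines_[i], , drop = FALSE]
    target <- paste0("Led_", paste(members$row, members$col, sep = "_",
                                   collapse = "|"))
    color <- c(0L, 0L, 0L); color[ch] <- level
    command(target, start_s, duration_s, color)
  })
  stim_program(cmds, plate = if (is.null(placement)) "96" else
    placement$plate$name, name = sprintf("gradient_%s_%d_%d", axis,
                                         start_level, end_level))
}
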