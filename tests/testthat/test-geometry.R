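test_that("LED centers sit half a pitch in from the top-left corner", {
  m <- default_matrix()
  expect_equal(unname(led_center(m, 0, 0)[1, ]), c(1.5, 1.5))
  expect_equal(unname(led_center(m, 0, 1)[1, ]), c(4.5, 1.5))
  expect_equal(unname(led_center(m, 31, 63)[1, ]), c(190.5, 94.5))
  expect_error(led_center(m, 32, 0), "out of bounds")
  expect_error(led_center(m, 0, -1), "out of bounds")
})

test_that("matrix invariants hold and bad specs are rejected", {
  m <- default_matrix()
  expect_equal(m$n_rows * m$n_cols, 2048L)
  expect_equal(m$intensity_levels, 256L)
  expect_error(matrix_spec(pitch_mm = 0))
  expect_error(matrix_spec(max_power_uW_cm2 = c(red = -1, green = 0, blue = 135)))
})

test_that("well centers follow the plate lattice and snap to 2x2 midpoints", {
  pl96 <- default_placement("96")
  expect_equal(unname(well_center(pl96, "A01")), c(3, 3))
  expect_equal(unname(well_center(pl96, "B01")), c(3, 12))
  # both spellings address the same well
  expect_equal(well_center(pl96, "A1"), well_center(pl96, "A01"))
  # 6-well pitch 39.12 is not a pitch multiple: A2 snaps 57.12 -> 57.0
  pl6 <- default_placement("6")
  expect_equal(unname(well_center(pl6, "A2")), c(57, 18))
  # rigid mode keeps the nominal center
  pl6r <- default_placement("6", snap_mode = "rigid")
  expect_equal(unname(well_center(pl6r, "A2"))[1], 18 + 39.12)
  # snap displacement bounded by half a pitch per axis
  for (w in well_addresses("24")) {
    d <- abs(well_center(default_placement("24"), w) -
             well_center(default_placement("24", snap_mode = "rigid"), w))
    expect_true(all(d <= 1.5 + 1e-12))
  }
  expect_error(well_center(pl96, "Z99"), "does not exist")
  expect_error(well_center(pl96, "A111"), "malformed")
})

test_that("96-well default placement gives 96 disjoint 2x2 LED blocks", {
  pl <- default_placement("96")
  sets <- lapply(well_addresses("96"), resolve_target, placement = pl)
  expect_true(all(vapply(sets, nrow, integer(1)) == 4L))
  all_leds <- do.call(rbind, lapply(sets, as.data.frame))
  expect_equal(nrow(unique(all_leds)), 96L * 4L)
  # the A01 block is the top-left 2x2
  expect_equal(as.data.frame(sets[[1]]),
               data.frame(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)))
})

test_that("a full 6-well well resolves to 112 LEDs", {
  pl <- default_placement("6")
  expect_equal(nrow(resolve_target("A1", pl)), 112L)
})

test_that("row, column, plate and whole targets are consistent unions", {
  for (fmt in c("96", "24")) {
    pl <- default_placement(fmt)
    f <- plate_format(fmt)
    by_well <- do.call(ledstim:::led_union,
                       lapply(well_addresses(f), resolve_target, placement = pl))
    by_row <- do.call(ledstim:::led_union,
                      lapply(LETTERS[seq_len(f$n_well_rows)],
                             resolve_target, placement = pl))
    plate <- resolve_target("Plate", pl)
    expect_equal(as.data.frame(plate), as.data.frame(by_well))
    expect_equal(as.data.frame(plate), as.data.frame(by_row))
  }
  pl96 <- default_placement("96")
  rowA <- resolve_target("A", pl96)
  expect_equal(nrow(rowA), 48L)  # 12 wells x 4 LEDs, disjoint
  expect_equal(nrow(resolve_target("Whole", pl96)), 2048L)
  expect_equal(nrow(resolve_target("1", pl96)), 32L)  # 8 wells x 4
})

test_that("rectangle, circle and explicit LED targets resolve", {
  pl <- default_placement("96")
  rect <- resolve_target("Rec_A1_B2", pl)
  expect_equal(nrow(rect), 16L)  # 4 wells x 4 LEDs
  # circle of radius 2 around an LED center catches exactly that LED
  expect_equal(nrow(resolve_target("Cir_1.5_1.5_2", pl)), 1L)
  leds <- resolve_target("Led_0_0|3_5", pl)
  expect_equal(as.data.frame(leds),
               data.frame(row = c(0L, 3L), col = c(0L, 5L)))
  expect_error(resolve_target("Gibberish!", pl), "unknown target")
  expect_error(resolve_target("Led_0_x", pl), "cannot parse")
})

test_that("an empty resolution warns instead of failing silently", {
  # a circle far outside the lattice covers no LED centers
  expect_warning(out <- resolve_target("Cir_500_500_1", NULL), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("all wells of a format resolve to congruent patterns under snapping", {
  for (fmt in c("6", "12", "24", "48", "96")) {
    pl <- default_placement(fmt)
    sets <- lapply(well_addresses(fmt), resolve_target, placement = pl)
    shapes <- vapply(sets, function(s) {
      paste(s$row - min(s$row), s$col - min(s$col), collapse = ";")
    }, character(1))
    expect_length(unique(shapes), 1L)
  }
})

test_that("resolved LEDs always lie within matrix bounds", {
  m <- default_matrix()
  for (seed in 1:20) {
    set.seed(seed)
    fmt <- sample(c("6", "12", "24", "48", "96"), 1L)
    pl <- placement(fmt, origin_offset_mm = runif(2, -30, 120))
    leds <- suppressWarnings(resolve_target("Plate", pl, m))
    if (nrow(leds) > 0L) {
      expect_true(all(leds$row >= 0L & leds$row < m$n_rows))
      expect_true(all(leds$col >= 0L & leds$col < m$n_cols))
    }
  }
})

test_that("placement validation reports empty, truncated and overlapping wells", {
  expect_equal(nrow(validate_placement(default_placement("96"))), 0L)

  # shift the plate so its last columns run past the right matrix edge
  shifted <- placement("96", c(3 + 9 * 11, 3))
  f <- validate_placement(shifted)
  expect_true(any(f$issue %in% c("truncated", "empty")))

  # two identical placements claim the same LEDs
  f2 <- validate_placement(list(default_placement("96"),
                                default_placement("96")))
  expect_true(any(f2$issue == "overlap"))
})

test_that("plate outline is the perimeter of the resolved bounding box", {
  pl <- default_placement("96")
  out <- outline_set(pl)
  plate <- resolve_target("Plate", pl)
  r0 <- min(plate$row); r1 <- max(plate$row)
  c0 <- min(plate$col); c1 <- max(plate$col)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  expect_equal(nrow(out), 2L * (nr + nc) - 4L)
  # outline has no interior points
  interior <- out$row > r0 & out$row < r1 & out$col > c0 & out$col < c1
  expect_false(any(interior))
  # every well LED lies inside or on the box
  expect_true(all(plate$row >= r0 & plate$row <= r1 &
                  plate$col >= c0 & plate$col <= c1))
})

test_that("plate registry covers the supported formats and can be overridden", {
  reg <- plate_registry()
  expect_setequal(reg$name, c("6", "12", "24", "48", "96", "dish100"))
  expect_true(all(reg$well_pitch_mm >= reg$well_diameter_mm))
  f96 <- plate_format("96")
  expect_equal(f96$well_pitch_mm, 9)
  expect_equal(f96$well_diameter_mm, 6.38)
  expect_error(plate_format("384"), "unknown plate format")

  tmp <- tempfile(fileext = ".yaml")
  writeLines(paste(
    "- name: '6'", "  n_well_rows: 2", "  n_well_cols: 3",
    "  well_pitch_mm: 39.12", "  well_diameter_mm: 35.0",
    "  geometry_kind: circular_well", sep = "\n"), tmp)
  reg2 <- load_plate_registry(tmp)
  expect_equal(reg2$well_diameter_mm[reg2$name == "6"], 35.0)
})

test_that("LED sets export as CSV and plate maps", {
  leds <- resolve_target("A01", default_placement("96"))
  tmp <- tempfile(fileext = ".csv")
  write_led_csv(leds, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back, data.frame(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)))
  map <- plate_map_text(leds)
  expect_length(map, 32L)
  expect_match(map[1], "^##\\.+$")
})
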