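test_that("a full-intensity blue LED delivers the calibration irradiance on-axis", {
  model <- emission_model()
  # closed form at r = 0, calibration height
  expect_equal(ledstim:::led_irradiance(0, 2, model$exponent_m, 135, 2), 135)
  # through the field pipeline: grid point exactly on the LED center
  fr <- array(0L, c(32, 64, 3)); fr[1, 1, 3] <- 255L
  field <- irradiance_field(fr, 2, model, window = c(1.25, 1.75, 1.25, 1.75),
                            res_mm = 0.5)
  expect_equal(field$values[1, 1, 3], 135, tolerance = 1e-12)
  # half intensity scales linearly
  fr[1, 1, 3] <- 100L
  f2 <- irradiance_field(fr, 2, model, window = c(1.25, 1.75, 1.25, 1.75),
                         res_mm = 0.5)
  expect_equal(f2$values[1, 1, 3], 135 * 100 / 255, tolerance = 1e-12)
  expect_error(irradiance_field(fr, 0, model), "h_mm must be > 0")
})

test_that("off-axis irradiance matches the generalized-Lambertian closed form", {
  # independent evaluation of S * h^(m+1) / (r^2 + h^2)^((m+3)/2)
  S <- 135 * 2^2
  expected <- S * 2^2 / (3^2 + 2^2)^2   # r = 3 mm, h = 2 mm, m = 1
  expect_equal(ledstim:::led_irradiance(9, 2, 1, 135, 2), expected,
               tolerance = 1e-12)
})

test_that("single-LED fields are radially symmetric", {
  fr <- array(0L, c(32, 64, 3)); fr[1, 1, 3] <- 255L  # center (1.5, 1.5)
  field <- irradiance_field(fr, 3, window = c(-3.5, 6.5, -3.5, 6.5),
                            res_mm = 0.25)
  z <- field$values[, , 3]
  # window is symmetric about the LED: reflections leave the field unchanged
  expect_equal(z, z[rev(seq_len(nrow(z))), ], tolerance = 1e-9)
  expect_equal(z, z[, rev(seq_len(ncol(z)))], tolerance = 1e-9)
  expect_equal(z, t(z), tolerance = 1e-9)
})

test_that("fields superpose: disjoint LED sets sum", {
  win <- c(0, 12, 0, 12)
  a <- led_set(0, 0); b <- led_set(2, 3)
  fa <- irradiance_field(a, 2, window = win, res_mm = 0.5)
  fb <- irradiance_field(b, 2, window = win, res_mm = 0.5)
  fab <- irradiance_field(ledstim:::led_union(a, b), 2, window = win,
                          res_mm = 0.5)
  expect_equal(fab$values, fa$values + fb$values, tolerance = 1e-9)
})

test_that("integrated irradiance over the plane is independent of height", {
  # point-source flux conservation: for m = 1 the analytic plane integral of
  # E is pi * S, independent of h
  S <- 135 * 4
  for (h in c(2, 5)) {
    led <- led_set(0, 0)
    f <- irradiance_field(led, h, window = c(1.5 - 120, 1.5 + 120,
                                             1.5 - 120, 1.5 + 120),
                          res_mm = 0.5)
    integral <- sum(f$values[, , 3]) * 0.5^2 / 100  # mm^2 -> cm^2
    expect_equal(integral, pi * S / 100, tolerance = 0.02)
  }
})

test_that("a uniform field has homogeneity zero; sharper beams are less uniform", {
  uniform <- structure(list(values = array(1, c(41, 41, 3)),
                            x_mm = seq(-5, 5, length.out = 41),
                            y_mm = seq(-5, 5, length.out = 41),
                            h_mm = 2, res_mm = 0.25),
                       class = "irradiance_field")
  expect_equal(homogeneity(uniform, list(center_mm = c(0, 0),
                                         radius_mm = 3)), 0)
  # homogeneity of the 2x2 block improves (V drops) with distance
  v2 <- ledstim:::block_homogeneity(1, 2, 3.19, emission_model())
  v6 <- ledstim:::block_homogeneity(1, 6, 3.19, emission_model())
  expect_lt(v6, v2)
  # V strictly decreases over h in [1, 20] mm
  vs <- vapply(c(1, 2, 4, 8, 12, 16, 20), function(h) {
    ledstim:::block_homogeneity(1, h, 3.19, emission_model())
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
  expect_error(homogeneity(structure(list(values = array(0, c(5, 5, 3)),
                                          x_mm = 1:5, y_mm = 1:5,
                                          h_mm = 2, res_mm = 1),
                                     class = "irradiance_field"),
                           list(center_mm = c(3, 3), radius_mm = 1)),
               "undefined")
})

test_that("spillover grows with height and vanishes near the matrix", {
  pl <- default_placement("96")
  sp <- vapply(c(1, 2, 5, 10, 20), function(h) {
    spillover(pl, "B02", h, res_mm = 0.5)
  }, numeric(1))
  expect_true(all(diff(sp) >= 0))
  expect_lt(spillover(pl, "B02", 0.1, res_mm = 0.5), sp[2])
  expect_true(all(sp >= 0 & sp <= 1))
})

test_that("emission calibration recovers planted exponents within 1%", {
  for (m_star in c(0.5, 1, 2, 5)) {
    v <- ledstim:::block_homogeneity(m_star, 2, 3.19, emission_model(),
                                     res_mm = 0.05)
    fit <- calibrate_emission(v, 2)
    expect_lt(abs(fit$exponent_m - m_star) / m_star, 0.01)
    # and reproduces the target homogeneity within the fit tolerance
    v_back <- ledstim:::block_homogeneity(fit$exponent_m, 2, 3.19,
                                          emission_model(), res_mm = 0.05)
    expect_lt(abs(v_back - v), 1e-3)
  }
})

test_that("unreachable homogeneity targets raise a calibration error", {
  expect_error(calibrate_emission(0, 2), "calibration error")
  expect_error(calibrate_emission(1, 2), "calibration error")
  # a point emitter cannot reach 25% uniformity at 2 mm: V(m = 0) ~ 0.47
  expect_error(calibrate_emission(0.25, 2), "outside the attainable range")
})

test_that("dose arithmetic: 10 s of full blue at the calibration point is 1.35 mJ/cm2", {
  expect_equal(dose_mJ_cm2(135, 10), 1.35)
  expect_equal(dose_mJ_cm2(135, 20), 2 * dose_mJ_cm2(135, 10))
})

test_that("well dose integrates in-well irradiance over lit seconds", {
  pl <- default_placement("96")
  mk <- function(dur) {
    build_timeline(expand_program(
      stim_program(list(command("A01", 0, dur, "blue"))), pl))
  }
  r10 <- well_dose(mk(10), placement = pl, res_mm = 0.5)
  a01 <- r10[r10$well == "A01", ]
  expect_equal(a01$lit_seconds, 10L)
  expect_gt(a01$dose_mJ_cm2, 0)
  expect_equal(a01$dose_mJ_cm2,
               dose_mJ_cm2(a01$mean_irradiance_uW_cm2, 10))
  # doubling every duration doubles every dose
  r20 <- well_dose(mk(20), placement = pl, res_mm = 0.5)
  expect_equal(r20$dose_mJ_cm2, 2 * r10$dose_mJ_cm2, tolerance = 1e-12)
  # empty timeline: all doses zero
  r0 <- well_dose(build_timeline(list()), placement = pl, res_mm = 0.5)
  expect_true(all(r0$dose_mJ_cm2 == 0))
  # optional optics columns for the lit well
  ro <- well_dose(mk(2), placement = pl, res_mm = 0.5, optics = TRUE)
  expect_true(is.finite(ro$homogeneity[ro$well == "A01"]))
  expect_true(ro$spillover[ro$well == "A01"] >= 0)
})

test_that("gradient programs interpolate and round intensities monotonically", {
  g <- gradient_program("Whole", "x", 0, 255)
  expect_length(g$commands, 64L)
  levels <- vapply(g$commands, function(cm) cm$color[["blue"]], integer(1))
  expect_equal(levels, round(255 * (0:63) / 63))
  expect_true(!is.unsorted(levels))
  # reversing the direction reverses the sequence
  rev_g <- gradient_program("Whole", "x", 255, 0)
  rev_levels <- vapply(rev_g$commands, function(cm) cm$color[["blue"]],
                       integer(1))
  expect_equal(rev_levels, rev(levels))
  # start = end is a uniform region
  u <- gradient_program("Whole", "y", 40, 40)
  expect_true(all(vapply(u$commands, function(cm) cm$color[["blue"]],
                         integer(1)) == 40L))
  expect_error(gradient_program("Cir_500_500_1", "x", 0, 255) |>
                 suppressWarnings(), "empty")
})

test_that("uncalibrated channels warn and contribute no irradiance", {
  fr <- array(0L, c(32, 64, 3)); fr[1, 1, 1] <- 255L  # red, no calibration
  expect_warning(f <- irradiance_field(fr, 2, window = c(0, 3, 0, 3),
                                       res_mm = 0.5), "no calibration")
  expect_true(all(f$values == 0))
})
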