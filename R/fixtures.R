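#' Seeded random illumination program
#'
#' Deterministic generator of valid programs for property tests and fuzzing:
#' the same seed always yields the same program, and every generated program
#' passes [validate_program()] on its plate's default placement. Targets are
#' drawn from wells, rows, columns and rectangles of the plate; colors from
#' single-channel intensities; repeat intervals are always >= the pulse
#' duration (no self-overlap). The caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_commands Number of commands (>= 0).
#' @param plate Plate format name.
#' @param max_start Latest command start (s).
#' @param max_duration Longest pulse (s).
#' @param max_repeats Largest repeat count.
#' @return A `stim_program`.
#' @export
random_program <- function(seed, n_commands = 5L, plate = "96",
                           max_start = 120L, max_duration = 10L,
                           max_repeats = 3L) {
  stopifnot(n_commands >= 0L, max_start >= 0L, max_duration >= 1L,
            max_repeats >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  fmt <- plate_format(plate)
  wells <- well_addresses(fmt)
  cmds <- lapply(seq_len(n_commands), function(i) {
    kind <- sample(c("well", "row", "column", "rect"), 1L,
                   prob = c(0.6, 0.15, 0.15, 0.1))
    target <- switch(kind,
      well = sample(wells, 1L),
      row = LETTERS[sample.int(fmt$n_well_rows, 1L)],
      column = as.character(sample.int(fmt$n_well_cols, 1L)),
      rect = {
        a <- sample(wells, 1L); b <- sample(wells, 1L)
        paste0("Rec_", a, "_", b)
      })
    duration <- sample.int(max_duration, 1L)
    repeats <- sample.int(max_repeats, 1L)
    interval <- if (repeats > 1L) duration + sample.int(30L, 1L) else NA_integer_
    color <- c(0L, 0L, 0L)
    color[sample.int(3L, 1L)] <- sample.int(255L, 1L)
    command(target = target, start_s = sample.int(max_start + 1L, 1L) - 1L,
            duration_s = duration, color = color, repeats = repeats,
            interval_s = interval)
  })
  stim_program(cmds, plate = plate, name = sprintf("random_seed_%d", seed))
}

#' Packaged stimulation protocols
#'
#' Replicas of characteristic stimulation experiments for the reference
#' hardware, built from their printed parameters:
#' \describe{
#'   \item{`phase_shift_pulses`}{Two well groups on a 96-well plate, each
#'     pulsed for 3 s of full blue every 5 min over a 1 h experiment; the
#'     second group starts with a 30 min delay (12 vs 6 pulses).}
#'   \item{`stagger_endpoints`}{A 12-point time course at 2 min resolution:
#'     each well gets one 10 s blue pulse, staggered so all wells reach their
#'     stimulation-to-end interval at a common fixation endpoint.}
#'   \item{`fixation_ladder`}{A high-temporal-resolution ladder: a single 2 s
#'     blue pulse per well, 12 wells at 1 min resolution, common endpoint.}
#'   \item{`pulse_train_high`}{10 s blue pulses every 2 min for a total of
#'     84 min (42 pulses) — drives sustained pathway activation.}
#'   \item{`pulse_train_low`}{10 s blue pulses every 20 min over the same
#'     84 min (5 pulses) — evokes discrete response pulses.}
#' }
#' Every preset passes [validate_program()] on its plate's default placement.
#'
#' @return Named list of presets; each has `name`, `program`, `note`.
#' @export
preset_protocols <- function() {
  presets <- list()
  add <- function(name, program, note) {
    program$name <- name
    presets[[name]] <<- list(name = name, program = program, note = note)
  }

  add("phase_shift_pulses",
      stim_program(list(
        command("A01", 0L, 3L, "blue", repeats = 12L, interval_s = 300L),
        command("B01", 0L, 3L, "blue", repeats = 12L, interval_s = 300L),
        command("C01", 1800L, 3L, "blue", repeats = 6L, interval_s = 300L),
        command("D01", 1800L, 3L, "blue", repeats = 6L, interval_s = 300L)),
        plate = "96"),
      "3 s blue pulse every 5 min over 1 h; second well pair delayed 30 min")

  add("stagger_endpoints",
      reverse_schedule(120L * (1:12), command("A01", 0L, 10L, "blue"),
                       sprintf("A%02d", 1:12), plate = "96"),
      "12-point time course, 2 min resolution, one 10 s pulse per well, simultaneous endpoint")

  add("fixation_ladder",
      reverse_schedule(60L * (1:12), command("A01", 0L, 2L, "blue"),
                       sprintf("B%02d", 1:12), plate = "96"),
      "single 2 s pulse per well, 1 min resolution, simultaneous endpoint")

  add("pulse_train_high",
      stim_program(list(
        command("A01", 0L, 10L, "blue", repeats = 42L, interval_s = 120L)),
        plate = "96"),
      "10 s blue pulses every 2 min for 84 min (42 pulses)")

  add("pulse_train_low",
      stim_program(list(
        command("A01", 0L, 10L, "blue", repeats = 5L, interval_s = 1200L)),
        plate = "96"),
      "10 s blue pulses every 20 min for 84 min (5 pulses)")

  presets
}

#' Load a packaged preset from its shipped CSV
#'
#' The presets of [preset_protocols()] are also shipped as CSV program files
#' under `extdata/programs/`; this reads one back through the normal parser.
#'
#' @param name Preset name.
#' @return A `stim_program`.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "programs", paste0(name, ".csv"),
                      package = "ledstim")
  if (!nzchar(path)) stop("no shipped preset named '", name, "'")
  parse_program(file = path, plate = "96", name = name)
}
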