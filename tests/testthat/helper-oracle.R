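# Brute-force per-second reference simulator, independent of the compiled
# timeline path: for every second it loops over every command and every pulse
# and takes the channel-wise max over covering pulses.
oracle_frame <- function(program, t, placement, matrix = default_matrix()) {
  fr <- array(0L, c(matrix$n_rows, matrix$n_cols, 3L))
  for (cm in program$commands) {
    if (!nzchar(cm$target)) next
    leds <- suppressWarnings(resolve_target(cm$target, placement, matrix))
    if (nrow(leds) == 0L) next
    step <- if (is.na(cm$interval_s)) 0L else cm$interval_s
    for (k in seq_len(cm$repeats) - 1L) {
      t_on <- cm$start_s + k * step
      if (t >= t_on && t < t_on + cm$duration_s) {
        for (ch in 1:3) {
          if (cm$color[[ch]] > 0L) {
            sel <- cbind(leds$row + 1L, leds$col + 1L, ch)
            fr[sel] <- pmax(fr[sel], cm$color[[ch]])
          }
        }
      }
    }
  }
  fr
}

# TRUE iff the compiled timeline matches the oracle at every second.
timeline_matches_oracle <- function(program, placement = NULL,
                                    matrix = default_matrix()) {
  if (is.null(placement)) placement <- default_placement(program$plate, matrix)
  tl <- build_timeline(expand_program(program, placement, matrix), matrix)
  horizon <- program_horizon(program)
  if (tl$horizon_s != horizon) return(FALSE)
  for (t in seq_len(horizon) - 1L) {
    if (!identical(timeline_frame(tl, t, matrix),
                   oracle_frame(program, t, placement, matrix))) {
      return(FALSE)
    }
  }
  TRUE
}

# A simple two-group pulse program (two wells pulsed from t = 0, two more
# with a delay, all until a common end), used across scheduler tests.
two_group_pulse_csv <- function() {
  c("target,start,duration,red,green,blue,interval,until",
    "A01,0,3,0,0,255,300,3600",
    "B01,0,3,0,0,255,300,3600",
    "C01,1800,3,0,0,255,300,3600",
    "D01,1800,3,0,0,255,300,3600")
}
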