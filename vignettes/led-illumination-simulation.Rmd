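---
title: "Programming and simulating LED-matrix optogenetic illumination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programming and simulating LED-matrix optogenetic illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledstim)
```

## The problem

Optogenetic actuators (optoFGFR, optoRaf and relatives) turn a light pulse
into a signaling event, so an illumination device doubles as a signal
generator for living cells. A cheap way to build one is to park a multiwell
plate directly on a commodity 32 x 64 RGB LED matrix with a 3 mm pitch: the
9 mm pitch of a 96-well plate is exactly three LED pitches, so a 2 x 2 block
of LEDs sits centered under every well. The device executes CSV
"illumination programs" — one command per line saying *which* LEDs, *when*,
*how long*, and *in what color and intensity* — and supports messages with
countdowns and a buzzer so the operator can pipette on cue.

`ledstim` is a desk-scale model of that tool chain. It parses and validates
the CSV dialect, resolves plate keywords to LED coordinates, compiles
programs to a deterministic 1 Hz frame timeline, emulates the operator-facing
actions, and simulates the physics the hardware documentation only
characterizes empirically: sample-plane irradiance, in-well homogeneity,
spillover between wells, cumulative light dose, and medium heating.

## Geometry

LED indices are 0-based, row-major from the matrix's top-left corner;
physical coordinates are millimetres from the same corner, so LED $(r, c)$
is centered at $((c + \tfrac12)p, (r + \tfrac12)p)$ with $p = 3$ mm.

A placement puts well A1's center at the 2 x 2-cell midpoint nearest to half
a well diameter from the corner. For the 96-well format this is $(3, 3)$ mm
and produces the canonical 2 x 2 block per well. The 6.38 mm well then
overhangs the matrix edge by 0.19 mm, which we accept because no assigned
LED is lost.

Because the 6-, 12-, 24- and 48-well pitches are *not* multiples of 3 mm,
each well's center is snapped to the nearest lattice midpoint by default
(`per_well_snap`), which keeps every well's LED pattern congruent — the
deterministic behaviour a scheduling tool needs. `rigid` mode keeps nominal
centers for physical-fidelity studies.

A well's LED set is every LED whose center lies *strictly* within the well
radius of the snapped center. With the ANSI/SLAS-conventional 34.8 mm
diameter for 6-well plates this rule yields exactly 112 LEDs per well
(4 x 28 lattice points), matching the count the reference hardware reports
for illuminating one full 6-well well. The manufacturer behind that diameter
is not documented; 34.8 mm is our inference and is config-overridable, as is
the whole registry (only the 96-well entry, 9 mm / 6.38 mm, is
hardware-anchored).

```{r}
pl6 <- default_placement("6")
nrow(resolve_target("A1", pl6))
```

## The program dialect

The CSV headers are `target, start, duration, red, green, blue, repeats,
interval, until, message, buzzer`. The original firmware's exact headers are
not documented publicly, so this dialect is our own with the same expressive
power, and programs written in it are *not* portable to the firmware. The
same caveat applies to our `Rec_A1_D4`, `Cir_x_y_r` and `Led_r_c` target
spellings. Times are integer seconds or `HH:MM:SS`; sub-second values are
rejected rather than rounded, because silent rounding would distort dose
accounting. The minimum pulse duration is 1 s, mirroring the firmware's
constraint.

Loops are end-exclusive: pulse $k$ (0-based) starts at
$\mathrm{start} + k \cdot \mathrm{interval}$ for $k < \mathrm{repeats}$. A
row may instead give `until`, an absolute end time, in which case
$\mathrm{repeats} = \lceil (\mathrm{until} - \mathrm{start}) /
\mathrm{interval} \rceil$ — i.e. every start strictly before `until` counts.
A 3 s pulse every 5 min until one hour is 12 pulses (t = 0, 300, ..., 3300);
the same program delayed by 30 min gets 6. `until` is the one column we
added beyond the minimal parameter set, because total-duration phrasing is
how such experiments are naturally written down.

By the same end-exclusive convention the packaged 84-min pulse-train
protocols expand to 42 pulses (every 2 min) and 5 pulses (every 20 min); a
terminal pulse at exactly 84 min would start at the horizon and is excluded.

## Scheduling

Programs compile to a sparse 1 Hz frame timeline: a full 32 x 64 x 3
intensity grid per lit second, absent seconds meaning all-off. 1 Hz matches
the firmware's 1 s granularity; finer resolution is out of scope. Event
intervals are half-open, so a 3 s pulse lights exactly 3 frames.

Overlapping commands combine **channel-wise by maximum**. The firmware's
actual conflict policy is undocumented; we chose max because it is
idempotent and order-independent, and because additive blending could exceed
the 255-level hardware ceiling and fabricate dose out of thin air. This is a
documented dialect-divergence risk.

`reverse_schedule()` implements the simultaneous-fixation design: to sample
a response at intervals $t_1 < t_2 < \dots$ with one fixation event, well
$k$ is stimulated at $T - t_k$ and everything is fixed at the common
endpoint $T$ (recorded in the program's `endpoint_s` attribute).

Message countdowns are only loosely specified by the hardware docs; here a
command's message appears at its start time, ticks once per second for the
command's duration, and (optionally) ends in a buzzer.

## Optics

Each LED is a generalized-Lambertian point emitter: radiant intensity
$\propto \cos^m\theta$, giving plane irradiance

$$E(r, h) = S\,\frac{h^{m+1}}{(r^2 + h^2)^{(m+3)/2}},$$

with $S$ fixed per channel so one full-intensity LED delivers the calibrated
on-axis power density at the calibration height. The only calibrated channel
is blue: 135 µW/cm², which we interpret as the on-axis value at $h = 2$ mm —
the sample height of a 96-well plate bottom; the measurement geometry behind
the figure is not documented, so both the constant and the height are
configurable. Red and green have no published calibration and therefore
contribute no physical irradiance (with a warning) until the user supplies
one. Fields superpose linearly over LEDs. Integration is midpoint-rule grid
summation at a default 0.25 mm resolution — deterministic and documented,
no Monte Carlo.

Homogeneity within a well is $V = 1 - E_{\min,\mathrm{edge}} / E_{\mathrm{center}}$,
the maximal fractional drop from well center to rim. "Intensity variation at
the well edge" could also be read as a global max-vs-min; we chose
center-vs-edge-minimum and document it. Spillover is the fraction of
integrated irradiance landing in *other* wells' footprints. Together they
encode the device's geometric trade-off, which the model reproduces: over
$h \in [1, 20]$ mm, $V$ strictly decreases while spillover is nondecreasing.

The exponent $m$ (default 1) is a free parameter; `calibrate_emission()`
bisects $m \in [0, 200]$ to hit a target $V$ at a given height (converging
both $V$, within $10^{-3}$, and the $m$-bracket, within $10^{-4}$ relative —
the latter because $dV/dm$ is shallow at small $m$). One honest limitation
falls out of the physics: the hardware's reported 25% edge variation at
$h = 2$ mm is *unreachable* by any point emitter — the most uniform case,
$m = 0$, already gives $V \approx 0.47$ for the 2 x 2 block in a 6.38 mm
well. Real LEDs are extended dies behind a diffusing package, which is more
uniform at close range than any cosine-power point source. We keep the
point-emitter model (it is simple, calibratable and right at moderate
heights), let `calibrate_emission(0.25, h = 2)` fail loudly with a
calibration error, and treat planted-exponent recovery — exact to within
0.01% — as the model's correctness check instead.

Dose is the time integral of in-well mean irradiance over the 1 Hz frames:
10 s of the full blue calibration irradiance is
$135\ \mu W/cm^2 \times 10\ s = 1.35\ mJ/cm^2$. A well's `lit_seconds`
counts seconds its *own* LEDs are on, while its dose integrates everything
reaching its footprint, spillover included.

## Heating

Medium temperature rise is a deliberately minimal first-order model:
$\Delta T(t) = G \cdot d \cdot (1 - e^{-t/\tau})$ with duty cycle $d$. The
published observation is qualitative — more frequent stimulation heats more,
with a plateau after about an hour — so $\tau = 1200$ s is chosen to be
$\ge 95\%$ saturated at one hour, and the gain $G$ has no anchored default
(1 K nominally). This module is an estimate, clearly not a measurement.

## What the generators emulate — and what they don't

`random_program()` draws valid programs (wells, rows, columns, rectangles;
single-channel colors; non-overlapping repeats) deterministically from a
seed; it is the workhorse of the property suites (round-trips, oracle
equivalence, bounds). The packaged presets reproduce the printed parameters
of characteristic experiments: phase-shifted 3 s/5 min pulse groups over
1 h, a 12-point/2-min staggered time course, a 2 s-pulse 1-min fixation
ladder, and the 84-min high/low-frequency pulse trains. The fixation ladder
preset encodes 12 wells; the original experiments spread related schemes
over up to 86 wells of a plate, and those full plate maps are deliberately
not reproduced. None of this emulates biology: no actuator kinetics, no
reporter dynamics, no cell-to-cell variability — passing tests certify the
scheduling and the physical model, not biological effect sizes.

## Numerical choices and test problem sizes

Deterministic throughout: no randomness outside seeded generators; snapping
uses round-half-up (`floor(x/p + 0.5) * p`) to avoid banker's-rounding
surprises; strict inequality for the center-within-radius rule (an LED
center exactly on the rim is out). Timeline correctness is checked against a
brute-force per-second simulator on 100 seeded random programs (3 commands,
~1-2 min horizons); serialization round-trips on 200; flux conservation is
verified by integrating a single-LED field over a 240 mm window to 2%. These
sizes keep the full suite under a couple of minutes while exercising every
code path; the properties they check are size-independent.

## Known limitations

- The CSV dialect and target spellings are not firmware-portable (above).
- Messages containing the field separator are not quoted/escaped.
- The optics ignore refraction by the plate bottom, reflection off well
  walls, and medium absorption; flasks are only a rectangular region target.
- The thermal model is spatially unresolved and its gain is nominal.
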