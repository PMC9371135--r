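---
title: "Emulating an aeroponic greenhouse monitoring stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating an aeroponic greenhouse monitoring stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerofog)
```

## What this package models

`aerofog` is a software twin of an IoT monitoring system for an aeroponic
greenhouse: lettuce grown suspended over a two-tank nutrient loop, misted by
sprinklers, watched by climate sensors and cameras, and managed by a set of
fog-layer microservices that aggregate telemetry into a quota-limited cloud
time-series store. The physical greenhouse is replaced by a synthetic device
layer; everything downstream of the sensors -- scheduling, packing, health
accounting, storage semantics, water-stress analytics, remote-command
encoding, and root-image enhancement -- is implemented as it operates in the
real deployment, so the full stack can be exercised, fault-injected and
tested on a desk.

## The water-stress model

The core analytic is the leaf-to-air vapor pressure deficit. Saturation
vapor pressure follows the FAO-56 Tetens form

$$P_{sat}(T) = 0.6108 \, e^{17.27\,T/(T + 237.3)} \quad \text{[kPa]},$$

and the deficit mixes the crop (leaf) temperature $T_c$ into the saturation
term and the air temperature $T_a$ into the actual-vapor term:

$$\mathrm{VPD} = P_{sat}(T_c) - \frac{RH}{100} P_{sat}(T_a).$$

A second, base-10 exponential form in pascals
($610.7\,[10^{7.5 T_c/(T_c+237.3)} - \frac{RH}{100} 10^{7.5 T_a/(T_a+237.3)}]$)
is implemented for cross-validation only: since $17.27/\ln 10 = 7.5006$, the
two forms agree to within about 0.2 % wherever the deficit is not vanishing.
Near the VPD sign crossing both exponentials cancel, so relative agreement
is meaningless there; the test suite asserts 0.2 % relative agreement
wherever $|\mathrm{VPD}| \ge 0.05$ kPa and an absolute bound of 0.002 kPa
everywhere on the $(T_c, T_a, RH)$ grid. All user-facing output reports the
kPa form.

Two categorical markers accompany the deficit. The crop-air temperature
difference $DT_{la} = T_c - T_a$ is classified against the arid-region field
bands: $[+4, +6]$ degC is water stress, $[-4, -1]$ degC is no stress, and --
because the published bands do not cover the whole line -- everything else,
including the gap $(-1, 4)$, is reported as *indeterminate* rather than
forced into a band. VPD above 1 kPa is *potentially harmful* (read strictly,
so exactly 1 kPa is still favorable), 0.5--1 kPa is the *favorable* window,
and below 0.5 kPa is *intermediate*.

Two modelling choices here were genuinely open and are pinned by tests
rather than by the source description: summary tables use the sample
standard deviation ($n-1$ denominator), and extremum-time ties break to the
earliest timestamp. Which humidity feeds the VPD equation (ambient or crop)
is also not stated explicitly in the deployment; the default is ambient
(`RHa`) with a `rh_source = "crop"` switch. Negative VPD values, which
arise when the leaf is much cooler than the air at high humidity, are
reported as computed and flagged, never clipped.

```{r vpd}
vpd_kpa(Tc = 25, Ta = 25, RH = 50)
classify_vpd(c(0.4, 0.7, 1.0, 1.3))
classify_dtla(c(-2, 0, 5))
```

## The synthetic device layer

The simulator's defaults *are* the deployment's stated world: the observed
climate extrema of a seven-day lettuce run (ambient temperature
6.47--34.19 degC peaking at 12:52 and bottoming at 07:01, ambient humidity
5.87--97.43 %, luminosity up to 9118 lux peaking at 12:23, crop-air
difference within $[-4.63, +0.24]$ degC), an 83.5 L main tank charged with
50 L of solution, a 21.5 L recirculation tank, a 160 L/h transfer/mixing
pump, irrigation every 24 min for 30 s, nine camera shots per day, and 30 s
sensor polling.

Design choices where the deployment is silent:

* **Diurnal shape.** A plain sinusoid cannot peak at 12:52 *and* trough at
  07:01, so each variable follows a piecewise half-cosine between its
  configured trough and peak times -- the simplest smooth periodic curve
  that attains both stated extrema exactly. Noise is added per variable and
  clipped to the configured range, so bounds hold for every seed.
* **Crop humidity** has no stated dynamics; it is ambient humidity plus
  bounded offset noise.
* **Leaf offset.** $T_c - T_a$ dips during daylight (transpirative cooling,
  matching the observed midday minimum and midnight maximum) via the same
  daylight arch that drives luminosity.
* **Tanks.** Level sensors report liters directly (no tank geometry is
  published, so the ultrasonic distance-to-volume conversion is abstracted
  away). Per-sprinkler flow is unpublished; the default draw is 6 L/h with
  a 0.95 return fraction. Plant uptake/evaporation is a constant
  configurable rate (default 0) tracked in an explicit accumulator, so
  total liquid $L_{sol} + L_{res} + \text{loss}$ is conserved exactly and
  testably (to $10^{-9}$ L over 1000 random steps). Tank temperatures relax
  toward ambient with a one-hour time constant.
* **Time** is timezone-naive local clock time; daylight spans 06:30--19:00
  (consistent with the observed "practically no sunlight after 19:00" and
  the late-autumn setting).
* **Randomness.** Every stream (temperature noise, humidity noise, root
  strands, ...) derives its own seed from the root seed through a fixed
  documented rule, so adding a stream never perturbs another and equal
  configurations give bit-identical output.

What the generator does *not* emulate: radiative/energy-balance physics,
plant growth, weather fronts, sensor drift or calibration error. A green
test therefore establishes that the downstream services and analytics are
correct over realistic-shaped telemetry -- not that the simulator predicts
a real greenhouse.

```{r sim}
cfg <- sim_config(noise_sd = 0)
sim <- simulate_greenhouse(cfg)
summarize_series(sim$climate$t, sim$climate$Ta, "Ta")[, 1:5]
```

## Fog services and failure semantics

The irrigation service fires every `frequency_min` minutes (phase anchored
at the window start, which the deployment leaves unstated) for `on_time_s`
seconds. The reservoir service switches the transfer pump on strictly above
16 L; the turn-off level is unpublished, so the service uses a configurable
hysteresis low setpoint (default 0.5 L), after which the mixing pump runs
for a configurable time. The camera service emits a status pulse at each
scheduled shot: 3 normal, 2 upper-camera flaw, 1 frontal-camera flaw, 0
service down (the published mapping is stated once and could also be read
as a bitmask; the literal reading is implemented). The sensor service packs
the eight environmental readings into one write per 30 s cycle and encodes
per-sensor success into the 0--255 health register; bit order follows the
environmental channel's field order (`Ta_htu`, `Ta_mlx`, `Tc`, `RHa`,
`RHc`, `Lum`, `T_res`, `L_res`), which the deployment never fixes. Missing
readings serialize as explicit NA/empty cells, never 0 -- a zero would be
indistinguishable from a valid reading of 0.

Failure detection mirrors the deployment's visual diagnostics with two
configurable thresholds: a periodic service fails when silent for more than
`miss_factor` (default 2) expected periods; a sensor is flagged when its
register bit is 0 in at least `theta` (default 0.5) of samples; scheduled
(camera) services fail on runs of `miss_factor` consecutive missed shots,
and a camera flaw is a stagnation of its degraded status code. The
recirculation pump is deliberately excluded from the default expectations:
its cadence depends on tank fill (days at the default duty cycle), so
silence carries no evidence of failure. Alerts are one per new finding,
idempotent across repeated reports, with a pluggable transport (JSON-lines
log by default; real SMTP is out of scope).

## Channel store and command vector

The store emulates the free-tier cloud semantics: four channels of up to 8
numeric fields (32 slots, 27 allocated -- the exact allocation is this
package's own, since the deployment does not enumerate its 27), a 15 s
per-channel minimum update interval, and a pooled quota of 8200 accepted
messages per calendar day. Rejected writes are logged, never partially
applied. Storage is an in-memory index with lossless CSV export/import (17
significant digits); service state snapshots persist as JSON rather than
binary logs.

The 10-bit command word carries eight payload bits (irrigation,
recirculation, mixer, camera trigger, config write/read, two reserved), an
attended bit, and an even-parity bit, always computed rather than
caller-supplied. The parity choice and the payload bit order are this
package's, as only the 10-bit layout (command bits, then status bit, then
parity bit) is published. Every single-bit corruption of every valid word
is detected; even-count corruptions are undetectable by construction, and
no correction is attempted.

```{r codec}
w <- encode_command(command_state(irrigation = TRUE, camera_trigger = TRUE))
w
mark_attended(w)
decode_command(mark_attended(w))
```

## Root-image enhancement

The imaging pipeline converts RGB to HSV, segments background hues
$H \in [35, 140]$ and high intensities $V \in [100, 255]$, ANDs the
intensity mask with the negated hue mask, and applies 2x2 morphological
filtering; the result is the root mask and its complement the background
mask. Numerical conventions: hue is quantized on the 0--179 scale (the
band's upper end, 140, exceeds no bound there, while on 0--360 it would cut
into the greens; the scale is configurable), band membership is inclusive,
and "morphological filtering" is implemented as *opening* -- the
noise-removal reading -- with closing available behind a flag. Opening pads
the border with background; closing pads its erosion with foreground so it
never eats the image edge. Whether the published HSV output masks the root
or the background is ambiguous, so both the masked HSV array and an RGB
rendering are returned.

The synthetic generator draws dark reddish strands (hue below 20, width
2--4 px) over a bright greenish background (hue around 75), with a
pixel-exact truth mask. Strands at least 2 px wide survive the 2x2 opening,
which is why clean fixtures score Dice >= 0.9; 1-px structures would be
(correctly) removed as noise.

```{r imaging}
truth <- synth_root_image(128, 128, root_fraction = 0.2, seed = 1)
enh <- enhance_root(truth$image)
dice_score(enh$root_mask, truth$truth_mask)
```

## Degenerate inputs and numerical edges

* `sat_vapor_pressure()` rejects temperatures at or below -237.3 degC (the
  Tetens pole); humidity outside [0, 100] is an argument error.
* Empty series cannot be summarized; all-NA series are likewise rejected.
* Transfers in the tank model are limited by source volume and destination
  headroom, so clipping can never destroy mass; overflow routes to the loss
  accumulator.
* `dice_score` of two empty masks is defined as 1.
* Channel CSV import reports the offending line number on the first
  non-numeric cell.

## Known limitations

The simulator is phenomenological: it reproduces stated ranges and timing,
not greenhouse physics, and the published seven-day experimental statistics
are used only as its defaults, never reproduced as results. The failure
detector's thresholds trade recall for precision at their defaults and are
exercised only on injected faults with durations beyond those thresholds.
The store is single-process and in-memory; no network API or real cloud
client is provided. Leaf-area-index processing and thermographic
temperature extraction are out of scope.

## Reproducing the protocol numbers

`scripts/acceptance.R --seed N --out f.json` recomputes, by running the
package: the all-success health-register value (8 simulated sensors), the
reservoir turn-on level (0.01 L ramp), and the harmful-VPD boundary
(0.001 kPa grid scan). The test suite additionally pins every cadence count
(2880 writes/day, 9 captures/camera, 60 irrigations/day), the exhaustive
codec sweeps, the quota/rate semantics, and the property suites described
above.
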