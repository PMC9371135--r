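# aerofog

Software emulation of an IoT monitoring stack for an **aeroponic
greenhouse** — for researchers in controlled-environment agriculture and
engineers of greenhouse telemetry systems who want to exercise the full
acquisition → fog-services → cloud-store → analytics chain without
hardware.

A synthetic device layer stands in for the greenhouse: diurnal climate
telemetry (ambient/crop temperature and humidity, luminosity), a two-tank
nutrient-solution loop with irrigation and recirculation pumps, injectable
sensor/service/camera faults, and synthetic root images with ground-truth
masks. On top of it the package implements, as they operate in a real
deployment:

* **Fog microservices** — irrigation scheduling (every 24 min for 30 s by
  default), threshold-triggered reservoir recirculation (pump on strictly
  above 16 L, hysteresis off), a nine-shot camera schedule with status
  codes (3 normal / 2 upper flaw / 1 frontal flaw / 0 down), 30 s sensor
  polling packed into single 8-field writes, failure detection by pulse
  absence and stuck-at-0 register bits, and idempotent alerting.
* **Sensor-health register** — one byte, bit *k* = 1 iff sensor *k* read
  successfully; all-success encodes to 255.
* **Channel store** — four 8-field time-series channels (32 slots, 27
  allocated), a 15 s per-channel rate limit, a pooled 8200 messages/day
  quota, request counters, and lossless CSV export/import.
* **Water-stress analytics** — Tetens saturation vapor pressure
  `Psat(T) = 0.6108·exp(17.27·T/(T+237.3))` kPa, leaf-to-air vapor pressure
  deficit `VPD = Psat(Tc) − (RH/100)·Psat(Ta)` (plus the equivalent base-10
  Pa form for cross-validation), `DT_la = Tc − Ta`, and the categorical
  bands: VPD > 1 kPa potentially harmful, 0.5–1 kPa favorable;
  `DT_la ∈ [4, 6]` °C stress, `[−4, −1]` °C no stress.
* **Command codec** — the 10-bit remote-operation word: 8 payload bits, an
  attended-status bit, an even-parity bit; detects every single-bit
  corruption.
* **Root imaging** — HSV segmentation (background hue band (35, 140) on the
  0–179 scale, intensity band (100, 255)), mask algebra, 2×2 morphological
  opening, RGB/HSV enhanced outputs, and Dice scoring against ground truth.

## Worked example

```r
library(aerofog)

cfg <- sim_config()                      # defaults = the deployment's stated world
sim <- simulate_greenhouse(cfg)          # one day, 2880 samples at 30 s
m   <- compute_stress_markers(sim$climate)
summarize_series(m$t, m$VPD, "VPD")
#>   variable      minimum  maximum     mean      std clock_max clock_min
#> 1      VPD -0.002071485 4.170012 1.583075 1.455355     15:18     07:54
table(m$stress_vpd)
#>    favorable      harmful intermediate
#>          320         1467         1093
```

The VPD peaks above 4 kPa in mid-afternoon and only dips into the
favorable 0.5–1 kPa window around dawn and dusk — the signature of a
water-stressed day under the default (observed-extrema) climate ranges.

```r
w <- encode_command(command_state(irrigation = TRUE, camera_trigger = TRUE))
w                  #> 9    (bits 0 and 3; parity already even)
mark_attended(w)   #> 777  (attended bit 8 set, parity bit 9 recomputed)

truth <- synth_root_image(128, 128, root_fraction = 0.2, seed = 1)
enh   <- enhance_root(truth$image)
dice_score(enh$root_mask, truth$truth_mask)
#> [1] 0.9264778
```

`run_pipeline(days = 1, seed = 42, out_dir = "out/")` chains everything —
simulation, services, store accounting, analytics, failure detection,
alerts, imaging — and writes telemetry CSVs, the twelve-report suite,
`stress_markers.csv`, `alerts.jsonl` and the enhanced PNGs, bit-identically
for a given seed. A thin CLI over the same functions lives at
`inst/cli/aerofog.R` (subcommands `simulate`, `analyze`, `report`,
`enhance-root`, `record-manual`, `decode-command`).

## Channel CSV / JSON formats

Channel exports are RFC-4180 CSV with header `timestamp,<field1>,…`,
ISO-8601 timestamps and 17-significant-digit numbers (lossless round
trip); missing readings are empty cells, never 0. Alerts are JSON-lines;
configurations serialize as JSON documents.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the stack's protocol constants from scratch by running the
installed package: the health-register value of an all-success polling
cycle over eight simulated sensors, the reservoir pump's turn-on level
located by a 0.01 L upward ramp, and the harmful-VPD decision boundary
located on a 0.001 kPa grid, and writes them as JSON.
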