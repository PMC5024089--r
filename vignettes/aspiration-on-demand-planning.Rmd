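---
title: "Planning aspiration-on-demand multimaterial prints: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning aspiration-on-demand multimaterial prints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aodprint)
```

## The deposition model

Aspiration-on-demand printing assembles each extruded filament *before*
deposition: liquid inks are drawn sequentially into one glass capillary,
gel in place as the temperature falls, and the whole column is extruded in
a single stroke. The planning problem is therefore different from
conventional multi-nozzle toolpathing — each filament is itself a
multimaterial object, and the planner's job is to decide, for every
filament, which inks to aspirate, in what order, and in what amounts.

`aodprint` models this with four assumptions, each of which is also a
tested contract:

1. **Fixed bore.** The capillary inner diameter (default 0.5 mm) is
   constant, so volume bookkeeping reduces to column *lengths*:
   `V = L · πd²/4` (`segment_volume`). Plunger displacement maps 1:1 to
   column length because the plunger runs in the same bore.
2. **LIFO column.** Ink enters and leaves through the tip, so the
   last-aspirated ink deposits first. The planner aspirates segments in
   the reverse of their deposition order. The hardware schematics this
   models show the step sequence but never state the reversal explicitly;
   we fix it as a contract and test it with an asymmetric two-segment
   filament, whose deposited order flips if the reversal is removed (a
   palindromic pattern would mask the defect).
3. **Finite column.** The total column, including any transient
   over-aspiration for waste steps, must fit the capillary length
   (default 85 mm). The planner raises a structured capacity error rather
   than splitting filaments, because the behaviour of the physical system
   when a filament exceeds one stroke is not documented; splitting would
   invent semantics.
4. **Sharp interfaces in the raster.** The mixed transition zone between
   consecutive segments is real (hundreds of µm) but is reported as a
   per-interface length estimate, not painted into the reconstructed
   label map. Rasterizing a composition gradient would claim more than
   the measurements behind the estimate support.

## The transition-zone policy and waste accounting

The interface between two sequenced segments is controlled by extruding a
small length of the previously aspirated ink into the next ink's
reservoir immediately before the next aspiration (`tzl_policy`). Two
knobs exist, both bounded by the hardware's characterized range:

| parameter | units | range | default | role |
|---|---|---|---|---|
| `pre_extrusion_displacement` | µm | 0–500 | 0 | length wasted at each switch; larger ⇒ smoother, longer transition |
| `plunger_speed` | mm/min | 50–100 | 50 | aspiration rate; 100 risks turbulent flow |

The default of 0 µm reflects that filament integrity at the interface is
preserved even with zero pre-extrusion, while any pre-extrusion costs
reservoir contamination; users opt into smoother transitions explicitly.

`estimate_tzl` is deliberately a *calibration placeholder*: TZL =
baseline (50 µm) + displacement, inflated ×4 at 100 mm/min, with the
"millimeter-scale mixing" flag when the estimate reaches 1 mm. The
underlying characterization is qualitative (monotone growth with
displacement; severe mixing at high speed and displacement), so the
function guarantees exactly those ordinal properties — monotonicity on
the whole 0–500 µm grid at both speeds is tested exhaustively — and the
constants are exposed through the `calibration` argument rather than
asserted as physics.

Waste accounting forced one genuine design decision. The waste step
ejects the *most recently aspirated* ink (it sits at the tip), so if the
planner aspirated exactly the designed segment length, every wasted µm
would shorten a deposited segment. `plan_filament` therefore
over-aspirates by exactly the waste displacement any segment that will be
followed by a waste step. The consequences, all tested:

- net bookkeeping: Σ aspirated − Σ wasted = filament length;
- per-ink conservation in the simulator: deposited + waste = aspirated,
  to 1e−9 mm³;
- the deposited map carries the *designed* segment lengths, so
  axis-aligned fixtures reconstruct with fidelity 1.0 even at the maximal
  500 µm waste setting;
- the capacity margin is one waste displacement (the only moment the
  column exceeds the designed total is between an over-aspiration and its
  waste step).

## Slicing and segment extraction

Layers are decomposed into parallel scan lines at pitch
`filament_diameter + gap`, lane centers at `pitch/2 + k·pitch` — symmetric
coverage, `floor(extent/pitch)` lanes. Orientation is restricted to
0°/90°: the patterns this targets are axis-aligned, and arbitrary-angle
scanning would complicate the raster contract for no tested benefit.
Choosing the orientation automatically (e.g. to minimize jagged edges) is
left to the user; the package only exposes the parameter.

Segments are extracted by sampling ink labels at pixel centers along the
centerline and run-length encoding them. Boundaries therefore sit on
pixel-cell edges — the grid is the ground truth, and sub-pixel edges are
unresolvable by construction. Cells are half-open `[x, x+px)`, so every
point belongs to exactly one pixel and a boundary point belongs to the
+x/+y side; this single convention makes `ink_at`, the rasterizer, and
the geometry loader mutually consistent (round-trips are bit-exact).

Runs shorter than `min_segment_length` are merged into their longer
neighbor, iterating from the shortest run, with ties going to the
*preceding* segment (a deterministic rule; some rule is needed and
deposition order is the natural tiebreak). The default of 0.5 mm encodes
the practical observation that below some length a region cannot be
aspirated without extensive interfacial mixing; no measured value exists,
so we chose one filament-diameter as a conservative engineering default.
With `min_segment_length = 0`, `extract_segments` must equal a
brute-force per-pixel RLE oracle exactly; that equivalence is tested over
three dissimilar fixtures.

## The virtual printer

`simulate` re-executes emitted G-code rather than replaying plan objects,
so the round trip emit → parse → execute is itself under test. The
dialect (G21/G90, X Y Z A, F, `;` comments, 4 decimals) is a declared
minimal Mach3-compatible subset — the actual macro set of the original
control stack is unknown, so the simulator validates strictly and errors
on any word outside the subset, with line numbers.

The simulator identifies aspirated inks *positionally*: a negative A move
is an aspiration of whatever reservoir the tip currently occupies. This
keeps the G-code free of out-of-band metadata and makes the simulator a
genuine independent check on the planner's reservoir routing.

Painting uses pixel-center membership in the swept rectangle (projection
within `[s0, s1)` along the move, perpendicular offset within
`[−d/2, d/2)`), which together with lane centering makes an axis-aligned
plan reconstruct its target exactly when the pattern's boundaries lie on
lane boundaries — the sharp-edge property that motivates single-filament
multimaterial deposition in the first place. Filaments are square-ended;
end-caps and die swell are not modeled.

## Ink physics

*Power-law rheology.* `fit_power_law` linearizes η = K·γ̇ⁿ⁻¹ and solves
by OLS in log–log space. This is the standard, deterministic estimator
for flow indices; a nonlinear fit in linear space would weight the
low-shear decade (where η spans orders of magnitude) arbitrarily. On
noise-free synthetic sweeps the fit recovers (K, n) to solver precision —
the parameter-recovery sweep covers K ∈ {0.5, 12, 300} × n ∈ {0.26, 0.3,
0.7}.

*Gel point.* `find_crossover` locates sign changes of log G′ − log G″ and
interpolates linearly in log space, which is exact for log-linear moduli
(the synthetic generator's construction, hence an analytic oracle). With
multiple crossings the highest-temperature one is returned: cooling from
the reservoir, that is the first gelation encountered, which is the
event that matters for printability.

*Modulus.* `fit_modulus` is a zero-intercept least-squares slope on the
0–4 % strain window (σ = E·ε with prestrain removed); the free-intercept
variant exists behind `intercept = TRUE` for uncorrected curves. Points
beyond the window never touch the fit — tested with a strain-hardening
tail.

*Series conductivity.* Segments in series with a common cross-section
give σ_eff = ΣLᵢ / Σ(Lᵢ/σᵢ), the length-weighted harmonic mean, bounded
by the segment extremes and strictly decreasing as the low-σ middle
segment of the 24 mm three-segment designs (middles 4/8/12 mm, heads
10/8/6 mm) lengthens. Measured filaments deviate from this expectation —
plausibly an interface effect — and the package deliberately does *not*
model that deviation: an `interface_resistance` hook exists, defaulting
to zero, so users can explore it without the package asserting a value
nobody has measured.

*Temperature.* `printability_window` is max(gel points) + margin up to a
ceiling: with the standard agarose/SWCNT ink set (crossovers below
45 °C, margin 5 °C) the window contains the 50 °C reservoir setting, and
with the low-melting bio-ink pair (crossover 35 °C, margin 3 °C, ceiling
38 °C for cell viability) it pins to exactly 38 °C.
`switching_temperature_drop` replaces transient finite-element analysis
with lumped-capacitance Newtonian cooling T(t) = T_env + (T₀−T_env)e^(−t/τ)
— appropriate because the Biot number of a sub-millimeter liquid column
in glass is small and the only question the planner asks is binary:
does the column cross a gel point during a switch of a few seconds?

## What the synthetic fixtures do and do not show

The generators reproduce the *checkable structure* of the canonical
builds — band orders, palindromic center sequences (7 segments, 6
switches for four inks), the 4/8/12 mm conductivity designs, the
six-filament striped cell pattern with four 3-segment filaments, the
two-layer "T" — and the defining equations of the measurement curves
(power-law sweeps over 0.01–100 s⁻¹, log-linear gelation curves crossing
at a prescribed temperature, linear-to-4 %-then-plateau stress–strain).
Absolute dimensions of the showcase objects were never published, so
band widths and extents are parameters with field-plausible defaults
(3 mm bands, 0.1 mm pixels = 5 pixels per filament width), and only the
topological counts are treated as anchored facts.

Passing tests on these fixtures therefore demonstrates that the
*planning algebra* is correct — ordering, volumes, conservation,
reconstruction — not that a physical print would match: real inks mix at
interfaces, filaments have round ends and finite wetting, and gelation
kinetics are not instantaneous. Noise models (log-normal multiplicative
on viscosity, additive Gaussian on stress) are conventional choices for
strictly positive and instrument-limited quantities respectively, not
fitted error models.

## Numerical choices and degenerate inputs

- Lengths are mm doubles throughout; conservation assertions use 1e−9
  tolerances (mm or mm³), far above double rounding at these magnitudes.
- Segment-sum validation in `filament_plan` tolerates 1e−9 mm.
- Label images store one integer per ink (8-bit, ≤255 inks) with a JSON
  sidecar; no RGB inference, so round-trips are bit-exact.
- Empty segment lists: `check_capacity` returns ok with column 0;
  `count_switches` errors (a filament with no segments is a planning
  bug, not a boundary case).
- Zero-length filaments are dropped by `plan_build` with a warning.
- `G' = G''` exactly at a sample counts as a crossing at that sample.
- Degenerate three-segment designs (`middle == total`) collapse to a
  single segment rather than emitting zero-length heads.

## Problem sizes

The shipped tests run the full chain on 24 × 24 mm layers at 0.1 mm
pixels (240×240 grids, 48 filaments) and simulate complete builds at
0.1–0.2 mm raster resolution; the acceptance script fits 50-point sweeps
and 61-point cooling curves. These sizes exercise every code path while
keeping the whole suite under a minute on one core; all operations scale
linearly in pixels × filaments.

## Known limitations

- No mesh/STL slicing; inputs are label grids or rectangle geometries.
- Orientation limited to 0°/90°; no automatic orientation selection.
- No fluid-dynamic model of interfacial mixing; TZL is an ordinal
  estimate with placeholder constants.
- No acceleration/jerk or timing model in the simulator; feeds are
  carried through but not integrated into a clock.
- Filaments exceeding one capillary stroke error out rather than being
  split across re-aspirations.
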