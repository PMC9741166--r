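---
title: "Multidimensional rose charts: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional rose charts: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirose)
```

## The chart model

A rose chart encodes a complete `n_cat × n_attr` grid of finite,
non-negative values. Negative values are rejected at load time — the
radial encoding has no meaning for them and the motivating use cases
(rates, counts) never produce them — and missing cells are an error
rather than being imputed, because the equal-angle partition assumes a
full grid. Zero values are legal and draw a petal of zero radial extent.

The package separates *layout* (a `chart_model`: petal geometry in
abstract chart units and degrees, resolved colours, labels, legend,
centre text) from *rendering* (SVG, or the JSON export for external
front ends). Everything downstream of `rose_chart()` is a pure function
of the model, which is what makes byte-identical output testable.

## Geometry

**Angles.** The flat layout gives each attribute a contiguous section of
`360 / n_attr` degrees and each category a slot of
`360 / (n_attr · n_cat)` degrees inside it; the stacked layout gives
each category a petal of `360 / n_cat` degrees. Model angles are
measured from the configurable start angle (default 0 = 12 o'clock),
increasing in the configured direction (default clockwise); the renderer
converts to canvas coordinates with `x = cx + r·sin θ`,
`y = cy − r·cos θ` on the y-down SVG canvas. With the default
`gap_deg = 0` the spans tile the circle exactly; a small gap can be
inset symmetrically at each boundary for legibility.

**Radii.** Two value-to-radius modes are provided because "petal size"
can reasonably mean either radial length or area, and the two disagree
visually — area-true encoding compresses large values, linear encoding
exaggerates them. The default is `area`:
`r = sqrt(r_inner² + (r_max² − r_inner²)·v/v_ref)`, the polar-area
convention under which a petal's annular area `(Δθ/2)(r_out² − r_in²)`
is proportional to its value (exactly, when `r_inner = 0`; tested to a
relative error below 1e-9). `linear` is the alternative for readers who
compare lengths. Both map 0 to `r_inner` and `v_ref` to `r_max` and are
monotone, so value order is always radius order within one chart.

**Reference maximum.** `v_ref` is the largest scaled value in the whole
table for flat charts and the largest per-category layer sum for stacked
charts. A single shared reference — rather than one per section — is
what makes petal sizes comparable *across* sections, which is the point
of the chart; it also guarantees the largest petal reaches `r_max`, so
clamping of over-reference values can only occur with a user-supplied
reference. Whether a per-layer reference would ever be preferable is a
genuinely open design point; the shared rule is the documented choice.

**Stacking.** Layer radii are cumulative: layer *k* spans from the
radius of the partial sum through *k − 1* to the radius of the partial
sum through *k*. Under linear mode each layer's thickness is
proportional to its own value; under area mode each layer's annular area
is. The layer order is a configurable permutation of the attributes
(default: column order from the centre outward). A single-attribute
stacked chart degenerates exactly to the flat rose of that attribute —
a tested equivalence.

**Scale factors.** Per-attribute positive multipliers (e.g. ×5 on a
small-valued rate) are applied to the *geometry only*, to keep small
petals visible next to large ones. Labels, the centre detail and the
colour normalisation always use unscaled values, so annotations state
the true numbers and shade ranks are unaffected (they would be anyway:
shading is normalised per attribute, and positive rescaling of a column
preserves its order).

## Colour

Each attribute receives a base hue by position; the default palette
starts red, yellow, blue, green and extends through purple, orange,
cyan, magenta, brown, grey. The built-in `"paper"` palette name refers
to this list; its hex anchors are conventional choices, documented as
approximate. Within an attribute, lightness falls linearly (in HSL
space, hue and saturation held from the anchor) from `light = 0.85` at
the column minimum to `dark = 0.35` at the column maximum — darker means
larger. The bounds keep petal fills distinguishable from the white
stroke and dark text at both ends. A constant column gets the midpoint
lightness. Single-axis lightness interpolation was chosen over a
perceptual (CIELAB) ramp as the minimal faithful reading of
"shades of one colour"; custom anchors are the hook for anyone needing
colour-blind-safe palettes. One numerical caveat: resolved colours are
8-bit hex, so values closer than ~1/255 in normalised lightness can
collapse to the same colour — the continuous lightness is strictly
monotone, the quantised one only weakly.

## Labels and sorting

Label *reduction* is the occlusion strategy: exactly one maximum and one
minimum label per attribute (a constant column gets a single `max`
label), placed at the petal mid-angle at `r_outer` plus a small offset.
Ties take the first category in row order — observable in the bundled
case study, where two categories share the death-rate value 1.18 —
and the same stable rule governs sorting. The only collision handling is
a deterministic radial push: labels are processed in attribute-then-kind
order, and a label whose anchor lies within 10° (circular) of an earlier
one moves outward by one text-height step per such neighbour. No general
overlap solver is attempted; with 2 labels per attribute none is needed.

Rounding in labels is half-even at `label_decimals` (R's `round`),
2 decimals and a `%` suffix by default.

Sorting permutes *occupancy*, never boundaries: flat charts sort each
attribute section independently by its own values, stacked charts sort
whole petals by a key attribute or the layer total. "Clockwise" places
the largest value first along the rotation direction, "counterclockwise"
the smallest; on tie-free data the two orders are exact reverses, and
sorting is idempotent.

## Rendering and determinism

SVG is the single output target: resolution-independent, text-based,
diffable in tests. Petals are closed paths of an outer arc, a radial
line, an inner arc (degenerating to the centre point when
`r_inner = 0`) and a close; spans above 180° are emitted as two arc
segments because a single SVG arc cannot express a full circle.
Coordinates are fixed at 4 decimals, element order is fixed, there are
no timestamps or generated ids, and the chart-model JSON is embedded in
a `<metadata>` block — identical models therefore render to
byte-identical documents, which the tests assert directly. The JSON
export uses 17 significant digits so doubles survive the text round-trip
exactly.

## The synthetic generator

`generate_matrix()` emulates case-study-shaped inputs: `n_cat × n_attr`
values drawn uniformly from a configurable range (default `[0, 100]`,
the natural range of percentage rates), or from a right-skewed standard
log-normal truncated at its 0.1%/99.9% quantiles and rescaled into the
range, for tables where a few cells dominate. Names are `C1…Cn` /
`A1…Am`; a fixed seed gives bit-identical output. The generator
reproduces the *shape* of real rate tables, not their structure: it has
no correlation between attributes, no time ordering and no ties except
by coincidence. Passing property tests on generated tables therefore
establishes the geometric and encoding invariants, not anything about
real epidemiological data.

The test suite runs its property batches on dozens of generated tables
per invariant and 1000 tables for the label-selection cross-check
(shapes 2–8 × 1–5); the acceptance script measures invariants on 200
tables. These sizes make the full suite complete in well under a minute
while exercising every degenerate shape (single row, single column,
zero cells).

## Command-line interface

`inst/scripts/rose.R` is a thin wrapper over `rose_cli()`, which parses
flags, loads the table, builds the model and writes SVG (and optionally
the model JSON), returning exit code 0 on success, 2 for bad arguments,
3 for validation failures, 4 for I/O failures. A flat `key = value`
config file mirrors the flag names, with flags taking precedence —
a deliberately schema-free format that stays diffable. `--demo` renders
the bundled case-study table; its ×5/×1.2 scale factors are applied only
under `--paper-scaling`, never silently.

## Known limitations

- No interactivity: hover detail, filtering and linked views are out of
  scope; the JSON chart model is the integration point for front ends
  that want them.
- No polar axis ticks or gridlines, no leader lines, no font metrics —
  label collision handling is geometric, not typographic.
- In area mode annular areas stay proportional to values for any
  `r_inner`, but the central hole (default `0.12 · r_max`) still
  distorts *perceived* petal length near the centre — a deliberate
  trade for the centre text; set `r_inner = 0` for the undistorted
  classic form.
- The lightness ramp is not perceptually uniform and the default
  palette is not verified colour-blind-safe.
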