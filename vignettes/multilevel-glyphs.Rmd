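---
title: "Multilevel cubic glyphs: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel cubic glyphs: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyphscape)
```

## The glyph model

glyphscape encodes one tabular record as one cubic glyph: a composite 3D
object whose channels — fills, heights, cap size and silhouette — each
carry one data variable. Channels are formalized as 16 *slots*
(`cubic_glyph_spec()`), each with a level of detail (1/2/3), a type
(color, geometry-size, geometry-shape), a Bertin scale capability
(nominal, ordinal, or both) and a length class (short/medium/long). Two
slot typings deserve a note: the cap's *size* slot is typed
geometry-shape and its *shape* slot geometry-size. That is deliberate in
the operative slot table — discrete size steps of the cap read as
silhouette changes and vice versa — and the validator treats both as
ordered channels, which is what matters for correctness.

Three assumptions shape everything downstream:

1. **Parallel projection.** Glyphs live on a 2:1 dimetric grid and are
   projected affinely (`project()`), never perspectively. Consequences:
   screen size is translation-invariant (so sprites can be cached and a
   pan never re-renders), and visual size comparisons between glyphs are
   valid anywhere on the canvas.
2. **Dominant-variable continuity.** The slot-1 color is the whole glyph
   at pixel level and remains the main cube's body color at iconic and
   detail levels, so semantic zoom never re-colors the scene's gestalt.
3. **Conjunctive filtering.** Subgroups are defined by per-variable
   ranges combined with AND; this matches per-attribute range sliders and
   keeps the selected histogram bar-wise dominated by the overall one.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `pixel_max_px` | 2 | px | below a 2×2 footprint only a colored cell is readable |
| `detail_min_px` | 64 | px | sub-elements need a 64×64 footprint to be legible |
| capacity short/medium/long | 10 / 25 / 256 | states | roughly ten hues or value steps are reliably distinguishable; medium and long are configuration keys for size- and position-like channels, not perceptual constants |
| `cell_w_px` × `cell_h_px` | 32 × 16 | px | classic 2:1 dimetric cell |
| `z_scale_px` | 8 | px per height unit | half a cell height per unit |
| quantization `steps` | 10 | steps | continuous variables on ordered slots are displayed in about ten graded increments |
| `max_height_units` | 2.5 | height units | occlusion rule: a front glyph may never fully bury the cap of the glyph behind it (see below) |
| `bin_years` | 5 | years | conventional age-pyramid class width |

LoD selection uses strict inequalities on both thresholds; the boundary
footprints 2 px and 64 px both map to iconic. The rule is monotone in the
footprint, which the suite checks property-style.

## Validation semantics

Per mapped slot: **red** when the data scale cannot sit on the slot
(nominal data on an ordinal-only channel, or ordered data on a purely
nominal channel such as shape); **yellow** when the scales fit but the
variable has more distinct values than the slot's length, and also when
an ordered variable is mapped to a hue slot with a categorical colormap
(hue alone carries no order; a sequential gradient restores it);
**green** otherwise. Continuous and interval variables are admitted on
ordered slots via quantization, and the length check then uses the
quantization step count, not the raw distinct count — mapping age to a
height is legitimate even though age has a hundred distinct values.
Overall status is the worst slot status. A mapped variable without
metadata is an error, not a verdict: the validator refuses to guess.
The suite checks the implementation against an independently written
brute-force rule interpreter over the exhaustive grid of scale × slot ×
distinct-count (1, capacity, capacity + 1).

## Layout choices that were genuinely open

* **Age-pyramid columns.** The column magnitude is stage rank + 1, so
  more advanced tumors sit further from the central axis; records with
  *missing* stage occupy column 1, right against the axis, because
  staging gaps are a finding to surface, not to hide. Collisions stack
  one column outward, turning counts into bar lengths. One consistent
  reading among several possible column rules; it keeps equal stages
  aligned across rows.
* **Row direction.** Placements store `gy` as the age bin; the row flip
  that puts age 0 at the pyramid's base happens at render time (screen y
  grows downward). Grouped layouts materialize the flip on a shared row
  scale so that group baselines align.
* **Group offsets.** In a dimetric view the screen-x axis is `gx - gy`,
  so grouped sub-layouts are shifted until their `gx - gy` ranges are
  disjoint, then moved back up-screen by adding the same correction to
  `gx` and `gy` (which leaves screen x untouched). Group bounding boxes
  provably cannot overlap.
* **Jitter.** Scatter collisions are resolved by a deterministic
  nearest-first spiral walk in dataset order — reproducible figures beat
  faithfully random jitter. Grid saturation is an error reporting the
  overflow count rather than silent stacking.
* **Painter order.** Ascending `gx + gy`, ties by `gx`, then record
  index. Ties at equal depth cannot occlude each other under the
  dimetric camera, so any consistent tie-break is correct; the suite
  verifies the order against an O(n²) pairwise occlusion oracle.

## Rendering and numerical choices

SVG is the reference output: coordinates are printed with a fixed
two-decimal format, so identical inputs give byte-identical files. PNG
uses a software rasterizer that samples pixel centers with an even-odd
test and no antialiasing; glyph anchors are rounded to integers, which
makes rasterization translation-invariant and the sprite cache exactly
transparent (cached vs uncached output is pixel-identical, asserted in
the suite). Sprite keys are the glyph's resolved polygon set plus zoom,
so two records with the same mapped values share one sprite.

Occlusion is controlled by three design rules: the most important
channel (the cap) sits on top of the geometry; total glyph height is
clamped to 2.5 height units; and the projection is parallel. With the
default grid, a worst-case packed block of maximal-height glyphs still
leaves a visible band of every cap — the suite rasterizes a packed 5×5
block with per-glyph unique cap colors and requires at least 3 visible
cap pixels per glyph. Body, cap and base default palettes are disjoint
in role (sequential gradient for the primary, categorical Okabe-Ito for
nominal slots) to avoid misleading secondary-color mixtures, and the
plinth is a neutral border that breaks up grid patterns.

Degenerate inputs: empty scenes render a background-only image; a canvas
smaller than the layout bounds is an error stating the required size;
values outside a declared domain are clamped to the nearest quantization
step under a countable warning condition; a record whose primary variable
is missing renders white at every level (the white-glyph convention for
missing staging), with the neutral plinth retained.

## What the synthetic generator does and does not emulate

`generate_cases()` draws sex (Bernoulli), age (normal truncated to
[0, 100], rounded to years), examination year (uniform), T-stage
(categorical, then blanked at a possibly sex-specific missing rate),
N/M/grading (weights shifted by T), death (Bernoulli per T class) and
disease-free survival (exponential per T class, truncated at follow-up).
These are the simplest forms that produce the phenomena the tool must
surface: pyramid-shaped age structure, cap-color mortality gradients,
white-glyph missing staging biased toward one sex (colon preset: male
0.15 vs female 0.05), and age entry errors injected at exactly 0 and
100. The presets (thyroid: 2109 cases, female-skewed, low mortality;
lung: 1782, male-skewed, high mortality; colon: 11000 across 1984–2004)
are qualitative emulations chosen once, not estimates of published
incidence; no calibration to real epidemiology is attempted, and
passing tests therefore demonstrate the *mechanics* on realistic
structure, not clinical validity. Determinism: one integer seed drives
the Mersenne-Twister with inversion sampling; the truncated normal is
drawn by inverse CDF so the consumed random-number count is independent
of the bounds.

## Problem sizes

The test suite and the acceptance script run cohorts of 25–20000
records; the figure-type reproductions use the preset sizes (3891 mixed,
11000 colon), chosen as the sizes at which the iconic and pixel levels
are respectively the natural rendering. Exhaustive validation checks
cover 192 cases; projection properties use 10⁴ random triples; painter
order 100 random instances of up to 100 glyphs.

## Known limitations

* No interactivity: filtering and highlighting are batch re-renders, not
  live coordinated views.
* LoD switching is discrete; no animated transitions between levels.
* The cap silhouette family (flat / bevel / pyramid) is a three-step
  interpretation of the cap-shape channel; finer shape gradations would
  need a documented extension of the geometry table.
* Only the cubic glyph family is implemented; the slot table is fixed at
  construction.
* The rasterizer is unantialiased by design (determinism first); SVG
  output is the right choice where print quality matters.
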