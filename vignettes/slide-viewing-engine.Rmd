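---
title: "Inside the slidecache viewing engine: pyramids, affine navigation and graded prefetching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside the slidecache viewing engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidecache)
```

## The problem

A diagnostic slide scan at 40× is on the order of 25,000 × 20,000 pixels —
far too large to transfer or hold in memory as a unit. Production viewers
therefore store the slide as a multi-resolution pyramid, serve only the
screen-sized region a pathologist is looking at, and hide network latency by
prefetching around the viewport. `slidecache` implements that whole pipeline
headlessly, so each layer — resampling, the request contract, the viewport
algebra, the cache policy, annotation anchoring — is an ordinary function
with a testable contract.

## The pyramid and magnification synthesis

A pyramid stores the slide at a decreasing set of magnifications; the
highest stored level **is** the scan, and every other level is derived from
it by nearest-neighbor reduction. Level dimensions follow
`ceil(base_dim × m / base_mag)`, so no level is ever empty and pixel counts
track `(m / base)²` up to rounding.

Requests may name *any* magnification `0 < m ≤ base`. The source is always
the stored level with the smallest magnification still ≥ `m` — synthesis
only ever discards resolution, never invents it — and the source crop is
reduced by the factor `m / source`.

**Nearest-neighbor convention.** Output pixel `i` (0-based) samples source
index `floor((i + 0.5) · n_src / n_out)`: the half-pixel-centre rule. It is
the least surprising of the common conventions (it is exact under identity
resampling, symmetric, and never reads out of bounds), and the test suite
pins it with an independent double-loop oracle rather than trusting the
vectorised implementation. Coordinates everywhere are 0-based, top-left
origin, half-open `[x, x + w)`; out-of-bounds pixels are white
(255, 255, 255), the screen background an uncovered viewer shows.

The intermediate stored levels are produced in software with the same
operator; a scanner that stored its own 10× pass would differ in pixel
content but not in any contract the engine relies on.

## The navigation algebra

Pan and zoom are homogeneous 3×3 affine transforms restricted to
translations and positive uniform scalings. Zooming about an arbitrary
focal point `p` (a pinch centred under the fingers) decomposes as

```
scale_about(s, p) = T(p) · S(s) · T(−p)
```

so `p` is a fixed point. A gesture is an ordered sequence `A₁ … Aₙ`; its
total effect is the product `Aₙ ⋯ A₁`, and the prefix products `Aⱼ ⋯ A₁`
are the intermediate states a renderer displays while the gesture is still
in progress (`intermediate_state()`). Composition equalities are asserted to
1e-9; the decomposition identity, being exact in floating point up to
association, to 1e-12.

`uncovered_screen_region()` answers the rendering question "which screen
rectangles lost content in this step?": with `D = after ∘ before⁻¹` the
screen-space delta, the uncovered set is
`(screen ∩ slide_footprint_after) \ D(screen)` — up to four axis-aligned
rectangles. A leftward pan of 300 px yields exactly the 300 px strip on the
right; a zoom-in about the screen centre yields nothing, because content
expands outward.

## The graded prefetch grid

The cache is a 9×12 grid of 256×256 px cells — 3072×2304 px, three screens
wide and three tall around a 1024×768 display. The central 3×4 block (rows
4–6, columns 5–8) is exactly the screen and loads at full resolution. The
periphery loads down-sampled, by pixel-*area* fraction:

```{r pattern}
default_resolution_pattern()[, 1:6] * 100  # left half; the pattern is symmetric
```

A fraction `f` cell fetches a source block of `round(256 · √f)` px per side
at the correspondingly reduced magnification — for `f = 0.25` at 40×, a
128×128 block at 20× — and enlarges it to the cell by nearest neighbor.
Two numerical choices live here:

- 12.5% and 6.25% have no exact isotropic integer source size
  (`256·√0.125 ≈ 90.51`); the request side is rounded (91 px, 64 px) so
  every request is realizable, while the **savings accounting uses the
  nominal fractions**, keeping the arithmetic of the pattern exact:
  summing the pattern gives 26.375 cell-equivalents over 108 cells, a
  loaded fraction of 26.375/108 ≈ 24.4213% and a saving of 75.5787…%,
  reported as 75.58%.
- Cells that fall beyond the slide edge come back white and are counted at
  their nominal fraction: the cache cannot know content from background
  without fetching.

Loading is modelled as a deterministic priority queue
(`load_queue_order()`): central cells first, then rings outward, ties by row
then column. Real viewers fetch asynchronously; a deterministic dequeue
order preserves the observable contract (central cells displayable first)
while keeping every test reproducible.

**Promotion and re-anchoring.** When navigation brings a down-sampled cell
onto the screen, `promote_visible()` re-fetches exactly that cell at full
resolution (idempotently — already-sharp cells are skipped), after which the
on-screen mosaic is bit-identical to one direct full-resolution region
request. The grid itself only reloads (`maybe_reanchor()`) when the screen
rectangle is no longer contained in the grid footprint. The description of
this rule could be read in either geometric direction; the reading
implemented — re-anchor when the *screen* escapes the *grid* — is the only
one consistent with the rule's purpose, preventing white backgrounds. With a
one-screen margin on every side (3072 − 1024 = 2 × 1024 horizontally,
2304 − 768 = 2 × 768 vertically), any single pan of at most one screen
width/height is absorbed without reload. On reload the new grid is centred
on the viewport at magnification `min(base, base · viewport_scale)`, so a
zoom-out session degrades gracefully to coarser levels while zoom-in is
handled by promotion alone.

Promotions are accounted as full-resolution loads on both counters
(`pixels_loaded` and `pixels_naive_equivalent`), preserving the invariant
`loaded ≤ naive` per event; the strategy-level comparison
(`compare_strategies()`) instead runs the whole trace twice — graded pattern
vs all-cells-full — which is the comparison the savings figure refers to.

## Annotations

Annotations (circle: centre + radius; rectangle: corner + extent) are stored
in **base-slide pixel coordinates** and never touched by viewport changes:
projection maps centres through the cumulative transform and multiplies
radii/extents by its scale, so slide and annotations visibly move as one
rigid object. Extents are kept at base magnification (rather than at the
magnification current when drawn) because it makes the anchoring invariant
exact rather than approximate. While an annotation is being edited the
session rejects viewport manipulation — the gesture stream belongs to the
shape — and editing deltas arrive in screen pixels and are divided by the
viewport scale. Resizing below 1 base pixel clamps instead of erroring:
a gesture overshoot should not destroy the annotation. Stores serialize to
JSON ordered by id; duplicate ids are a parse error.

## The synthetic slide generator

`generate_slide()` emulates an H&E-stained tissue scan with three spatial
scales: a low-frequency eosin-pink wash (3 sinusoids, amplitudes 6–14
intensity units), clusters of dark nucleus-like ellipses (≈1 cluster per
0.3 Mpx, ≈20 ellipses each, semi-axes 4–16 px — plausible nucleus sizes at
40×), and per-pixel uniform noise (±8 units). The noise floor guarantees
that any down-sampling changes at least 1% of pixels, which is what makes
"blurred cache cell" vs "full-resolution cell" a bit-level distinction the
tests can assert.

What it does **not** emulate: stain variation and scanner colour profiles,
JPEG compression artefacts, tissue folds and coverslip debris, and the
long-range anatomical structure a pathologist navigates by. Passing tests
therefore demonstrate the engine's geometric and accounting contracts, not
image-quality claims about real tissue.

## Problem sizes and defaults

| Parameter | Default | Why |
|---|---|---|
| screen | 1024 × 768 px | reference display of the target device |
| grid | 9 × 12 cells of 256 px | 3 screens in each direction; 12 cells on screen |
| stored magnifications | 40, 10, 1 | scan level plus two intermediate levels |
| tile size | 256 px | standard WSI/web-map tile size |
| reference slide | 4096 × 3072 px at 40× | smallest size holding a full grid at base magnification |

The test suite exercises three pyramid sizes (256×192 with 64 px tiles,
1024×768, and the 4096×3072 reference slide, built once and shared) and
randomized property checks under fixed seeds. Grid shape, cell size, screen
dimensions and the resolution pattern are all configuration
(`slidecache_config()`), so larger displays are expressible without code
changes.

## Known limitations

- No rotation: the manipulation group is translations and uniform scalings,
  which is what touch navigation of slides uses.
- No network model: latency, bandwidth and concurrency are outside the
  contract; asynchrony is reduced to the deterministic dequeue order.
- Nearest-neighbor display enlargement of peripheral cells (chosen for
  consistency with magnification synthesis) looks blockier than a bilinear
  viewer would; the choice is cosmetic for the accounting.
- The on-disk layout (PNG tiles + `pyramid.json`) is deliberately simple;
  vendor WSI containers are not parsed.
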