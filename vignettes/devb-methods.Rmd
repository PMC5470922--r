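---
title: "Methods: depth-extended sample-based background subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-extended sample-based background subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devibe)
```

## The model

`devibe` segments moving foreground from co-registered color + depth video
with a sample-based per-pixel background model. Each pixel `x` keeps `N`
raw observed values `M(x) = {v_1, …, v_N}`. An observation is background
when at least `λ` samples lie within Euclidean distance `R` of it (strict
`< R` on the distance, `≥ λ` on the count). Background pixels update by
random subsampling: with probability `1/ϕ` one uniformly chosen own sample
is replaced by the observation, and independently with probability `1/ϕ`
one uniformly chosen sample of one uniformly chosen in-bounds 8-neighbor is
replaced by the *current pixel's* value. Foreground pixels do not update,
which is what makes ghosts persistent in a color-only model.

The model is seeded from frame 1 alone: each pixel's `N` samples are drawn
uniformly with replacement from its 8-neighborhood plus itself (border
pixels use the clipped neighborhood). This makes frame 1 classifiable
immediately at the cost of absorbing any object present in frame 1 into the
model — the canonical ghost inducer.

Assumptions inherited from this family of models: a static camera, a mostly
static background, and foreground that differs from the stored samples by
more than `R` in the value space.

### The depth extension

Depth frames arrive in millimeters with 0 meaning "no reading" (hole). We
map them to a proximity image `d̂ = clip((max_range − depth)/max_range, 0, 1)`
with holes pinned to 0 — larger is closer, the way depth images are
usually displayed. The per-pixel uncertainty is `σ = 1 − d̂`: far surfaces
are measured less reliably by active-IR sensors, and holes are maximally
uncertain. Color (normalized per channel to `[0,1]`) and proximity fuse per
channel as

\[ w_d = (1-\sigma)\hat d,\qquad w_c = (1+\sigma)\hat c_k,\qquad
   \hat I_k = \tfrac12 (w_d + w_c), \]

so `σ = 1` yields the color channel exactly and `σ = 0` the average of
proximity and color; `Î ∈ [0, 1.5]`. The classifier then runs unchanged on
the fused 3-channel image. We deliberately fuse into three channels with a
shared depth term rather than appending depth as a fourth channel: it keeps
the matching radius `R` meaningful on a fixed scale and lets the entire
color machinery run unmodified.

A per-pixel depth model `MD(x)` is initialized from the first depth frame's
proximity. Foreground-classified pixels are given one extra chance: if
`MD(x) − d̂(x, t) > τ` — the modelled surface has *receded* — the pixel is a
ghost: it is stored as background and its sample model adapts (the usual
background-branch updates), but `MD(x)` itself is left alone. `MD(x)` is
refreshed only in the true background branch, riding the same `1/ϕ` coin as
the pixel's own sample replacement. Two consequences we consider essential:

* **Ghost excuses survive until the color model catches up.** If the ghost
  branch also refreshed `MD(x)`, the first coin fire would erase the
  evidence that the surface receded while the color model had accumulated
  only one matching sample (fewer than `λ = 2`), permanently stranding the
  pixel as foreground. Keeping `MD` stale during the ghost period means the
  excuse holds exactly as long as it is needed; once the pixel classifies
  as background through its colors, the background branch takes over and
  `MD` converges to the new scene.
* **The test is signed.** An approaching object (`d̂` above `MD`) can never
  be reclassified, so a new object crossing an old target's footprint with
  camouflaging colors — the black-shadow case — stays foreground on depth
  evidence alone.

With `τ = ∞` and a constant-proximity depth channel, the depth path is
fully inert and the segmenter reproduces the color-only algorithm mask for
mask under a shared seed (this reduction is asserted in the tests; sharing
the depth-refresh coin is what keeps the two RNG streams aligned).

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `n_samples` (N) | samples per pixel | — | 20 |
| `radius` (R) | matching radius | 8-bit pixel-value units | 20 |
| `min_matches` (λ) | matches required for background | — | 2 |
| `subsample_factor` (ϕ) | update probability is 1/ϕ | — | 16 |
| `ghost_threshold` (τ) | ghost-test margin | 8-bit proximity units | 2 |
| `max_range_mm` | depth normalization range | mm | 8000 |

`N = 20, R = 20, λ = 2, ϕ = 16` is the standard operating point for this
family; larger `N` saturates, larger `λ` costs proportionally more distance
evaluations. Two scale conventions are ours to fix because fusion changes
the value range: the fused image is placed on a `[0,255]` working scale by
multiplying `[0,1.5]` by 170, so the default `R = 20` keeps its usual
magnitude after fusion; and `τ` is evaluated on the 8-bit proximity scale
(`d̂·255`), where the recommended range 1–3 corresponds to a few parts in
255 of the full depth range. Both the threshold and its scale are exposed
as configuration rather than asserted as universal.

`max_range_mm = 8000` reflects the practical limit of consumer
structured-light sensors; depths at or beyond it clip to proximity 0.

## Randomness and reproducibility

One seeded stream drives a run. Draws occur in raster order (rows, then
columns) and, within a background pixel, in the fixed order *self coin,
self slot, neighbor coin, neighbor index, neighbor slot*, with slot/index
draws made only when the corresponding coin fires. The depth-model refresh
consumes no draw of its own. Identical seed and inputs therefore give
bit-identical masks, models and on-disk artifacts, which the tests assert
down to PNG bytes. Neighbor choice at borders is uniform over the in-bounds
8-neighbors only — no wrap-around, no duplicated clamping.

## The lifespan law and how we test it

Under random subsampling, a sample present in a model survives one update
event with probability `(N−1)/N`, hence `((N−1)/N)^dt` after `dt` events —
equivalently `exp(−ln(N/(N−1))·dt)`; both closed forms are implemented and
agree to better than `1e−12` across a parameter grid. Folding in the `1/ϕ`
selection, a tagged sample of a background pixel survives `T` frames with
probability `(1 − 1/(Nϕ))^T`. `lifespan_experiment()` tags all samples of a
static 100×100 scene and measures the surviving fraction after `T = 320`
frames (64 million coin/slot decisions, ~0.4 expected survival), asserting
agreement within three binomial standard deviations. The experiment
deliberately isolates the *in-place* update channel that the law describes:
in the full loop the neighbor-diffusion channel replaces samples too (for
an interior pixel at roughly the same rate again), so full-loop survival
decays about twice as fast; the diffusion channel's own rate is checked
separately against a binomial oracle at `1/ϕ`.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders a textured static background (i.i.d. uniform
noise, frozen at frame 1) at a fixed depth, with rectangle/ellipse objects
in front of it on arbitrary per-frame trajectories, exact ground truth,
per-pixel depth holes re-drawn each frame (mimicking sensor flicker), and
optional global illumination flicker (which also re-draws the texture per
frame). The canned scenarios reproduce the situations that matter:
`ghost_scenario` (object in frame 1 only), `black_shadow_scenario` (object
A departs; object B with near-identical color but much closer depth crosses
A's footprint — the fixture guarantees B's color is within `R` of A's in
color space but far from it in fused space), `holes_scenario`,
`flicker_scenario`, `static_scenario`.

Real RGB-D footage differs in ways the generator does not model: textured
and multi-surface backgrounds with depth gradients, shadows and
reflections, motion blur, correlated (edge-aligned) depth holes and
quantization noise, imperfect color/depth registration, and gradual
illumination drift. Passing the synthetic suite therefore demonstrates the
*mechanisms* — ghost suppression, black-shadow retention, hole tolerance,
the update statistics — not field-grade accuracy on arbitrary recordings.
Scenario geometry (object ~¼ of the frame edge, depths 800–2500 mm against
3000–5000 mm backgrounds, noise amplitude 3, hole rate 0.005–0.05) was
chosen once as a plausible indoor configuration.

## Numerical and degenerate-input choices

* Matching uses strict `<` at the radius and `≥ λ` on the count; the
  match-count loop exits early at `λ`, which cannot change the label.
* Frame 1 is classified against its own just-initialized model (yielding a
  near-all-background first mask) and runs the same update branch as any
  other frame, so output length equals input length and all frames are
  treated identically.
* A 1×1 frame degenerates gracefully (its neighborhood is itself); empty
  frames, shape mismatches and out-of-bounds positions raise errors.
* Proximity, `σ` and fusion are exact in double precision; the `[0,1.5] →
  [0,255]` rescale is a single multiplication, and fusion-limit identities
  (`σ=1 ⇒ Î=ĉ`, `σ=0 ⇒ Î=(d̂+ĉ)/2`) hold to `1e−12` on random grids.
* PWC is undefined (an error) on zero evaluated pixels; the optional ignore
  mask removes pixels from every confusion bucket.
* 16-bit depth PNGs are written by a minimal built-in grayscale encoder
  (filter-0 scanlines, zlib stream, CRC32) and read back through `png`,
  which doubles as an independent check on the encoder; color and mask
  PNGs go through `png` directly. The depth "bit-swap" dialect of public
  benchmarks is exposed as a pair of inverse 16-bit rotations
  (`rotl3`/`rotr3`), verified as exact inverses on all 65 536 values,
  with `none` the default.

## Problem sizes

The shipped tests and the acceptance script run on 64×64 scenes of 60
frames (segmentation behavior), 100×100×320 (lifespan statistics), and
500-instance oracle sweeps — sizes at which every property is measurable
with comfortable statistical margins on a single CPU in seconds. All
fixtures are regenerated from seeds at run time; nothing is stored.

## Known limitations

* A ghost pixel whose *frame-1* depth reading was a hole carries no depth
  evidence (`MD = 0`) and cannot be reclassified; it decays only through
  neighbor diffusion, like plain color ViBe.
* Objects at nearly the background's depth (fused difference below `R`)
  fall back on color separation alone.
* The depth model stores a single value per pixel, not a distribution; a
  scene whose true background depth oscillates (foliage, fans) will
  trigger spurious ghost tests.
* No morphological post-processing is applied anywhere — masks are raw
  classifier output by design, so small speckle (e.g., at flickering
  holes) is expected and visible in the depth-only baseline.
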